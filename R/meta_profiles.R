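#' Select intergenic regions upstream of gene TSSs
#'
#' For every gene, the strand-oriented upstream gap — from the nearest
#' annotated gene boundary on the TSS's 5' side to the gene — is selected
#' when it spans at least `min_gap` bp. The chromosome start (for '+'
#' genes with no upstream neighbour) or end (for '-' genes) serves as the
#' boundary for terminal genes. Each selected gap is trimmed by `trim` bp
#' at both ends (those flanks are covered by the gene profiles) and the
#' remainder is later profiled in equal bins. Two genes sharing a gap
#' produce a single region.
#'
#' @param ann an [annotation()].
#' @param min_gap minimum gap span in bp (default 30000).
#' @param trim bp removed from each end of a selected gap (default 10000);
#'   must satisfy `min_gap > 2 * trim`.
#' @return `data.frame` of class `"intergenic_regions"`: `chrom`, `start`,
#'   `end` (trimmed, 0-based half-open), `gap_start`, `gap_end`, `gene_id`
#'   (a gene whose upstream gap produced the region).
#' @export
select_intergenic_regions <- function(ann, min_gap = 30000, trim = 10000) {
  stopifnot(inherits(ann, "annotation"))
  if (min_gap <= 2 * trim)
    stop("min_gap must exceed 2 * trim")
  g <- ann_genome(ann)
  out <- list()
  for (i in seq_len(nrow(ann))) {
    gene <- ann[i, ]
    same <- ann[ann$chrom == gene$chrom & ann$gene_id != gene$gene_id, ]
    if (gene$strand == "+") {
      ends <- same$tx_end[same$tx_end <= gene$tx_start]
      u <- if (length(ends)) max(ends) else 0
      gap <- c(u, gene$tx_start)
    } else {
      starts <- same$tx_start[same$tx_start >= gene$tx_end]
      v <- if (length(starts)) min(starts) else unclass(g)[[gene$chrom]]
      gap <- c(gene$tx_end, v)
    }
    if (gap[2] - gap[1] >= min_gap)
      out[[length(out) + 1]] <- data.frame(
        chrom = gene$chrom, start = gap[1] + trim, end = gap[2] - trim,
        gap_start = gap[1], gap_end = gap[2], gene_id = gene$gene_id,
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(), start = numeric(),
                         end = numeric(), gap_start = numeric(),
                         gap_end = numeric(), gene_id = character(),
                         stringsAsFactors = FALSE)
  res <- res[!duplicated(res[, c("chrom", "start", "end")]), , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, genome = g,
            class = c("intergenic_regions", "data.frame"))
}

# Fractional partition of a length-L region into `bins` bins: offset p
# belongs to bin floor(p * bins / L), i.e. bin k covers fractional
# coordinates [L*k/bins, L*(k+1)/bins). Returns integer boundaries
# (length bins + 1); an empty bin (possible only when L < bins) is later
# served by the single position containing its fractional start.
fractional_boundaries <- function(L, bins) {
  k <- 0:bins
  (k * L + bins - 1) %/% bins  # ceiling(k*L/bins) in exact arithmetic
}

# Means of `v` (a full chromosome vector, 0-based positions) over `bins`
# fractional bins of [start, end); positions outside [0, chrom_len) are
# dropped from a bin's mean and an entirely out-of-range bin reports 0.
fractional_bin_means <- function(v, start, end, bins) {
  L <- end - start
  b <- fractional_boundaries(L, bins) + start
  out <- numeric(bins)
  len <- length(v)
  for (k in seq_len(bins)) {
    lo <- b[k]; hi <- b[k + 1]
    if (hi <= lo) {  # repeated-position bin for L < bins
      p <- ((k - 1) * L) %/% bins + start
      out[k] <- if (p >= 0 && p < len) v[p + 1] else 0
      next
    }
    lo2 <- max(lo, 0); hi2 <- min(hi, len)
    out[k] <- if (hi2 > lo2) mean(v[(lo2 + 1):hi2]) else 0
  }
  out
}

# Fixed-width left-to-right flank bins over [start, start + nbins*width).
flank_bin_means <- function(v, start, nbins, width) {
  b <- start + width * (0:nbins)
  out <- numeric(nbins)
  len <- length(v)
  for (k in seq_len(nbins)) {
    lo <- max(b[k], 0); hi <- min(b[k + 1], len)
    out[k] <- if (hi > lo) mean(v[(lo + 1):hi]) else 0
  }
  out
}

#' Bin a track over one gene body and its flanks
#'
#' The gene body is divided evenly into `body_bins` bins regardless of gene
#' length (fractional-coordinate partition), aligning all genes at the TSS
#' and TES; the immediate upstream and downstream `flank` regions are
#' divided into `flank / flank_bin` fixed-width bins of `flank_bin` bp.
#' Each bin value is the mean normalized count over its positions. The
#' returned vector is strand-oriented: index 1 is the most 5'-upstream
#' flank bin, so '-'-strand genes are reversed.
#'
#' @param track a (normalized) track.
#' @param gene one-row `data.frame` with `chrom`, `strand`, `tx_start`,
#'   `tx_end`.
#' @param flank flank span in bp (default 10000).
#' @param body_bins number of gene-body bins (default 50).
#' @param flank_bin flank bin width in bp (default 200).
#' @return numeric vector of length `2 * flank/flank_bin + body_bins`
#'   (150 with defaults).
#' @export
profile_gene <- function(track, gene, flank = 10000, body_bins = 50,
                         flank_bin = 200) {
  stopifnot(inherits(track, "track"), flank %% flank_bin == 0)
  v <- unclass(track)[[gene$chrom]]
  if (is.null(v)) stop("gene chromosome absent from track")
  nfl <- flank %/% flank_bin
  left <- flank_bin_means(v, gene$tx_start - flank, nfl, flank_bin)
  body <- fractional_bin_means(v, gene$tx_start, gene$tx_end, body_bins)
  right <- flank_bin_means(v, gene$tx_end, nfl, flank_bin)
  prof <- c(left, body, right)
  if (gene$strand == "-") prof <- rev(prof)
  prof
}

#' Build a genes-by-bins profile matrix
#'
#' Applies [profile_gene()] to every gene of an annotation.
#'
#' @inheritParams profile_gene
#' @param ann an [annotation()].
#' @return matrix of class `"profile_matrix"` (rows = gene ids, columns =
#'   bins, strand-oriented 5' to 3') with a `layout` attribute.
#' @export
profile_genes <- function(track, ann, flank = 10000, body_bins = 50,
                          flank_bin = 200) {
  stopifnot(inherits(ann, "annotation"))
  nfl <- flank %/% flank_bin
  m <- t(vapply(seq_len(nrow(ann)),
                function(i) profile_gene(track, ann[i, ], flank, body_bins,
                                         flank_bin),
                numeric(2 * nfl + body_bins)))
  rownames(m) <- ann$gene_id
  structure(m, layout = list(kind = "gene", flank = flank,
                             body_bins = body_bins, flank_bin = flank_bin,
                             flank_bins = nfl),
            class = c("profile_matrix", class(m)))
}

#' Bin a track over intergenic regions
#'
#' Each (trimmed) intergenic region is divided evenly into `bins`
#' fractional bins; a bin's value is the mean normalized count over its
#' positions.
#'
#' @param track a (normalized) track.
#' @param regions an `"intergenic_regions"` table from
#'   [select_intergenic_regions()].
#' @param bins number of bins per region (default 100).
#' @return matrix of class `"profile_matrix"` (rows = regions).
#' @export
profile_intergenic_regions <- function(track, regions, bins = 100) {
  stopifnot(inherits(track, "track"))
  m <- t(vapply(seq_len(nrow(regions)), function(i) {
    v <- unclass(track)[[regions$chrom[i]]]
    fractional_bin_means(v, regions$start[i], regions$end[i], bins)
  }, numeric(bins)))
  if (nrow(regions) > 0)
    rownames(m) <- paste0(regions$chrom, ":", regions$start, "-",
                          regions$end)
  structure(m, layout = list(kind = "intergenic", bins = bins),
            class = c("profile_matrix", class(m)))
}

#' Per-class condition-ratio enrichment curves
#'
#' For each gene class, the per-bin ratio of summed profile mass between
#' two conditions: `(sum_A + pc) / (sum_B + pc)` where the sums run over
#' the class's genes. Summed (rather than per-gene averaged) mass mirrors a
#' read-count ratio; the pseudocount guards empty bins. Both are
#' configurable.
#'
#' @param matA,matB `"profile_matrix"` objects with identical row ids and
#'   layout (condition A = numerator).
#' @param classes a `"gene_class_table"` (see [classify_genes()]) or a
#'   named character vector `gene_id -> class`.
#' @param pseudocount added to numerator and denominator sums (default 0.5).
#' @param aggregate `"sum"` (default) or `"mean"` across class genes.
#' @return list of class `"class_ratio_profiles"`: one numeric ratio curve
#'   per class, plus attributes `pseudocount` and `layout`. Empty classes
#'   are skipped with a warning.
#' @export
class_ratio_profile <- function(matA, matB, classes, pseudocount = 0.5,
                                aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(matA, "profile_matrix"),
            inherits(matB, "profile_matrix"))
  if (!identical(rownames(matA), rownames(matB)) ||
      !identical(dim(matA), dim(matB)))
    stop("profile matrices must share row ids and layout")
  if (inherits(classes, "gene_class_table"))
    classes <- setNames(classes$class, classes$gene_id)
  classes <- classes[names(classes) %in% rownames(matA)]
  out <- list()
  for (cl in unique(classes)) {
    ids <- names(classes)[classes == cl]
    if (length(ids) == 0) {
      warning("empty class '", cl, "' skipped")
      next
    }
    agg <- if (aggregate == "sum") colSums else colMeans
    a <- agg(matA[ids, , drop = FALSE])
    b <- agg(matB[ids, , drop = FALSE])
    out[[cl]] <- (a + pseudocount) / (b + pseudocount)
  }
  structure(out, pseudocount = pseudocount, aggregate = aggregate,
            layout = attr(matA, "layout"), class = "class_ratio_profiles")
}

#' @export
print.class_ratio_profiles <- function(x, ...) {
  cat("<class_ratio_profiles> classes:",
      paste(names(x), collapse = ", "), "\n")
  for (cl in names(x))
    cat(sprintf("  %-14s bins %d, ratio range [%.3f, %.3f]\n", cl,
                length(x[[cl]]), min(x[[cl]]), max(x[[cl]])))
  invisible(x)
}

#' @export
plot.class_ratio_profiles <- function(x, ...) {
  nb <- length(x[[1]])
  cols <- grDevices::rainbow(length(x))
  plot(NULL, xlim = c(1, nb), ylim = range(unlist(x), 1),
       xlab = "bin", ylab = "condition A / condition B", ...)
  for (i in seq_along(x)) lines(seq_len(nb), x[[i]], col = cols[i])
  abline(h = 1, lty = 3)
  legend("topright", legend = names(x), col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Order profile rows by descending expression
#'
#' Rows are ranked from the highest expression (top) to the lowest
#' (bottom); ties break by gene id so the order is deterministic.
#'
#' @param mat a `"profile_matrix"` whose rows are genes.
#' @param expression named numeric vector of per-gene expression scalars
#'   covering every row of `mat`.
#' @return the reordered matrix.
#' @export
expression_ranked_matrix <- function(mat, expression) {
  missing <- setdiff(rownames(mat), names(expression))
  if (length(missing))
    stop("no expression value for: ", paste(missing, collapse = ", "))
  e <- expression[rownames(mat)]
  o <- order(-e, names(e))
  mat[o, , drop = FALSE]
}
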