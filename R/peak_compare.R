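#' Construct a peak set
#'
#' @param chrom,start,end peak intervals (0-based half-open).
#' @param height nonnegative summit/enrichment score.
#' @param name optional peak names.
#' @param genome optional [genome()].
#' @return `data.frame` of class `"peak_set"`.
#' @export
peak_set <- function(chrom, start, end, height, name = NULL,
                     genome = NULL) {
  n <- length(start)
  if (is.null(name)) name <- if (n) paste0("peak", seq_len(n)) else character()
  stopifnot(length(chrom) == n, length(end) == n, length(height) == n)
  if (any(start >= end)) stop("peak start must be < end")
  if (any(height < 0)) stop("peak heights must be nonnegative")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   height = as.numeric(height), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("peak_set", "data.frame"))
}

peaks_granges <- function(pk) {
  GRanges(pk$chrom, IRanges(start = pk$start + 1, end = pk$end))
}

#' Genes whose promoters overlap a peak set
#'
#' A gene is reported when any peak overlaps the promoter window
#' `[TSS - window, TSS + window]` (inclusive of both ends); each gene is
#' counted once regardless of how many peaks hit it. The default window of
#' 2 kb is a conventional promoter definition and is configurable.
#'
#' @param peaks a [peak_set()].
#' @param ann an [annotation()].
#' @param window half-width of the promoter window in bp (default 2000).
#' @return character vector of gene ids (sorted, unique).
#' @export
assign_promoter_genes <- function(peaks, ann, window = 2000) {
  stopifnot(inherits(ann, "annotation"))
  if (nrow(peaks) == 0) return(character())
  t <- tss(ann)
  prom <- GRanges(ann$chrom, IRanges(start = pmax(t - window, 0) + 1,
                                     end = t + window + 1))
  hits <- findOverlaps(prom, peaks_granges(peaks))
  sort(unique(ann$gene_id[queryHits(hits)]))
}

#' Two-set Venn counts
#'
#' @param set_a,set_b vectors (treated as sets).
#' @return list of class `"venn_counts"`: `only_a`, `common`, `only_b`.
#' @export
venn_counts <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  structure(list(only_a = length(setdiff(set_a, set_b)),
                 common = length(intersect(set_a, set_b)),
                 only_b = length(setdiff(set_b, set_a))),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("<venn_counts> A-only:", x$only_a, " common:", x$common,
      " B-only:", x$only_b, "\n")
  invisible(x)
}

#' Match peaks shared between two sets
#'
#' Pairs peaks with reciprocal positional overlap of at least 1 bp; each
#' peak pairs with at most one partner. Candidate pairs are ranked by
#' overlap width (largest first), ties broken by smallest coordinates, and
#' assigned greedily.
#'
#' @param peaks_a,peaks_b [peak_set()] objects.
#' @return `data.frame` with one row per matched pair: indices `idx_a`,
#'   `idx_b` (rows of the inputs), `overlap` (bp), and the heights and
#'   lengths of both sides.
#' @export
match_shared_peaks <- function(peaks_a, peaks_b) {
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      overlap = numeric(),
                      height_a = numeric(), height_b = numeric(),
                      length_a = numeric(), length_b = numeric())
  if (nrow(peaks_a) == 0 || nrow(peaks_b) == 0) return(empty)
  hits <- findOverlaps(peaks_granges(peaks_a), peaks_granges(peaks_b))
  if (length(hits) == 0) return(empty)
  qa <- queryHits(hits); qb <- subjectHits(hits)
  ov <- pmin(peaks_a$end[qa], peaks_b$end[qb]) -
        pmax(peaks_a$start[qa], peaks_b$start[qb])
  o <- order(-ov, peaks_a$start[qa], peaks_b$start[qb], qa, qb)
  used_a <- logical(nrow(peaks_a)); used_b <- logical(nrow(peaks_b))
  keep <- integer()
  for (i in o) {
    if (used_a[qa[i]] || used_b[qb[i]]) next
    used_a[qa[i]] <- used_b[qb[i]] <- TRUE
    keep <- c(keep, i)
  }
  data.frame(idx_a = qa[keep], idx_b = qb[keep], overlap = ov[keep],
             height_a = peaks_a$height[qa[keep]],
             height_b = peaks_b$height[qb[keep]],
             length_a = peaks_a$end[qa[keep]] - peaks_a$start[qa[keep]],
             length_b = peaks_b$end[qb[keep]] - peaks_b$start[qb[keep]])
}

#' Compare height and length of shared peaks between conditions
#'
#' Welch two-sample t-tests comparing the A-side and B-side heights and
#' lengths of matched peak pairs.
#'
#' @param pairs output of [match_shared_peaks()].
#' @return list of class `"peak_dimension_stats"` with components `height`
#'   and `length`, each holding `t`, `p`, `mean_a`, `mean_b`, `df`. A
#'   dimension with zero variance on both sides is reported as `NA` with
#'   `note = "undefined: zero variance"`.
#' @export
compare_peak_dimensions <- function(pairs) {
  if (nrow(pairs) < 2)
    stop("at least 2 matched pairs required")
  one <- function(a, b) {
    if (var(a) == 0 && var(b) == 0)
      return(list(t = NA_real_, p = NA_real_, mean_a = mean(a),
                  mean_b = mean(b), df = NA_real_,
                  note = "undefined: zero variance"))
    tt <- t.test(a, b, var.equal = FALSE)
    list(t = unname(tt$statistic), p = tt$p.value, mean_a = mean(a),
         mean_b = mean(b), df = unname(tt$parameter), note = NULL)
  }
  structure(list(height = one(pairs$height_a, pairs$height_b),
                 length = one(pairs$length_a, pairs$length_b),
                 n_pairs = nrow(pairs)),
            class = "peak_dimension_stats")
}

#' @export
print.peak_dimension_stats <- function(x, ...) {
  cat("<peak_dimension_stats> ", x$n_pairs, " shared peaks\n", sep = "")
  for (d in c("height", "length")) {
    s <- x[[d]]
    if (!is.null(s$note))
      cat(sprintf("  %-7s %s\n", d, s$note))
    else
      cat(sprintf("  %-7s A=%.2f B=%.2f  Welch t=%.3f, p=%.3g\n",
                  d, s$mean_a, s$mean_b, s$t, s$p))
  }
  invisible(x)
}
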