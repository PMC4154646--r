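#' Read aligned reads from a 6-column BED file
#'
#' The 5' position of a '+' read is the BED `start`; of a '-' read, the
#' BED `end - 1` (BED is 0-based half-open). Rows on chromosomes absent
#' from the genome are rejected and their count reported.
#'
#' @param path BED file (chrom, start, end, name, score, strand).
#' @param genome a [genome()].
#' @return a [read_set()].
#' @export
read_reads_bed <- function(path, genome) {
  genome <- check_genome(genome)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED file '", path, "': ",
                        conditionMessage(e)))
  st <- as.character(strand(gr))
  if (any(st == "*"))
    stop("BED reads must carry a '+' or '-' strand")
  chrom <- as.character(seqnames(gr))
  known <- chrom %in% names(genome)
  if (any(!known))
    message(sum(!known), " read(s) on unknown chromosomes rejected")
  pos <- ifelse(st == "+", start(gr) - 1, end(gr) - 1)
  read_set(chrom[known], pos[known], st[known], genome)
}

#' Write a read set as 6-column BED
#'
#' Each read is written as a 1-bp interval at its 5' position, so the
#' file round-trips exactly through [read_reads_bed()].
#'
#' @param rs a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  gr <- GRanges(rs$chrom, IRanges(start = rs$pos + 1, width = 1),
                strand = rs$strand)
  if (nrow(rs) > 0) {
    mcols(gr)$name <- paste0("r", seq_len(nrow(rs)))
    mcols(gr)$score <- 0
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `strand`, `txStart`,
#'   `txEnd` (0-based half-open).
#' @param genome a [genome()]; when `NULL`, chromosome lengths are
#'   inferred as the maximum `txEnd` per chromosome.
#' @return an [annotation()].
#' @export
read_annotation_table <- function(path, genome = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "))
  if (is.null(genome))
    genome <- genome(tapply(df$txEnd, df$chrom, max))
  annotation(df$gene_id, df$chrom, df$strand, df$txStart, df$txEnd,
             genome)
}

#' Write a gene annotation table
#'
#' @param ann an [annotation()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  stopifnot(inherits(ann, "annotation"))
  df <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                   strand = ann$strand, txStart = ann$tx_start,
                   txEnd = ann$tx_end)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 5-column peak BED file
#'
#' @param path BED file (chrom, start, end, name, height-as-score).
#' @param genome optional [genome()].
#' @return a [peak_set()].
#' @export
read_peaks_bed <- function(path, genome = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED file '", path, "': ",
                        conditionMessage(e)))
  h <- if (!is.null(mcols(gr)$score)) as.numeric(mcols(gr)$score)
       else rep(0, length(gr))
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else NULL
  peak_set(as.character(seqnames(gr)), start(gr) - 1, end(gr), h,
           name = nm, genome = genome)
}

#' Write a peak set as 5-column BED
#'
#' @param pk a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(pk, path) {
  stopifnot(inherits(pk, "peak_set"))
  gr <- GRanges(pk$chrom, IRanges(start = pk$start + 1, end = pk$end))
  mcols(gr)$name <- pk$name
  mcols(gr)$score <- pk$height
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a normalized track as bedGraph
#'
#' Runs of equal value are merged; zero-valued runs are omitted (readers
#' treat absence as 0). Two scalings are offered: `"expectation1"` writes
#' the normalized values themselves (genome-average density 1), `"per10M"`
#' rescales to the read depth of a 10-million-read library (raw counts
#' times `1e7 / n_reads`), the conventional browser-track scaling.
#'
#' @param track a `"normalized_track"`.
#' @param path output path.
#' @param scaling `"expectation1"` (default) or `"per10M"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path,
                           scaling = c("expectation1", "per10M")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(track, "normalized_track"))
  fac <- if (scaling == "per10M") {
    # normalized value v = count / (n_reads/g_eff); count * 1e7/n_reads
    # = v * 1e7 / g_eff
    1e7 / attr(track, "g_eff")
  } else 1
  grs <- list()
  for (cn in names(unclass(track))) {
    r <- rle(unclass(track)[[cn]] * fac)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != 0
    if (!any(keep)) next
    grs[[cn]] <- GRanges(cn, IRanges(start = starts[keep],
                                     end = ends[keep]),
                         score = r$values[keep])
  }
  gr <- if (length(grs)) do.call(c, unname(grs)) else
    GRanges(score = numeric())
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a per-base track
#'
#' Positions absent from the file are 0.
#'
#' @param path bedGraph path.
#' @param genome a [genome()].
#' @param kind track kind label (default `"centered"`).
#' @return a `"track"` of per-base values.
#' @export
read_bedgraph <- function(path, genome, kind = "centered") {
  genome <- check_genome(genome)
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(names(genome), function(cn) {
    v <- numeric(unclass(genome)[[cn]])
    sel <- as.character(seqnames(gr)) == cn
    if (any(sel)) {
      s <- start(gr)[sel]; e <- end(gr)[sel]
      sc <- mcols(gr)$score[sel]
      for (i in seq_along(s)) v[s[i]:e[i]] <- sc[i]
    }
    v
  })
  names(vals) <- names(genome)
  new_track(vals, genome, kind)
}

#' Write an expression matrix with a two-row header
#'
#' Row 1 carries the condition of every sample column, row 2 the
#' replicate label; data rows start with the gene/probe id.
#'
#' @param mat an [expression_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  cond <- attr(mat, "condition")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("condition", cond), collapse = "\t"), con)
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  write.table(data.frame(id = rownames(mat), unclass(mat),
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param path TSV path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  cond <- strsplit(lines[1], "\t")[[1]][-1]
  reps <- strsplit(lines[2], "\t")[[1]][-1]
  df <- read.delim(text = lines[-(1:2)], header = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- reps
  expression_matrix(m, cond)
}

#' Write a gene class table
#'
#' @param tab a `"gene_class_table"`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(tab, path) {
  stopifnot(inherits(tab, "gene_class_table"))
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene class table written by [write_class_table()]
#'
#' @param path TSV path.
#' @return a `"gene_class_table"` data.frame.
#' @export
read_class_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("gene_class_table", "data.frame"))
}

#' Write a profile matrix as TSV
#'
#' The header encodes the bin layout: gene matrices use
#' `up_<i>` / `body_<i>` / `down_<i>` columns, intergenic matrices
#' `bin_<i>`.
#'
#' @param mat a `"profile_matrix"`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "profile_matrix"))
  lay <- attr(mat, "layout")
  labels <- if (lay$kind == "gene")
    c(paste0("up_", seq_len(lay$flank_bins)),
      paste0("body_", seq_len(lay$body_bins)),
      paste0("down_", seq_len(lay$flank_bins)))
  else paste0("bin_", seq_len(lay$bins))
  df <- data.frame(id = rownames(mat), unclass(mat), check.names = FALSE)
  colnames(df) <- c("id", labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile matrix written by [write_profile_matrix()]
#'
#' @param path TSV path.
#' @return a `"profile_matrix"`.
#' @export
read_profile_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cols <- colnames(df)[-1]
  lay <- if (all(grepl("^bin_", cols)))
    list(kind = "intergenic", bins = length(cols))
  else {
    nfl <- sum(grepl("^up_", cols))
    list(kind = "gene", flank_bins = nfl,
         body_bins = sum(grepl("^body_", cols)), flank_bin = NA,
         flank = NA)
  }
  structure(m, layout = lay, class = c("profile_matrix", class(m)))
}
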