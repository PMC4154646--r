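#' Per-base read-count tracks
#'
#' A track holds one numeric value per base of the genome, either the count
#' of shifted fragment centers at each position (`kind = "centered"`) or the
#' number of extended fragments covering each position (`kind = "coverage"`).
#'
#' @name tracks
NULL

new_track <- function(values, genome, kind, normalized = FALSE,
                      n_reads = NULL, g_eff = NULL) {
  structure(values, genome = genome, kind = kind,
            n_reads = n_reads, g_eff = g_eff,
            class = if (normalized) c("normalized_track", "track")
                    else "track")
}

#' Genome and kind of a track
#' @param tr a `"track"`.
#' @return the attached [genome()] / the kind string.
#' @export
track_genome <- function(tr) attr(tr, "genome")

#' @rdname track_genome
#' @export
track_kind <- function(tr) attr(tr, "kind")

#' @export
print.track <- function(x, ...) {
  tot <- sum(vapply(x, sum, numeric(1)))
  cat("<", paste(class(x)[1]), "> kind=", track_kind(x), ", ",
      length(x), " chromosome(s), total mass ", format(tot), "\n", sep = "")
  invisible(x)
}

#' Count fragment centers at each genomic position
#'
#' @param centers `data.frame` with columns `chrom`, `center` (0-based), as
#'   returned by [shift_to_centers()].
#' @param genome a [genome()].
#' @return a `"track"` (named list of per-base numeric vectors, one per
#'   chromosome) with `kind = "centered"`. The track sum equals the number
#'   of centers.
#' @export
centered_counts <- function(centers, genome) {
  genome <- check_genome(genome)
  stopifnot(all(c("chrom", "center") %in% names(centers)))
  if (nrow(centers) > 0) {
    if (!all(centers$chrom %in% names(genome)))
      stop("centers on chromosomes absent from the genome")
    if (any(centers$center < 0) ||
        any(centers$center >= unclass(genome)[centers$chrom]))
      stop("centers out of chromosome bounds")
  }
  vals <- lapply(names(genome), function(cn) {
    as.numeric(tabulate(centers$center[centers$chrom == cn] + 1,
                        nbins = unclass(genome)[[cn]]))
  })
  names(vals) <- names(genome)
  new_track(vals, genome, "centered")
}

#' Count fragments covering each genomic position
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), as returned by [extend_to_fragments()].
#' @param genome a [genome()].
#' @return a `"track"` with `kind = "coverage"`; its sum equals the total
#'   interval length.
#' @export
fragment_coverage <- function(intervals, genome) {
  genome <- check_genome(genome)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  vals <- lapply(names(genome), function(cn) {
    len <- unclass(genome)[[cn]]
    iv <- intervals[intervals$chrom == cn, , drop = FALSE]
    if (nrow(iv) == 0) return(numeric(len))
    if (any(iv$start < 0) || any(iv$end > len) || any(iv$start >= iv$end))
      stop("intervals out of bounds on ", cn)
    cov <- coverage(IRanges(start = iv$start + 1, end = iv$end),
                    width = len)
    as.numeric(cov)
  })
  names(vals) <- names(genome)
  new_track(vals, genome, "coverage")
}

#' Normalize a track by the average read frequency per base pair
#'
#' Divides every per-base value by `n_reads / g_eff`, the average read
#' frequency per base pair of the effective genome size. After this
#' normalization the expectation of the read count at any position is 1, so
#' a value of `v` means `v`-fold the genome-average density. For human data
#' the mappable genome size 2.7e9 bp is the conventional `g_eff`; for
#' synthetic genomes use the genome length.
#'
#' @param track a `"track"`.
#' @param n_reads number of (post-deduplication) reads contributing to the
#'   track; must be `> 0`.
#' @param g_eff effective genome size in bp (default `2.7e9`).
#' @return a `"normalized_track"` carrying `n_reads` and `g_eff` metadata.
#' @export
normalize_track <- function(track, n_reads, g_eff = 2.7e9) {
  stopifnot(inherits(track, "track"))
  if (!is.numeric(n_reads) || n_reads <= 0)
    stop("n_reads must be positive")
  if (!is.numeric(g_eff) || g_eff <= 0)
    stop("g_eff must be positive")
  scale <- n_reads / g_eff
  vals <- lapply(unclass(track), function(v) v / scale)
  new_track(vals, track_genome(track), track_kind(track),
            normalized = TRUE, n_reads = n_reads, g_eff = g_eff)
}

track_mean <- function(tr) {
  tot <- sum(vapply(unclass(tr), sum, numeric(1)))
  tot / genome_size(track_genome(tr))
}
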