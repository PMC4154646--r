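#' Define a genome as named chromosome lengths
#'
#' @param lengths named numeric vector of chromosome lengths in bp, or a
#'   list of `(name, length)` pairs.
#' @return named integer-valued numeric vector with class `"mm_genome"`.
#' @examples
#' genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome <- function(lengths) {
  if (is.list(lengths)) {
    nm <- vapply(lengths, function(x) as.character(x[[1]]), character(1))
    lengths <- setNames(vapply(lengths, function(x) as.numeric(x[[2]]),
                               numeric(1)), nm)
  }
  if (is.null(names(lengths)) || anyNA(names(lengths)) ||
      any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("chromosome lengths must be positive")
  structure(round(lengths), class = "mm_genome")
}

#' Total genome size in bp
#' @param g a [genome()].
#' @return numeric total length.
#' @export
genome_size <- function(g) sum(unname(unclass(g)))

is_genome <- function(g) inherits(g, "mm_genome")

check_genome <- function(g) {
  if (!is_genome(g)) g <- genome(g)
  g
}

#' @export
print.mm_genome <- function(x, ...) {
  cat("<genome> ", length(x), " chromosome(s), ",
      format(genome_size(x), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}
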