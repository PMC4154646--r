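#' Construct an expression matrix with condition labels
#'
#' @param values numeric matrix (rows = probes or genes, log scale) with
#'   row names.
#' @param condition character vector over columns, two levels (condition A
#'   first, e.g. the MMSET-high sample; condition B second).
#' @return matrix of class `"expression_matrix"` with a `condition`
#'   attribute.
#' @export
expression_matrix <- function(values, condition) {
  stopifnot(is.matrix(values), length(condition) == ncol(values))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  lev <- unique(condition)
  if (length(lev) != 2) stop("exactly two conditions required")
  if (min(table(condition)) < 2)
    stop("at least 2 replicates per condition required")
  structure(values, condition = as.character(condition),
            class = c("expression_matrix", class(values)))
}

em_split <- function(mat) {
  cond <- attr(mat, "condition")
  lev <- unique(cond)
  list(A = unclass(mat)[, cond == lev[1], drop = FALSE],
       B = unclass(mat)[, cond == lev[2], drop = FALSE],
       levels = lev)
}

#' Filter probes by detection across replicates
#'
#' A probe is kept when it has at least `min_positive` positive (log-scale
#' value `> 0`) expression values among the replicates of condition A
#' *and* of condition B.
#'
#' @param mat an [expression_matrix()].
#' @param min_positive minimum count of positive values per condition
#'   (default 4, against 6 replicates).
#' @return character vector of kept probe ids.
#' @export
filter_probes <- function(mat, min_positive = 4) {
  s <- em_split(mat)
  if (ncol(s$A) < min_positive || ncol(s$B) < min_positive)
    stop("min_positive exceeds the replicate count")
  keep <- rowSums(s$A > 0) >= min_positive & rowSums(s$B > 0) >= min_positive
  rownames(mat)[keep]
}

#' Collapse probe-level rows to gene level
#'
#' Keeps protein-coding probes only; a gene measured by several probes is
#' represented by the probe with the highest overall mean expression.
#' Genes in the map with no surviving probe are dropped and reported in
#' the `"dropped_genes"` attribute.
#'
#' @param mat an [expression_matrix()] of (filtered) probes.
#' @param map `data.frame` with columns `probe_id`, `gene_id`,
#'   `protein_coding` (logical).
#' @return a gene-level `"expression_matrix"`.
#' @export
collapse_probes_to_genes <- function(mat, map) {
  stopifnot(all(c("probe_id", "gene_id", "protein_coding") %in% names(map)))
  map <- map[map$protein_coding, , drop = FALSE]
  all_genes <- unique(map$gene_id)
  map <- map[map$probe_id %in% rownames(mat), , drop = FALSE]
  if (anyDuplicated(map$probe_id))
    stop("a probe maps to more than one gene")
  means <- rowMeans(unclass(mat))[map$probe_id]
  best <- vapply(split(seq_len(nrow(map)), map$gene_id), function(ix) {
    m <- means[ix]
    ix[order(-m, map$probe_id[ix])][1]  # deterministic on tied means
  }, integer(1))
  out <- unclass(mat)[map$probe_id[best], , drop = FALSE]
  rownames(out) <- names(best)
  out <- out[order(rownames(out)), , drop = FALSE]
  res <- expression_matrix(out, attr(mat, "condition"))
  attr(res, "dropped_genes") <- setdiff(all_genes, rownames(out))
  res
}

# Vectorized two-sample t-tests across rows; Welch by default,
# pooled-variance Student via var_equal = TRUE.
row_t_tests <- function(A, B, var_equal = FALSE) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(mA))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  t <- (mA - mB) / se
  # zero variance on both sides with equal means: no evidence of change
  t[se == 0 & mA == mB] <- 0
  df[se == 0] <- nA + nB - 2
  p <- 2 * pt(-abs(t), df)
  p[se == 0 & mA != mB] <- 0  # degenerate but unambiguous separation
  t[se == 0 & mA != mB] <- sign(mA - mB)[se == 0 & mA != mB] * Inf
  list(t = t, p = p, df = df, mean_a = mA, mean_b = mB)
}

#' Classify genes by differential expression between two conditions
#'
#' A gene whose (log-scale) mean expression is below `low_expr` in both
#' conditions is `not_expressed`. Every other gene gets a two-sample
#' t-test between the condition replicates: genes with `p < p_threshold`
#' are `up` (condition A above B) or `down` according to the sign of the
#' t statistic, all remaining genes are `no_change`. No multiple-testing
#' correction is applied; the fixed threshold is the classification rule.
#'
#' @param mat a gene-level [expression_matrix()].
#' @param p_threshold two-sided p-value cutoff (default 0.002).
#' @param low_expr not-expressed cutoff on the condition means (default 3,
#'   log scale). Set `low_expr_per_replicate = TRUE` to require every
#'   replicate (rather than the mean) below the cutoff.
#' @param var_equal `FALSE` (default) for the Welch test, `TRUE` for the
#'   pooled-variance Student test.
#' @param low_expr_per_replicate see `low_expr`.
#' @return `data.frame` of class `"gene_class_table"`: `gene_id`, `class`
#'   (`up` / `down` / `no_change` / `not_expressed`), `t`, `p`,
#'   `mean_a`, `mean_b` (`t`, `p` are `NA` for `not_expressed`).
#' @export
classify_genes <- function(mat, p_threshold = 0.002, low_expr = 3,
                           var_equal = FALSE,
                           low_expr_per_replicate = FALSE) {
  s <- em_split(mat)
  if (any(!is.finite(unclass(mat)))) {
    bad <- rownames(mat)[apply(!is.finite(unclass(mat)), 1, any)]
    stop("non-finite expression for: ", paste(bad, collapse = ", "))
  }
  tt <- row_t_tests(s$A, s$B, var_equal = var_equal)
  notexpr <- if (low_expr_per_replicate)
    apply(s$A < low_expr, 1, all) & apply(s$B < low_expr, 1, all)
  else
    tt$mean_a < low_expr & tt$mean_b < low_expr
  cls <- ifelse(notexpr, "not_expressed",
         ifelse(tt$p < p_threshold & tt$t > 0, "up",
         ifelse(tt$p < p_threshold & tt$t < 0, "down", "no_change")))
  res <- data.frame(gene_id = rownames(mat), class = cls,
                    t = ifelse(notexpr, NA_real_, tt$t),
                    p = ifelse(notexpr, NA_real_, tt$p),
                    mean_a = tt$mean_a, mean_b = tt$mean_b,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, p_threshold = p_threshold, low_expr = low_expr,
            var_equal = var_equal,
            class = c("gene_class_table", "data.frame"))
}

#' @export
print.gene_class_table <- function(x, ...) {
  tab <- table(factor(x$class,
                      c("up", "down", "no_change", "not_expressed")))
  cat("<gene_class_table> ", nrow(x), " genes (p < ",
      attr(x, "p_threshold"), "): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
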