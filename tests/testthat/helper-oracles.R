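# Independent brute-force oracles. These deliberately re-derive each
# quantity with plain loops and textbook formulas, sharing no code with
# the package internals they check.

# Strand-oriented upstream-gap selection, position by position.
oracle_intergenic <- function(ann, min_gap = 30000, trim = 10000) {
  g <- unclass(attr(ann, "genome"))
  found <- list()
  for (i in seq_len(nrow(ann))) {
    gi <- ann[i, ]
    lo <- NA; hi <- NA
    if (gi$strand == "+") {
      lo <- 0
      for (j in seq_len(nrow(ann))) {
        gj <- ann[j, ]
        if (j != i && gj$chrom == gi$chrom &&
            gj$tx_end <= gi$tx_start && gj$tx_end > lo)
          lo <- gj$tx_end
      }
      hi <- gi$tx_start
    } else {
      lo <- gi$tx_end
      hi <- g[[gi$chrom]]
      for (j in seq_len(nrow(ann))) {
        gj <- ann[j, ]
        if (j != i && gj$chrom == gi$chrom &&
            gj$tx_start >= gi$tx_end && gj$tx_start < hi)
          hi <- gj$tx_start
      }
    }
    if (hi - lo >= min_gap)
      found[[length(found) + 1]] <-
        c(chrom = gi$chrom, start = lo + trim, end = hi - trim)
  }
  if (!length(found))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  df <- unique(data.frame(
    chrom = vapply(found, `[[`, "", "chrom"),
    start = as.numeric(vapply(found, `[[`, "", "start")),
    end = as.numeric(vapply(found, `[[`, "", "end")),
    stringsAsFactors = FALSE))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Fractional binning: offset p of a length-L region belongs to bin
# floor(p * bins / L); an empty bin takes the position holding its
# fractional start. Means computed position by position.
oracle_bin_means <- function(v, start, end, bins) {
  L <- end - start
  out <- numeric(bins)
  for (k in 0:(bins - 1)) {
    ps <- integer()
    for (p in 0:(L - 1)) if (floor(p * bins / L) == k)
      ps <- c(ps, start + p)
    if (!length(ps)) ps <- start + floor(k * L / bins)
    ps <- ps[ps >= 0 & ps < length(v)]
    out[k + 1] <- if (length(ps)) mean(v[ps + 1]) else 0
  }
  out
}

# Welch two-sample t statistic, p-value and df from the textbook
# formulas.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Strand cross-correlation by explicit summation: Pearson correlation of
# the pooled overlapping segments of f+(x) and f-(x+d).
oracle_xcorr <- function(rs, lags) {
  g <- unclass(attr(rs, "genome"))
  fw <- rv <- list()
  for (cn in names(g)) {
    fw[[cn]] <- rv[[cn]] <- numeric(g[[cn]])
    for (i in seq_len(nrow(rs))) {
      if (rs$chrom[i] != cn) next
      p <- rs$pos[i] + 1
      if (rs$strand[i] == "+") fw[[cn]][p] <- fw[[cn]][p] + 1
      else rv[[cn]][p] <- rv[[cn]][p] + 1
    }
  }
  vapply(lags, function(d) {
    x <- numeric(); y <- numeric()
    for (cn in names(g)) {
      n <- g[[cn]]
      if (n <= d + 1) next
      x <- c(x, fw[[cn]][1:(n - d)])
      y <- c(y, rv[[cn]][(1 + d):n])
    }
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- sum(x * y) - sx * sy / n
    den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}

# Small-scale defaults used across tests: a two-chromosome genome sized
# so the 30 kb gap rule is exercised while everything stays fast.
tiny_cfg <- function(...) {
  args <- list(chromosomes = c(chrA = 1.2e6, chrB = 9e5), n_genes = 30,
               n_fragments = 2e4)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Drawn intergenic gaps of a generated annotation: the space before each
# gene, measured from the previous gene end (or the chromosome start).
diff_gaps <- function(ann) {
  gaps <- numeric()
  for (cn in unique(ann$chrom)) {
    sub <- ann[ann$chrom == cn, ]
    sub <- sub[order(sub$tx_start), ]
    prev <- 0
    for (i in seq_len(nrow(sub))) {
      gaps <- c(gaps, sub$tx_start[i] - prev)
      prev <- sub$tx_end[i]
    }
  }
  gaps
}

# A deterministic constant-plus-spike track for profile tests.
flat_track <- function(genome, value = 1) {
  tr <- centered_counts(data.frame(chrom = character(),
                                   center = numeric()), genome)
  for (cn in names(tr)) tr[[cn]] <- rep(value, length(tr[[cn]]))
  tr
}
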