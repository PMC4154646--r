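test_that("annotation generation is deterministic and non-overlapping", {
  cfg <- sim_config(chromosomes = c(c1 = 2e5), n_genes = 2, seed = 7)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 2)

  # brute-force pairwise interval intersection over a larger annotation
  cfg <- sim_config(chromosomes = c(c1 = 2e6, c2 = 1e6), n_genes = 50,
                    seed = 1)
  ann <- generate_annotation(cfg)
  overlaps <- 0
  for (i in seq_len(nrow(ann))) for (j in seq_len(nrow(ann))) {
    if (i == j || ann$chrom[i] != ann$chrom[j]) next
    if (ann$tx_start[i] < ann$tx_end[j] &&
        ann$tx_start[j] < ann$tx_end[i]) overlaps <- overlaps + 1
  }
  expect_equal(overlaps, 0)
})

test_that("gap mixture controls the intergenic truth set", {
  cfg1 <- tiny_cfg(chromosomes = c(chrA = 2e6, chrB = 1.5e6),
                   gap_mixture = 1.0, seed = 3)
  ann1 <- generate_annotation(cfg1)
  gaps <- diff_gaps(ann1)
  expect_true(all(gaps >= 30000))

  cfg2 <- tiny_cfg(gap_mixture = 0.5, seed = 3)
  ann2 <- generate_annotation(cfg2)
  gaps2 <- diff_gaps(ann2)
  expect_true(any(gaps2 >= 30000) && any(gaps2 < 30000))
})

test_that("planted truth partitions genes and matches the oracle gaps", {
  cfg <- tiny_cfg(seed = 11)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  expect_setequal(names(truth$classes), ann$gene_id)
  expect_true(all(truth$classes %in%
                  c("up", "down", "no_change", "not_expressed")))
  expect_equal(truth$fragment_length, cfg$fragment_length)

  # oracle gaps >= 30 kb recomputed by brute force, compared as interval
  # sets
  orc <- oracle_intergenic(ann, min_gap = 30000, trim = 0)
  got <- unique(truth$oracle_gaps[, c("chrom", "start", "end")])
  got <- got[order(got$chrom, got$start), ]
  rownames(got) <- NULL
  expect_equal(got, orc)
})

test_that("read generation conserves counts and recovers TSS enrichment", {
  cfg <- tiny_cfg(n_fragments = 1e4, seed = 5)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  rs <- generate_reads(ann, "focal", cfg, truth)
  expect_s3_class(rs, "read_set")
  expect_equal(nrow(rs), 10000)
  expect_error(generate_reads(ann, "nonsense", cfg, truth),
               "unknown condition")

  # analytic mixture density: mean centered count within +/-500 bp of
  # expressed TSSs relative to the genome-wide mean
  cfg <- tiny_cfg(n_fragments = 2e5, focal_peak_sd = 300, seed = 5)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  rs <- generate_reads(ann, "focal", cfg, truth)
  tr <- centered_counts(shift_to_centers(rs, cfg$fragment_length),
                        ann_genome(ann))
  ts <- tss(ann)[expressed_genes(truth)]
  cn <- ann$chrom[match(names(ts), ann$gene_id)]
  lens <- unclass(ann_genome(ann))[cn]
  ok <- ts - 500 >= 0 & ts + 500 < lens  # windows fully in bounds
  win <- unlist(lapply(which(ok), function(i)
    tr[[cn[i]]][(ts[i] - 500):(ts[i] + 500) + 1]))
  observed <- mean(win) / (nrow(rs) / sum(cfg$chromosomes))
  s <- cfg$focal_peak_sd
  G <- sum(cfg$chromosomes)
  w_bg <- 1 / (1 + length(ts) * cfg$focal_peak_height * s *
                 sqrt(2 * pi) / G)
  frac_in <- stats::pnorm(500.5 / s) - stats::pnorm(-500.5 / s)
  per_gene_mass <- (1 - w_bg) / length(ts)
  expected <- w_bg + per_gene_mass * frac_in * G / 1001
  expect_lt(abs(observed - expected) / expected, 0.20)
})

test_that("diffuse-to-focal background mass ratio approaches the configured fold", {
  cfg <- sim_config(chromosomes = c(c1 = 2e6, c2 = 1e6), n_genes = 40,
                    n_fragments = 1e5, seed = 9)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  focal <- generate_reads(ann, "focal", cfg, truth)
  diffuse <- generate_reads(ann, "diffuse", cfg, truth)

  # gene-poor windows: positions over 5 kb from any TSS (background-only
  # in the focal mixture)
  g <- ann_genome(ann)
  ts <- tss(ann)
  far_mass <- function(rs) {
    ctr <- shift_to_centers(rs, cfg$fragment_length)
    tot <- 0; bp <- 0
    for (cn in names(unclass(g))) {
      len <- unclass(g)[[cn]]
      keep <- rep(TRUE, len)
      for (t in ts[ann$chrom == cn]) {
        lo <- max(1, t - 5000); hi <- min(len, t + 5000)
        keep[lo:hi] <- FALSE
      }
      cc <- tabulate(ctr$center[ctr$chrom == cn] + 1, nbins = len)
      tot <- tot + sum(cc[keep]); bp <- bp + sum(keep)
    }
    tot / bp
  }
  ratio <- far_mass(diffuse) / far_mass(focal)
  expect_lt(abs(ratio - cfg$diffuse_fold) / cfg$diffuse_fold, 0.05)
})

test_that("expression generator plants classes as configured", {
  cfg <- tiny_cfg(seed = 13)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  mat <- generate_expression(cfg, truth)
  expect_equal(ncol(mat), 12)
  ne <- names(truth$classes)[truth$classes == "not_expressed"]
  expect_true(all(rowMeans(unclass(mat)[ne, , drop = FALSE]) < 3))

  # null case: no planted effects makes conditions exchangeable in
  # distribution; check the pooled mean difference is small
  cfg0 <- tiny_cfg(effect_size_up = 0, effect_size_down = 0, seed = 13)
  mat0 <- generate_expression(cfg0, truth)
  s <- unclass(mat0)
  d <- rowMeans(s[, 1:6]) - rowMeans(s[, 7:12])
  expect_lt(abs(mean(d)), 4 * cfg0$noise_sd / sqrt(6 * nrow(s)) * 2)

  # planted-up recovery: classifier finds > 95% of 2.0-log-unit effects
  cfgp <- sim_config(chromosomes = c(c1 = 4e7), n_genes = 1000,
                     gene_length_range = c(5000, 15000),
                     class_fractions = c(up = 1, down = 0, no_change = 0,
                                         not_expressed = 0), seed = 17)
  annp <- generate_annotation(cfgp)
  truthp <- simulate_truth(cfgp, annp)
  matp <- generate_expression(cfgp, truthp)
  cls <- classify_genes(matp)
  expect_gt(mean(cls$class == "up"), 0.95)
})

test_that("peak generator realizes the requested Venn structure", {
  cfg <- sim_config(chromosomes = c(c1 = 2e6, c2 = 1e6), n_genes = 40,
                    seed = 19)
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann, c(10, 8, 5))
  ga <- assign_promoter_genes(pk$a, ann)
  gb <- assign_promoter_genes(pk$b, ann)
  vc <- venn_counts(ga, gb)
  expect_equal(c(vc$only_a, vc$common, vc$only_b), c(10, 8, 5))

  # (0, k, 0): both promoter gene sets identical
  pk2 <- generate_peaks(cfg, ann, c(0, 12, 0))
  expect_setequal(assign_promoter_genes(pk2$a, ann),
                  assign_promoter_genes(pk2$b, ann))

  expect_error(generate_peaks(cfg, ann, c(30, 30, 30)), "only")
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- tiny_cfg(n_fragments = 5e3, seed = 23)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  expect_identical(generate_reads(ann, "focal", cfg, truth),
                   generate_reads(ann, "focal", cfg, truth))
  expect_identical(generate_expression(cfg, truth),
                   generate_expression(cfg, truth))
  expect_identical(generate_peaks(cfg, ann, c(3, 3, 3)),
                   generate_peaks(cfg, ann, c(3, 3, 3)))
})
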