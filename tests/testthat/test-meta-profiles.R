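test_that("intergenic selection applies the 30 kb / 10 kb rule", {
  g <- genome(c(c1 = 120000))
  ann <- annotation(c("gA", "gB"), c("c1", "c1"), c("+", "+"),
                    c(0, 40000), c(100, 60000), g)
  # gB's upstream gap runs from gA's end (100) to gB's TSS (40000):
  # 39,900 bp >= 30 kb -> selected and trimmed to [10100, 30000)
  reg <- select_intergenic_regions(ann)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(10100, 30000))

  # a 25 kb gap falls below the threshold
  ann2 <- annotation(c("gA", "gB"), c("c1", "c1"), c("+", "+"),
                     c(0, 30000), c(5000, 50000), g)
  expect_equal(nrow(select_intergenic_regions(ann2)), 0)

  # terminal '+' gene: chromosome start is the upstream boundary
  ann3 <- annotation("gA", "c1", "+", 50000, 60000, g)
  reg3 <- select_intergenic_regions(ann3)
  expect_equal(c(reg3$start, reg3$end), c(10000, 40000))

  expect_error(select_intergenic_regions(ann, min_gap = 15000),
               "min_gap")
})

test_that("intergenic selection equals the brute-force oracle on random annotations", {
  for (s in 1:20) {
    cfg <- tiny_cfg(seed = 1000 + s)
    ann <- generate_annotation(cfg)
    got <- select_intergenic_regions(ann)
    got <- data.frame(chrom = got$chrom, start = got$start,
                      end = got$end, stringsAsFactors = FALSE)
    rownames(got) <- NULL
    expect_equal(got, oracle_intergenic(ann), info = paste("seed", s))
  }
})

test_that("gene profiles bin exactly and respect orientation", {
  g <- genome(c(c1 = 60000))
  const <- flat_track(g, value = 3)
  ann <- annotation("g1", "c1", "+", 20000, 32345, g)
  prof <- profile_gene(const, ann[1, ])
  expect_length(prof, 150)
  expect_true(all(prof == 3))

  # spike just upstream of a '-' gene's TSS lands in the last upstream
  # flank bins (indices 48-50 of the oriented profile)
  spike <- flat_track(g, value = 0)
  annm <- annotation("g1", "c1", "-", 20000, 30000, g)
  spike$c1[30000 + 150 + 1] <- 100  # 150 bp 3'-of-TSS = upstream for '-'
  profm <- profile_gene(spike, annm[1, ])
  expect_equal(which(profm > 0), 50)
  annp <- annotation("g1", "c1", "+", 20000, 30000, g)
  spike2 <- flat_track(g, value = 0)
  spike2$c1[20000 - 150 + 1] <- 100
  expect_equal(which(profile_gene(spike2, annp[1, ]) > 0), 50)

  # body partition matches the position-by-position oracle for an
  # awkward length
  set.seed(21)
  v <- flat_track(g, value = 0)
  v$c1 <- runif(60000)
  ann_odd <- annotation("g1", "c1", "+", 20000, 32345, g)
  prof <- profile_gene(v, ann_odd[1, ])
  body_oracle <- oracle_bin_means(v$c1, 20000, 32345, 50)
  expect_equal(unname(prof[51:100]), body_oracle, tolerance = 1e-12)
  # and a short-gene (L < bins) body still yields 50 bins
  ann_short <- annotation("g1", "c1", "+", 20000, 20030, g)
  prof_s <- profile_gene(v, ann_short[1, ])
  expect_length(prof_s, 150)
  expect_equal(unname(prof_s[51:100]),
               oracle_bin_means(v$c1, 20000, 20030, 50),
               tolerance = 1e-12)
})

test_that("intergenic profiles use equal fractional bins", {
  g <- genome(c(c1 = 60000))
  const <- flat_track(g, 2.5)
  reg <- structure(data.frame(chrom = "c1", start = 10000, end = 30000),
                   class = c("intergenic_regions", "data.frame"))
  m <- profile_intergenic_regions(const, reg)
  expect_equal(dim(m), c(1, 100))
  expect_true(all(m == 2.5))

  set.seed(22)
  v <- flat_track(g, 0)
  v$c1 <- rpois(60000, 2)
  m2 <- profile_intergenic_regions(v, reg)
  # equal 200-bp bins: mean of bin means equals the region mean
  expect_equal(mean(m2[1, ]), mean(v$c1[10001:30000]), tolerance = 1e-12)
  expect_equal(unname(m2[1, ]), oracle_bin_means(v$c1, 10000, 30000, 100),
               tolerance = 1e-12)
})

test_that("strand reflection leaves profiles unchanged", {
  # gene lengths divisible by the bin count make the fractional
  # partition exactly reflection-symmetric
  glen <- 12000
  g <- genome(c(c1 = 80000))
  set.seed(23)
  v <- runif(80000)
  fwd <- flat_track(g, 0); fwd$c1 <- v
  rev_tr <- flat_track(g, 0); rev_tr$c1 <- rev(v)
  ann_f <- annotation("g1", "c1", "+", 30000, 30000 + glen, g)
  ann_r <- annotation("g1", "c1", "-", 80000 - 30000 - glen,
                      80000 - 30000, g)
  expect_equal(profile_gene(fwd, ann_f[1, ]),
               profile_gene(rev_tr, ann_r[1, ]), tolerance = 1e-12)
})

test_that("class ratio curves behave as planted", {
  g <- genome(c(c1 = 2e5))
  ann <- annotation(c("g1", "g2", "g3"), rep("c1", 3), rep("+", 3),
                    c(30000, 90000, 150000),
                    c(40000, 100000, 160000), g)
  t1 <- flat_track(g, 2)
  mA <- profile_genes(t1, ann)
  curves <- class_ratio_profile(mA, mA,
                                c(g1 = "up", g2 = "up", g3 = "down"))
  expect_true(all(abs(curves$up - 1) < 1e-12))
  t2 <- flat_track(g, 4)
  mA2 <- profile_genes(t2, ann)
  curves2 <- class_ratio_profile(mA2, mA, c(g1 = "up", g2 = "up",
                                            g3 = "down"),
                                 pseudocount = 0)
  expect_true(all(abs(curves2$up - 2) < 1e-12))

  # planted A-only enrichment restricted to the upstream flank
  tUp <- flat_track(g, 2)
  for (s in c(30000, 90000)) # g1, g2 upstream flanks
    tUp$c1[(s - 10000):(s - 1) + 1] <- 8
  mUp <- profile_genes(tUp, ann)
  cu <- class_ratio_profile(mUp, mA, c(g1 = "up", g2 = "up",
                                       g3 = "down"))
  expect_true(all(cu$up[1:50] > 1.5))
  expect_true(all(abs(cu$up[51:150] - 1) < 0.01))
  expect_true(all(abs(cu$down - 1) < 1e-12))

  expect_warning(
    class_ratio_profile(mA, mA, c(g1 = "up", g2 = "up", g3 = "down",
                                  g9 = "ghost")),
    NA)
})

test_that("expression ranking orders rows deterministically", {
  m <- structure(matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), NULL)),
                 layout = list(kind = "intergenic", bins = 3),
                 class = c("profile_matrix", "matrix", "array"))
  expect_equal(rownames(expression_ranked_matrix(m, c(g1 = 5, g2 = 9))),
               c("g2", "g1"))
  expect_equal(rownames(expression_ranked_matrix(m, c(g1 = 5, g2 = 5))),
               c("g1", "g2"))
  expect_error(expression_ranked_matrix(m, c(g1 = 5)), "g2")

  # random permutation then rank equals an independent sorting oracle
  set.seed(24)
  ids <- paste0("g", sample(100))
  mm <- matrix(rnorm(300), nrow = 100, dimnames = list(ids, NULL))
  mm <- structure(mm, layout = list(kind = "intergenic", bins = 3),
                  class = c("profile_matrix", "matrix", "array"))
  e <- setNames(sample(1:10, 100, replace = TRUE), ids)
  ranked <- expression_ranked_matrix(mm, e)
  oracle_order <- ids[order(-e[ids], ids)]
  expect_equal(rownames(ranked), oracle_order)
})
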