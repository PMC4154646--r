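mk_mat <- function(values, n_rep = 6) {
  expression_matrix(values, rep(c("A", "B"), each = n_rep))
}

test_that("probe filtering requires detection in both conditions", {
  v <- rbind(p1 = c(rep(5, 6), rep(5, 6)),            # 6/6 in both
             p2 = c(rep(-1, 3), rep(5, 3), rep(5, 6)), # 3 positive in A
             p3 = c(rep(5, 6), rep(-1, 6)))            # 0 positive in B
  kept <- filter_probes(mk_mat(v))
  expect_equal(kept, "p1")

  expect_error(filter_probes(mk_mat(v[, c(1:2, 7:8)], n_rep = 2)),
               "min_positive")

  # planted pass/fail structure recovered exactly
  set.seed(31)
  n <- 500
  base <- matrix(rnorm(n * 12, 5, 1), n)
  pass <- rbinom(n, 1, 0.5) == 1
  base[!pass, 1:3] <- -abs(base[!pass, 1:3])  # only 3 can be positive in A
  rownames(base) <- paste0("p", seq_len(n))
  kept <- filter_probes(mk_mat(base))
  # brute-force recount
  manual <- apply(base, 1, function(r)
    sum(r[1:6] > 0) >= 4 && sum(r[7:12] > 0) >= 4)
  expect_setequal(kept, rownames(base)[manual])
})

test_that("probe-to-gene collapse keeps the highest-mean coding probe", {
  v <- rbind(p1 = rep(5.1, 12), p2 = rep(7.3, 12), p3 = rep(2, 12),
             p4 = rep(9, 12))
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("g1", "g1", "g2", "g3"),
                    protein_coding = c(TRUE, TRUE, TRUE, FALSE))
  gm <- collapse_probes_to_genes(mk_mat(v), map)
  expect_setequal(rownames(gm), c("g1", "g2"))
  expect_equal(unname(unclass(gm)["g1", 1]), 7.3)
  # non-coding probes absent; unmapped-after-filter genes reported
  map2 <- rbind(map, data.frame(probe_id = "p9", gene_id = "g9",
                                protein_coding = TRUE))
  gm2 <- collapse_probes_to_genes(mk_mat(v), map2)
  expect_equal(attr(gm2, "dropped_genes"), "g9")
})

test_that("classification follows the not-expressed and p-value rules", {
  v <- rbind(low = rep(2.5, 12),
             same = rep(c(4, 5, 6, 4, 5, 6), 2),
             near = c(1:6, 2:7),
             up = c(rep(8, 6), rep(4, 6)) + rep(c(0.1, -0.1), 6))
  cls <- classify_genes(mk_mat(v))
  expect_equal(cls$class, c("not_expressed", "no_change", "no_change",
                            "up"))
  expect_true(is.na(cls$t[1]))
  expect_equal(cls$t[2], 0)

  # [1..6] vs [2..7]: oracle Welch gives t = -0.926, p ~ 0.38
  orc <- oracle_welch(1:6, 2:7)
  expect_equal(cls$t[3], orc$t, tolerance = 1e-12)
  expect_equal(cls$p[3], orc$p, tolerance = 1e-12)
  expect_equal(round(orc$t, 3), -0.926)

  # a matrix smuggling in a non-finite value is rejected naming the gene
  raw <- rbind(bad = c(NA, rep(1, 11)), ok = rep(5, 12))
  broken <- structure(raw, condition = rep(c("A", "B"), each = 6),
                      class = c("expression_matrix", "matrix", "array"))
  expect_error(classify_genes(broken), "bad")
})

test_that("vectorized t statistics match the reference implementation", {
  set.seed(32)
  for (ve in c(FALSE, TRUE)) {
    v <- matrix(rnorm(50 * 12, 5, 1), 50)
    v[1:10, 1:6] <- v[1:10, 1:6] + 2
    rownames(v) <- paste0("g", 1:50)
    cls <- classify_genes(mk_mat(v), var_equal = ve)
    for (i in c(1, 7, 25, 50)) {
      tt <- t.test(v[i, 1:6], v[i, 7:12], var.equal = ve)
      expect_equal(cls$t[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(cls$p[i], tt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("relabeling conditions swaps up and down exactly", {
  set.seed(33)
  v <- matrix(rnorm(300 * 12, 5, 1), 300)
  v[1:30, 1:6] <- v[1:30, 1:6] + 2
  v[31:60, 7:12] <- v[31:60, 7:12] + 2
  v[61:70, ] <- matrix(rnorm(10 * 12, 1, 0.3), 10)
  rownames(v) <- paste0("g", 1:300)
  a <- classify_genes(mk_mat(v))
  b <- classify_genes(mk_mat(v[, c(7:12, 1:6)]))
  expect_equal(a$class == "up", b$class == "down")
  expect_equal(a$class == "down", b$class == "up")
  expect_equal(a$class == "not_expressed", b$class == "not_expressed")
  # classes always partition the universe
  expect_true(all(a$class %in% c("up", "down", "no_change",
                                 "not_expressed")))
  expect_equal(nrow(a), 300)
})

test_that("null data yield the nominal changed fraction", {
  set.seed(34)
  n <- 5000
  v <- matrix(rnorm(n * 12, 6, 0.5), n)
  rownames(v) <- paste0("g", seq_len(n))
  cls <- classify_genes(mk_mat(v))
  frac <- mean(cls$class %in% c("up", "down"))
  se <- sqrt(0.002 * 0.998 / n)
  expect_lt(abs(frac - 0.002), 3 * se)
})

test_that("planted effects are detected at the noncentral-t prediction", {
  set.seed(35)
  n <- 2000
  v <- cbind(matrix(rnorm(n * 6, 8, 0.5), n),
             matrix(rnorm(n * 6, 6, 0.5), n))
  rownames(v) <- paste0("g", seq_len(n))
  cls <- classify_genes(mk_mat(v))
  sens <- mean(cls$class == "up")
  ncp <- 2 / (0.5 * sqrt(2 / 6))
  crit <- qt(1 - 0.001, df = 10)
  power <- 1 - pt(crit, 10, ncp) + pt(-crit, 10, ncp)
  expect_lt(abs(sens - power), 0.05)
})
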