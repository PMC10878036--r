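test_that("relative abundance normalises every sample", {
  ft <- tiny_counts(matrix(c(10L, 30L, 0L, 0L), 2, 2,
                           dimnames = list(c("a", "b"), c("s1", "s2"))))
  pr <- relative_abundance(ft)
  expect_equal(pr$values[, "s1"], c(a = 0.25, b = 0.75))
  expect_equal(pr$values[, "s2"], c(a = 0, b = 0))   # all-zero stays zero
  one <- tiny_counts(matrix(7L, 1, 1, dimnames = list("a", "s")))
  expect_equal(relative_abundance(one)$values[1, 1], 1)
  set.seed(2)
  for (i in 1:100) {
    ft <- random_counts(nf = sample(2:10, 1), ns = sample(1:5, 1))
    cs <- colSums(relative_abundance(ft)$values)
    nz <- colSums(ft$values) > 0
    expect_equal(unname(cs[nz]), rep(1, sum(nz)), tolerance = 1e-12)
  }
})

test_that("TPM follows the per-kilobase rate normalisation", {
  one <- tiny_counts(matrix(37L, 1, 1, dimnames = list("a", "s")))
  expect_equal(compute_tpm(one, c(a = 5000L))$values[1, 1], 1e6)

  two <- tiny_counts(matrix(c(10L, 10L), 2, 1,
                            dimnames = list(c("a", "b"), "s")))
  expect_equal(compute_tpm(two, c(a = 2000L, b = 2000L))$values[, 1],
               c(a = 5e5, b = 5e5))

  # rates 100/10 kb = 10 and 100/20 kb = 5 -> 2/3 and 1/3 of a million
  cc <- tiny_counts(matrix(c(100L, 100L), 2, 1,
                           dimnames = list(c("a", "b"), "s")))
  tpm <- compute_tpm(cc, c(a = 10000L, b = 20000L))
  expect_equal(tpm$values[, 1], c(a = 2e6 / 3, b = 1e6 / 3), tolerance = 1e-9)

  expect_error(compute_tpm(cc, c(a = 10000L)), "missing length")
})

test_that("TPM is invariant to global scaling of a sample's counts", {
  set.seed(21)
  ft <- random_counts(nf = 8, ns = 1, max_count = 30)
  len <- stats::setNames(sample(1000:9000, 8), rownames(ft$values))
  t1 <- compute_tpm(ft, len)
  ft2 <- feature_table(ft$values * 7L, "counts")
  expect_equal(compute_tpm(ft2, len)$values, t1$values, tolerance = 1e-12)
})

test_that("coverage gate zeroes under-covered cells and nothing else", {
  v <- matrix(c(5000, 2000, 100, 900), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  v <- sweep(v, 2, colSums(v), "/") * 1e6
  tpm <- feature_table(v, "tpm")
  cov <- matrix(c(0.5, 0.8, 1, 0.79), 2, 2, dimnames = dimnames(v))
  g <- gate_tpm(tpm, cov, 0.8)
  expect_equal(g$values["a", "s1"], 0)            # below the gate
  expect_equal(g$values["b", "s1"], v["b", "s1"]) # exactly 0.8 passes
  expect_equal(g$values["a", "s2"], v["a", "s2"])
  expect_equal(g$values["b", "s2"], 0)
  # full coverage leaves the table untouched
  id <- gate_tpm(tpm, matrix(1, 2, 2, dimnames = dimnames(v)), 0.8)
  expect_equal(id$values, v)
  # idempotence and non-increase on random tables
  set.seed(31)
  for (i in 1:25) {
    ft <- random_counts(5, 3, 500)
    len <- stats::setNames(sample(1000:9000, 5), rownames(ft$values))
    tpm <- compute_tpm(ft, len)
    cov <- matrix(runif(15), 5, 3, dimnames = dimnames(tpm$values))
    g1 <- gate_tpm(tpm, cov)
    expect_true(all(g1$values <= tpm$values))
    expect_equal(gate_tpm(g1, cov)$values, g1$values)
  }
  bad <- matrix(1, 3, 3)
  expect_error(gate_tpm(tpm, bad), "identical feature/sample registries")
})

test_that("rarefaction subsamples to a common depth, reproducibly", {
  ft <- tiny_counts(matrix(c(4L, 6L, 10L, 30L), 2, 2,
                           dimnames = list(c("a", "b"), c("s1", "s2"))))
  r <- rarefy(ft, seed = 5)
  expect_equal(unname(colSums(r$values)), c(10, 10))
  expect_equal(r$values[, "s1"], c(a = 4, b = 6))  # already at target
  expect_identical(rarefy(ft, seed = 5)$values, r$values)
  expect_false(identical(rarefy(ft, seed = 6)$values, r$values) &&
                 identical(rarefy(ft, seed = 7)$values, r$values))
  expect_error(rarefy(ft, seed = 1, target = 11), "s1")
})

test_that("rarefied proportions are unbiased (hypergeometric expectation)", {
  counts <- c(a = 40L, b = 25L, c = 30L, d = 5L)
  ft <- feature_table(matrix(counts, 4, 1,
                             dimnames = list(names(counts), "s1")),
                      "counts")
  target <- 50L
  draws <- vapply(seq_len(1000), function(i)
    rarefy(ft, seed = 3000 + i, target = target)$values[, 1] / target,
    numeric(4))
  p <- counts / sum(counts)
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - p) <= 3 * se + 1e-12))
})
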