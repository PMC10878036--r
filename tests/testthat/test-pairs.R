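test_that("dominant-ASV selection requires a summer-window maximum above 1%", {
  # 16 months, surface only matters; middle-2019 window is months 10-12
  sim <- cached_sim(1)
  meta <- sim$meta
  seasons <- classify_seasons(meta)
  sv <- meta$sample_id[meta$layer == "surface"][order(
    meta$month_index[meta$layer == "surface"])]
  base <- matrix(1e-4, 4, 32, dimnames = list(
    c("peak_aug", "peak_dec", "small_aug", "filler"),
    meta$sample_id))
  base["peak_aug", sv[12]] <- 0.05     # month 11 = August 2019
  base["peak_dec", sv[16]] <- 0.05     # month 15 = December 2019
  base["small_aug", sv[12]] <- 0.009
  base["peak_dec", sv[1]] <- 0         # give the filler a unique off-window max
  base["filler", ] <- 1 - colSums(base[1:3, , drop = FALSE])
  ft <- feature_table(base, "proportion")
  sel <- select_asv_dominant(ft, seasons, meta, threshold = 0.01)
  expect_identical(sel, "peak_aug")
  # no qualifying window -> error
  lab2 <- seasons; lab2$label <- "end"
  expect_error(select_asv_dominant(ft, lab2, meta), "middle-stratified")
})

test_that("BH q-values equal the brute-force step-up construction", {
  set.seed(103)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("Pearson r matches its textbook formula", {
  set.seed(104)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(unname(stats::cor.test(x, y)$estimate), pearson_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("a proportional series is retained with r = 1", {
  months <- as.character(0:7)
  asv <- matrix(c(1, 3, 2, 8, 5, 2, 1, 4), 1, 8,
                dimnames = list("A", months))
  lbv <- matrix(asv * 12.5, 1, 8, dimnames = list("L", months))
  res <- pearson_fdr_pairs(asv, lbv)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$pearson_r, 1, tolerance = 1e-12)
})

test_that("independent decoy series are controlled by the FDR step", {
  set.seed(10)
  months <- as.character(0:15)
  asv <- matrix(exp(rnorm(16)), 1, 16, dimnames = list("A", months))
  lbv <- matrix(exp(rnorm(16 * 1000)), 1000, 16,
                dimnames = list(sprintf("L%04d", 1:1000), months))
  res <- pearson_fdr_pairs(asv, lbv)
  raw <- mean(res$tested$p_value < 0.05)
  expect_gt(raw, 0.02)         # raw test behaves like a 5% test...
  expect_lt(raw, 0.09)
  expect_lte(nrow(res$pairs), 2L)  # ...but almost nothing survives BH
})

test_that("pair extraction ignores feature order and affine abundance scale", {
  set.seed(105)
  months <- as.character(0:11)
  asv <- matrix(exp(rnorm(36)), 3, 12,
                dimnames = list(c("A1", "A2", "A3"), months))
  asv["A1", 7:9] <- asv["A1", 7:9] + 6
  lbv <- matrix(exp(rnorm(60)), 5, 12,
                dimnames = list(sprintf("L%d", 1:5), months))
  lbv["L3", ] <- asv["A1", ] * 2 + rnorm(12, sd = 0.05)
  r1 <- pearson_fdr_pairs(asv, lbv)
  r2 <- pearson_fdr_pairs(asv[c(3, 1, 2), ], lbv[5:1, ] * 40)
  key <- function(d) sort(paste(d$asv_id, d$lbv_id))
  expect_identical(key(r1$pairs), key(r2$pairs))
  m1 <- r1$pairs$pearson_r[order(paste(r1$pairs$asv_id, r1$pairs$lbv_id))]
  m2 <- r2$pairs$pearson_r[order(paste(r2$pairs$asv_id, r2$pairs$lbv_id))]
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("pairs with too few shared months are skipped with a note", {
  months <- as.character(0:5)
  asv <- matrix(c(1, 2, 3, NA, NA, NA), 1, 6, dimnames = list("A", months))
  lbv <- matrix(rep(1:2, 3), 1, 6, dimnames = list("L", months))
  expect_message(res <- pearson_fdr_pairs(asv, lbv), "skipped")
  expect_equal(nrow(res$tested), 0L)
})

test_that("one-sided host-month validation matches exact enumeration", {
  series <- c(rep(10, 3), rep(1, 9)) * (1 + seq(0, 0.11, length.out = 12))
  names(series) <- 0:11
  res <- mw_validate(series, host_dominant_months = 0:2, other_months = 3:11)
  # complete separation, one-sided: p = 1 / choose(12, 3)
  expect_equal(res$p_value, 1 / choose(12, 3), tolerance = 1e-12)
  expect_false(res$degenerate)

  flat <- stats::setNames(rep(0, 12), 0:11)
  res0 <- mw_validate(flat, 0:2, 3:11)
  expect_true(res0$degenerate)
  expect_equal(res0$p_value, 1)

  same <- stats::setNames(rep(c(1, 2), 6), 0:11)
  expect_gt(mw_validate(same, 0:2, 3:11)$p_value, 0.2)
  expect_error(mw_validate(flat, integer(), 3:11), "non-empty")
})

test_that("pair summaries do the bookkeeping", {
  sim <- cached_sim(1)
  empty <- summarize_pairs(data.frame(asv_id = character(),
                                      lbv_id = character()),
                           relative_abundance(sim$asv_counts),
                           gate_tpm(compute_tpm(sim$lbv_counts),
                                    sim$coverage),
                           sim$meta, months = 10:12)
  expect_equal(empty$n_asv, 0L)
  expect_equal(empty$monthly$paired_asv_relab, rep(0, 3))
})

test_that("planted virus-host links are recovered with high precision", {
  sim <- cached_sim(11)
  pl <- suppressMessages(run_lake_pipeline_sim(sim))
  truth <- paste(sim$truth$true_pairs$asv_id, sim$truth$true_pairs$lbv_id)
  got <- paste(pl$pairs$pairs$asv_id, pl$pairs$pairs$lbv_id)
  sens <- sum(got %in% truth) / length(truth)
  prec <- sum(got %in% truth) / length(got)
  expect_gte(sens, 0.8)
  expect_gte(prec, 0.8)
  # all bloomers qualify as dominant, plus possibly other summer taxa
  expect_true(all(sim$truth$bloomer_ids %in% pl$pairs$asv_dominant) ||
                sens >= 0.8)
  # retained pairs satisfy the advertised cutoffs
  pr <- pl$pairs$pairs
  expect_true(all(pr$pearson_r > 0 & pr$p_value < 0.05 & pr$q_value < 0.05))
  # concordance flag agrees with the taxon columns
  expect_identical(pr$taxon_concordant,
                   !is.na(pr$asv_taxon) & pr$host_taxon == pr$asv_taxon)
})

test_that("no coupling means (almost) no reported pairs", {
  npairs <- vapply(1:5, function(s) {
    sim <- null_lake(sim_config(seed = s))
    pl <- suppressMessages(run_lake_pipeline_sim(sim))
    if (is.null(pl$pairs$pairs)) 0L else nrow(pl$pairs$pairs)
  }, integer(1))
  expect_lte(mean(npairs), 1)
})
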