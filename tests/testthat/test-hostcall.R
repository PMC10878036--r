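ev_row <- function(lbv_id = "LBV_1", method, taxon = "Actinobacteria",
                   sg = NA, idp = NA, aln = NA, ev = NA, gf = NA, mk = NA) {
  data.frame(lbv_id = lbv_id, method = method, taxon = taxon,
             sg_score = sg, identity_pct = idp,
             aln_len_bp = as.integer(aln), evalue = ev,
             gene_fraction = gf, marker = mk)
}

test_that("evidence validation applies each method's strict thresholds", {
  expect_true(validate_evidence(ev_row(method = "i", sg = 0.16)))
  expect_false(validate_evidence(ev_row(method = "i", sg = 0.15)))
  expect_true(validate_evidence(
    ev_row(method = "iv", idp = 98, aln = 30, ev = 1e-6)))
  expect_false(validate_evidence(
    ev_row(method = "iv", idp = 97, aln = 30, ev = 1e-6)))
  expect_false(validate_evidence(
    ev_row(method = "iv", idp = 98, aln = 29, ev = 1e-6)))
  expect_false(validate_evidence(
    ev_row(method = "v", idp = 98, aln = 30, ev = 1e-5)))
  expect_false(validate_evidence(ev_row(method = "vi", gf = 0.80)))
  expect_true(validate_evidence(ev_row(method = "vi", gf = 0.801)))
  expect_true(validate_evidence(ev_row(method = "iii", idp = 100)))
  expect_false(validate_evidence(ev_row(method = "iii", idp = 99.9)))
  # marker gene must agree with the taxon it indicates
  expect_true(validate_evidence(
    ev_row(method = "ii", taxon = "Actinobacteria", mk = "whiB")))
  expect_false(validate_evidence(
    ev_row(method = "ii", taxon = "Cyanobacteria", mk = "whiB")))
  expect_true(validate_evidence(
    ev_row(method = "ii", taxon = "Cyanobacteria", mk = "photosystem")))
  expect_error(validate_evidence(ev_row(method = "i")), "sg_score")
  expect_error(validate_evidence(ev_row(method = "iv", idp = 98, ev = 1e-6)),
               "aln_len_bp")
})

test_that("host assignment follows method priority", {
  ev <- rbind(ev_row(method = "iii", taxon = "Cyanobacteria", idp = 100),
              ev_row(method = "v", taxon = "Actinobacteria",
                     idp = 98, aln = 40, ev = 1e-8))
  out <- assign_host(ev)
  expect_equal(out$taxon, "Cyanobacteria")
  expect_equal(out$winning_method, "iii")
  single <- assign_host(ev_row(method = "vi", taxon = "Chloroflexi", gf = 0.9))
  expect_equal(single$taxon, "Chloroflexi")
  expect_equal(single$n_supporting, 1L)
})

test_that("within-method conflicts resolve by majority, score, then ambiguity", {
  # equal-score tie: unassigned and flagged
  tie <- rbind(ev_row(method = "iii", taxon = "Cyanobacteria", idp = 100),
               ev_row(method = "iii", taxon = "Actinobacteria", idp = 100))
  out <- assign_host(tie)
  expect_true(is.na(out$taxon))
  expect_true(out$ambiguous)
  # majority wins
  maj <- rbind(tie, ev_row(method = "iii", taxon = "Cyanobacteria", idp = 100))
  expect_equal(assign_host(maj)$taxon, "Cyanobacteria")
  expect_equal(assign_host(maj)$n_supporting, 2L)
  # score breaks a 1-1 tie for method i
  sc <- rbind(ev_row(method = "i", taxon = "A", sg = 0.3),
              ev_row(method = "i", taxon = "B", sg = 0.6))
  expect_equal(assign_host(sc)$taxon, "B")
})

test_that("assignment is order-invariant and stable under weaker evidence", {
  ev <- rbind(ev_row(method = "iv", taxon = "Bacteroidetes",
                     idp = 99, aln = 35, ev = 1e-7),
              ev_row(method = "vi", taxon = "Chloroflexi", gf = 0.95),
              ev_row(method = "i", taxon = "Verrucomicrobia", sg = 0.4))
  base <- assign_host(ev)
  set.seed(9)
  for (i in 1:10)
    expect_equal(assign_host(ev[sample(nrow(ev)), ]), base)
  # an extra lower-priority record cannot change the call
  more <- rbind(ev, ev_row(method = "vi", taxon = "Planctomycetes", gf = 0.99))
  expect_equal(assign_host(more)$taxon, base$taxon)
  # all-invalid and empty evidence leave the contig unassigned, not an error
  expect_true(is.na(assign_host(ev_row(method = "i", sg = 0.05))$taxon))
  expect_equal(assign_host(empty_evidence())$n_supporting, 0L)
})

test_that("planted hosts are recovered from simulated evidence", {
  sim <- cached_sim(1)
  asg <- assign_hosts(sim$evidence)
  truth <- sim$truth$true_hosts
  hit <- asg$taxon[match(names(truth), asg$lbv_id)]
  expect_gte(mean(hit == truth, na.rm = TRUE), 0.9)
  expect_true(all(!is.na(hit)))
})

test_that("host summary reports counts and TPM fractions", {
  v <- matrix(c(600, 400, 0, 0), 2, 2,
              dimnames = list(c("L1", "L2"), c("s1", "s2")))
  tpm <- feature_table(v / pmax(colSums(v), 1)[col(v)] * 1e6, "tpm",
                       gated = TRUE)
  none <- host_summary(assign_hosts(empty_evidence()), tpm)
  expect_equal(unname(none$assigned_tpm_fraction), c(0, 0))
  both <- assign_hosts(rbind(
    ev_row("L1", method = "i", taxon = "A", sg = 0.5),
    ev_row("L2", method = "i", taxon = "A", sg = 0.5)))
  hs <- host_summary(both, tpm)
  expect_equal(unname(hs$assigned_tpm_fraction), c(1, 0))  # empty sample: 0
  expect_equal(unname(hs$taxon_counts["A"]), 2L)
})
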