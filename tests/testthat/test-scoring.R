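# Rescoring: DiffIRScore, DDPScore, mixed score, and target-decoy FDR.

test_that("DiffIRScore matches its worked values and is symmetric", {
  expect_equal(diff_ir_score(1.2, 1.2), 2)
  expect_equal(diff_ir_score(0, 0.5), 1)
  expect_equal(diff_ir_score(1, 2.5), 0.5)
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(diff_ir_score(a, b), diff_ir_score(b, a))
  expect_true(all(diff_ir_score(a, b) > 0 & diff_ir_score(a, b) <= 2))
  # strictly decreasing in |difference|
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(diff_ir_score(d, 0)) < 0))
  expect_error(diff_ir_score(NA_real_, 1), "non-finite")
  expect_error(diff_ir_score(1, Inf), "non-finite")
})

test_that("DDPScore is 2 on a perfect match and 0 on a disjoint spectrum", {
  amz <- c(200.01, 300.02, 400.03)
  bmz <- c(250.01, 350.02)
  sp <- spectrum(c(amz, bmz), rep(1, 5), scan_id = "perfect")
  expect_equal(ddp_score(amz, bmz, sp), 2)
  far <- spectrum(c(900, 1000), c(5, 5), scan_id = "far")
  expect_equal(ddp_score(amz, bmz, far), 0)
})

test_that("shared bins are excluded from both sides", {
  amz <- c(200.005, 500.0)
  bmz <- c(200.009, 700.0)     # first bin shared with alpha at 0.02 Th
  sp <- spectrum(c(200.007, 500.0, 700.0), c(100, 1, 1), scan_id = "sh")
  # with the shared bin removed each side reduces to one exact match
  expect_equal(ddp_score(amz, bmz, sp, bin_width = 0.02), 2)
  # the shared peak's large intensity must not contribute
  sp2 <- spectrum(c(200.007), c(1000), scan_id = "sh2")
  expect_equal(ddp_score(amz, bmz, sp2, bin_width = 0.02), 0)
})

test_that("DDPScore equals the brute-force oracle on random toy spectra", {
  set.seed(17)
  for (rep in 1:200) {
    na <- sample(2:6, 1L); nb <- sample(2:6, 1L)
    amz <- runif(na, 100, 1000)
    bmz <- c(runif(nb - 1L, 100, 1000), amz[1L] + runif(1, -0.01, 0.01))
    np <- sample(3:10, 1L)
    smz <- c(sample(c(amz, bmz), 3L), runif(np - 3L, 100, 1000))
    sint <- runif(np, 1, 100)
    width <- sample(c(0.02, 0.5, 1.0), 1L)
    sp <- spectrum(smz, sint, scan_id = "toy")
    expect_equal(ddp_score(amz, bmz, sp, bin_width = width),
                 oracle_ddp(amz, bmz, sp$mz, sp$intensity, width),
                 tolerance = 1e-9)
  }
})

test_that("DDPScore is invariant to uniform intensity scaling and bounded", {
  set.seed(19)
  for (rep in 1:20) {
    amz <- runif(5, 100, 1000); bmz <- runif(4, 100, 1000)
    smz <- c(sample(amz, 2L), sample(bmz, 2L), runif(6, 100, 1000))
    sint <- runif(10, 1, 50)
    s1 <- ddp_score(amz, bmz, spectrum(smz, sint, scan_id = "a"))
    s2 <- ddp_score(amz, bmz, spectrum(smz, sint * 137.5, scan_id = "b"))
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_gte(s1, 0); expect_lte(s1, 2)
  }
})

test_that("mixed score combines its components linearly", {
  expect_equal(mixed_score(0, 1), 0.02)
  expect_equal(mixed_score(1.0, 2.0), 1.04)
  expect_equal(mixed_score(0.7, 0), 0.7)
  # monotone in each argument
  expect_true(all(diff(mixed_score(seq(0, 2, 0.1), 1)) > 0))
  expect_true(all(diff(mixed_score(1, seq(0, 2, 0.1))) > 0))
  expect_equal(mixed_score(1, 1, gamma = 0.5), 1.5)
})

test_that("fraction better than random applies the strict-tie rule", {
  measured <- c(1, 2, 3)
  expect_equal(fraction_better_than_random(measured, measured,
                                           measured + 0.5), 1)
  expect_equal(fraction_better_than_random(measured, measured + 0.2,
                                           measured + 0.2), 0)
  # per-CSM |error|: model (0, 0.2, 0.9) vs random (0.5, 0.1, 0.5)
  expect_equal(fraction_better_than_random(measured, c(1, 2.2, 3.9),
                                           c(1.5, 2.1, 3.5)), 1 / 3)
})

test_that("q-values match a hand-ranked oracle on an interleaved list", {
  scores <- c(6, 5, 4, 3, 2, 1)
  decoy <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  res <- tda_fdr(scores, decoy, fdr_levels = 0.01)
  # ranks: t d t d t d -> FDR = 0, 1, 1/2, 1, 2/3, 1; q = cummin from below
  expect_equal(res$q_values, c(0, 1 / 2, 1 / 2, 2 / 3, 2 / 3, 1))
  expect_equal(res$summary$n_target_csms, 1L)

  perfect <- tda_fdr(c(10, 9, 8, 1, 0.5), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$q_values[1:3], c(0, 0, 0))
  expect_error(tda_fdr(1:3, rep(FALSE, 3)), "no decoy")
  expect_error(tda_fdr(1:3, rep(TRUE, 3)), "no target")
})

test_that("q-values are monotone in score and pair counts respect the pigeonhole", {
  set.seed(23)
  scores <- rnorm(300)
  decoy <- runif(300) < 0.4
  ids <- sample(sprintf("p%02d", 1:40), 300, replace = TRUE)
  res <- tda_fdr(scores, decoy, ids, fdr_levels = c(0.05, 0.2, 0.5))
  o <- order(scores, decreasing = TRUE)
  expect_true(all(diff(res$q_values[o]) >= -1e-12))
  expect_true(all(res$summary$n_unique_pairs <= res$summary$n_target_csms))
  expect_true(all(res$q_values >= 0 & res$q_values <= 1))
})

test_that("rescoring a small synthetic table adds scores and an FDR report", {
  cfg <- generative_config(seed = 41L, n_pairs = 10L, csms_per_pair = 4L)
  ds <- make_dataset(cfg, tempfile("rs"), decoy_fraction = 0.5)
  tab <- read_csm_table(ds$csm)
  spectra <- ds$spectra
  names(spectra) <- vapply(spectra, function(s) s$scan_id, "")
  for (i in seq_len(nrow(tab))) {
    pr <- xlratio:::pair_from_row(tab[i, ])
    tab$measured_ratio[i] <- extract_ratio(spectra[[tab$scan_id[i]]], pr,
                                           max_frag_charge = 1L)$measured_ratio
  }
  preds <- vapply(seq_len(nrow(tab)), function(i)
    true_ratio(xlratio:::pair_from_row(tab[i, ]), cfg), 0)
  rs <- rescore_csms(tab, preds, spectra)
  expect_true(all(c("diff_ir_score", "ddp_score", "mixed_score",
                    "q_value_ddp", "q_value_mixed") %in% names(rs$table)))
  expect_true(all(rs$table$ddp_score >= 0 & rs$table$ddp_score <= 2))
  expect_equal(nrow(rs$report), 4L)
  # true assignments should dominate reversed decoys on spectral similarity
  expect_gt(mean(rs$table$ddp_score[!rs$table$is_decoy]),
            mean(rs$table$ddp_score[rs$table$is_decoy]))
  expect_error(rescore_csms(tab, preds, spectra[-1]), "not found")
})
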