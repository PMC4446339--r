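test_that("simulated experiments are deterministic under a fixed seed", {
  fc <- matrix(c(8, 1), 1, 2,
               dimnames = list("gA", c("male_antenna", "female_antenna")))
  t1 <- simulation_truth(fc, seed = 99)
  t2 <- simulation_truth(fc, seed = 99)
  expect_identical(synth_qpcr(t1), synth_qpcr(t2))
  expect_identical(synth_fpkm(50, seed = 5), synth_fpkm(50, seed = 5))
  expect_identical(synth_obp("classic", seed = 5),
                   synth_obp("classic", seed = 5))
  # and the simulation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(synth_qpcr(t1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noise-free wells invert the quantification formulas exactly", {
  fc <- matrix(c(8, 1, 0.25, 2), 2, 2,
               dimnames = list(c("gA", "gB"),
                               c("male_antenna", "female_antenna")))
  truth <- simulation_truth(fc, ct_noise_sd = 0, seed = 17)
  wells <- synth_qpcr(truth)
  expect_equal(nrow(wells), (3 + 2) * 6 * 3)
  rel <- quantify_experiment(wells, truth$housekeeping_ids)
  for (i in seq_len(nrow(rel))) {
    expect_equal(rel$mean_rel_expr[i],
                 fc[rel$gene_id[i], rel$group[i]], tolerance = 1e-9)
  }
  # with sample efficiency at the primer maximum, Ct sits log_E(expr)
  # cycles from the true NF
  e_max <- apply(truth$efficiency, 1, max)
  hit <- which(wells$primer_id == "gA" &
               wells$sample_id == colnames(truth$efficiency)[
                 which.max(truth$efficiency["gA", ])])
  grp <- sub("\\.[^.]*$", "", wells$sample_id[hit[1]])
  expect_equal(wells$ct[hit[1]],
               truth$nf_true - log(fc["gA", grp], base = e_max[["gA"]]),
               tolerance = 1e-9)
})

test_that("transcripts below the detection horizon are censored", {
  fc <- matrix(1e-9, 1, 1, dimnames = list("gZ", list("ant")))
  truth <- simulation_truth(fc, ct_noise_sd = 0, seed = 3)
  wells <- synth_qpcr(truth)
  expect_true(all(is.na(wells$ct[wells$primer_id == "gZ"])))
  expect_true(all(!is.na(wells$ct[wells$primer_id != "gZ"])))
  rel <- quantify_experiment(wells, truth$housekeeping_ids)
  expect_true(rel$bld)
})

test_that("synthetic curves yield the programmed efficiency", {
  for (e_true in seq(1.7, 2.0, by = 0.05)) {
    est <- estimate_efficiency(synth_amp_curve(e_true))
    expect_false(est$censored)
    expect_equal(est$e, e_true, tolerance = 0.05)
  }
  # noisy curve still yields a finite estimate or an honest censoring flag
  noisy <- synth_amp_curve(1.9, noise_sd = 0.05, seed = 2)
  est <- estimate_efficiency(noisy)
  expect_true(est$censored || abs(est$e - 1.9) < 0.2)
})

test_that("FPKM generator centres unbiased genes and encodes programmed bias", {
  unbiased <- synth_fpkm(1000, bias_factors = 1, dispersion = 0.05,
                         seed = 21)
  lr <- sex_ratio(unbiased$fpkm_f_ant, unbiased$fpkm_m_ant)$log2_ratio
  expect_lt(abs(mean(lr)), 0.1)

  biased <- synth_fpkm(1000, bias_factors = 8, dispersion = 0.01,
                       base_meanlog = 6, seed = 22)
  lr8 <- log2((biased$fpkm_f_ant + 1) / (biased$fpkm_m_ant + 1))
  expect_lt(abs(mean(lr8) - 3), 0.5)

  zero <- synth_fpkm(5, base_meanlog = -Inf, base_sdlog = 0, seed = 1)
  expect_equal(zero$fpkm_f_ant, rep(0, 5))

  expect_error(synth_fpkm(5, bias_factors = 0), "positive")
  expect_error(synth_fpkm(5, dispersion = 0), "positive")
})

test_that("generator blueprints validate against their class", {
  expect_error(synth_obp("classic", gaps = c(1, 3, 30, 10, 8)),
               "incompatible")
  expect_error(synth_obp("classic", gaps = c(20, 3, 30)), "expected 5 gaps")
  expect_error(synth_obp("plus-C", extra_c = 1), "extra cysteines")
  expect_error(simulation_truth(matrix(-1, 1, 1)), "positive")
})

test_that("synthetic protein families hit their programmed identity", {
  fam <- synth_protein_family(n = 4, length = 300, target_identity = 0.8,
                              seed = 13)
  m <- identity_matrix(fam)
  expect_equal(attr(m, "mean_offdiagonal"), 80, tolerance = 0.05)
})
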