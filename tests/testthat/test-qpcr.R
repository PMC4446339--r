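test_that("Ct correction solves the efficiency-rescaling identity", {
  expect_equal(correct_ct(20, 2.0, 2.0), 20)
  expect_equal(correct_ct(20, 1.9, 2.0), 20 * log(1.9) / log(2),
               tolerance = 1e-12)
  expect_equal(correct_ct(0, 1.8, 2.0), 0)
  expect_error(correct_ct(20, 1.0, 2.0), "exceed 1")
  expect_error(correct_ct(20, 2.0, 0.9), "exceed 1")

  set.seed(101)
  for (i in 1:50) {
    ct <- runif(1, 5, 40)
    e <- runif(1, 1.5, 2.1)
    em <- runif(1, 1.5, 2.1)
    expect_equal(correct_ct(ct, e, e), ct)  # identity at equal efficiency
    # exponentiation consistency: e_max^ct_corrected == e^ct
    expect_equal(em^correct_ct(ct, e, em), e^ct,
                 tolerance = 1e-9)
  }
})

test_that("normalization factor is the mean of available housekeeping Cts", {
  expect_equal(normalization_factor(c(20, 22, 24)), 22)
  expect_equal(normalization_factor(c(22, 22, 22)), 22)
  expect_equal(normalization_factor(c(18.52, 21.30, 19.90)),
               mean(c(18.52, 21.30, 19.90)))
  expect_warning(nf <- normalization_factor(c(20, 22)), "2 of 3")
  expect_equal(nf, 21)
  expect_error(normalization_factor(numeric(0)), "no housekeeping signal")
  expect_error(normalization_factor(c(NA_real_, NA_real_)),
               "no housekeeping signal")
})

test_that("relative expression exponentiates the delta-Ct correctly", {
  expect_equal(relative_expression(2, 22, 22), 1)
  expect_equal(relative_expression(2, 25, 22), 0.125)
  expect_equal(relative_expression(2, 21, 22), 2)
  expect_error(relative_expression(1, 20, 22), "exceed 1")
  # strictly decreasing in corrected Ct, crossing 1 at the NF
  cts <- seq(15, 30, by = 0.5)
  vals <- relative_expression(1.9, cts, 22)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals[cts < 22] > 1) && all(vals[cts > 22] < 1))
})

test_that("Welch test matches the hand-evaluated formulas", {
  res <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674234614, tolerance = 1e-8)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  set.seed(202)
  for (i in 1:1000) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    got <- welch_test(a, b)
    want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    # symmetry: swapping groups negates t, keeps p
    swapped <- welch_test(b, a)
    expect_equal(swapped$t, -got$t, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
})

test_that("Welch p agrees with an exact permutation test at n = 3 + 3", {
  set.seed(303)
  for (i in 1:20) {
    a <- rnorm(3, mean = runif(1, 0, 2))
    b <- rnorm(3)
    p_w <- welch_test(a, b)$p
    p_perm <- permutation_oracle(a, b)
    # 20 distinct splits -> permutation granularity 0.1; agreement is coarse
    expect_lt(abs(p_w - p_perm), 0.25)
  }
})

test_that("Welch degenerate-variance conventions hold", {
  eps <- c(0, 1e-12, -1e-12)
  near <- welch_test(5 + eps, 5 + eps)
  expect_lt(abs(near$t), 1e-3)
  expect_gt(near$p, 0.99)

  same <- welch_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)
  expect_false(same$degenerate)

  apart <- welch_test(c(5, 5, 5), c(7, 7, 7))
  expect_equal(apart$p, 0)
  expect_true(apart$degenerate)
  expect_lt(apart$t, 0)

  expect_error(welch_test(1, c(1, 2)), "two values")
  expect_error(welch_test(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("efficiency estimator recovers the exponential growth rate", {
  # pure exponential phase: F(c) = 0.01 * E^c with negligible baseline
  for (e_true in c(1.85, 2.0)) {
    f <- 0.01 * e_true^(1:25)
    est <- estimate_efficiency(f, baseline_cycles = integer(0))
    expect_false(est$censored)
    expect_equal(est$e, e_true, tolerance = 0.01)
    # window slope agrees with an independent least-squares fit
    idx <- which(seq_along(f) >= est$window_start &
                 seq_along(f) <= est$window_end)
    expect_equal(est$e, lsq_efficiency_oracle(f, seq_along(f), idx),
                 tolerance = 1e-6)
  }
})

test_that("efficiency estimator censors curves without a log-linear phase", {
  expect_true(estimate_efficiency(rep(0.5, 45))$censored)
  expect_true(estimate_efficiency(seq(1, 2, length.out = 45))$censored)
  expect_error(estimate_efficiency(2^(1:10)), "15 cycles")
  expect_error(estimate_efficiency(c(-1, 2^(1:19))), "non-negative")
})

test_that("quantification aggregates replicates as specified", {
  # two samples per group, identical truth -> mean equals each replicate
  hk <- expand.grid(primer_id = c("actin", "tubulin", "ef1a"),
                    sample_id = c("ant.1", "ant.2", "ant.3"),
                    tech_rep = 1, stringsAsFactors = FALSE)
  hk$ct <- 22; hk$efficiency <- 2
  g <- data.frame(primer_id = "gX", sample_id = c("ant.1", "ant.2", "ant.3"),
                  tech_rep = 1, ct = 21, efficiency = 2)
  rel <- quantify_experiment(rbind(hk, g), c("actin", "tubulin", "ef1a"))
  expect_equal(rel$mean_rel_expr, 2)  # one cycle earlier = one doubling
  expect_equal(rel$n_reps_aggregated, 3)
  expect_false(rel$bld)

  # replicates {1.0, 2.0, 3.0} -> mean 2.0: Ct offsets log2(1), log2(2), log2(3)
  g2 <- data.frame(primer_id = "gY",
                   sample_id = c("ant.1", "ant.2", "ant.3"),
                   tech_rep = 1, ct = 22 - log2(c(1, 2, 3)), efficiency = 2)
  rel2 <- quantify_experiment(rbind(hk, g2), c("actin", "tubulin", "ef1a"))
  expect_equal(rel2$mean_rel_expr, 2, tolerance = 1e-12)
  expect_equal(sort(rel2$rep_values[[1]]), c(1, 2, 3), tolerance = 1e-12)
})

test_that("partially censored genes use the detected replicates", {
  hk <- expand.grid(primer_id = c("actin", "tubulin", "ef1a"),
                    sample_id = c("ant.1", "ant.2"), tech_rep = 1,
                    stringsAsFactors = FALSE)
  hk$ct <- 22; hk$efficiency <- 2
  g <- data.frame(primer_id = "gX", sample_id = c("ant.1", "ant.2"),
                  tech_rep = 1, ct = c(21, NA), efficiency = 2)
  rel <- quantify_experiment(rbind(hk, g), c("actin", "tubulin", "ef1a"))
  expect_equal(rel$mean_rel_expr, 2)
  expect_equal(rel$n_reps_aggregated, 1)
  expect_false(rel$bld)

  g$ct <- NA_real_
  rel2 <- quantify_experiment(rbind(hk, g), c("actin", "tubulin", "ef1a"))
  expect_true(rel2$bld)
  expect_true(is.na(rel2$mean_rel_expr))
})

test_that("technical replicate handling modes agree on noise-free wells", {
  fc <- matrix(c(4, 0.5), 1, 2,
               dimnames = list("gA", c("male_antenna", "female_antenna")))
  truth <- simulation_truth(fc, ct_noise_sd = 0, seed = 5)
  wells <- synth_qpcr(truth)
  r1 <- quantify_experiment(wells, truth$housekeeping_ids,
                            tech_rep_mode = "mean_ct")
  r2 <- quantify_experiment(wells, truth$housekeeping_ids,
                            tech_rep_mode = "separate")
  expect_equal(r1$mean_rel_expr, r2$mean_rel_expr, tolerance = 1e-12)
})

test_that("sex-bias calls report direction, significance and censoring", {
  build_rel <- function(m, f) {
    structure(data.frame(
      gene_id = "g", group = c("male_antenna", "female_antenna"),
      mean_rel_expr = c(mean(m), if (length(f)) mean(f) else NA_real_),
      n_reps_aggregated = c(length(m), length(f)),
      bld = c(FALSE, length(f) == 0),
      rep_values = I(list(m, f))),
      class = c("relative_expression_table", "data.frame"))
  }
  up <- call_sex_bias(build_rel(c(10, 11, 12), c(1, 1.1, 0.9)))
  expect_equal(up$direction, "male")
  expect_lt(up$p, 0.05)
  expect_equal(welch_oracle(c(10, 11, 12), c(1, 1.1, 0.9))$p, up$p,
               tolerance = 1e-9)

  flat <- call_sex_bias(build_rel(c(1, 2, 3), c(1.1, 2.1, 2.9)))
  expect_equal(flat$direction, "none")

  cens <- call_sex_bias(build_rel(c(10, 11, 12), numeric(0)))
  expect_equal(cens$direction, "undetermined")
  expect_true(is.na(cens$p))
})
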