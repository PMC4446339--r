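test_that("generator-built OBPs classify as their blueprint class", {
  classic <- synth_obp("classic", gaps = c(20, 3, 30, 10, 8), seed = 1)
  expect_equal(classify_obp(classic[[1]])$obp_class, "classic")

  # same backbone with skeleton cysteines 2 and 5 removed
  minus <- synth_obp("minus-C", gaps = c(23, 30, 18), seed = 1)
  expect_equal(classify_obp(minus[[1]])$obp_class, "minus-C")

  plus <- synth_obp("plus-C", gaps = c(20, 3, 30, 10, 8), extra_c = 2,
                    seed = 2)
  expect_equal(classify_obp(plus[[1]])$obp_class, "plus-C")
  expect_equal(obp_regex_oracle(plus[[1]]), "plus-C")
})

test_that("classification agrees with a regex oracle on generated inputs", {
  set.seed(7)
  classes <- sample(c("classic", "minus-C", "plus-C"), 300, replace = TRUE)
  for (i in seq_along(classes)) {
    s <- synth_obp(classes[i], seed = 1000 + i)[[1]]
    got <- classify_obp(s)$obp_class
    expect_equal(got, classes[i])
    expect_equal(got, obp_regex_oracle(s))
  }
})

test_that("classification is exclusive, exhaustive and reports coordinates", {
  s <- synth_obp("classic", gaps = c(20, 3, 30, 10, 8), seed = 3)[[1]]
  cl <- classify_obp(s)
  expect_true(cl$obp_class %in% c("classic", "minus-C", "plus-C",
                                  "unclassified"))
  # reported skeleton positions are cysteines, 1-based
  expect_true(all(strsplit(s, "")[[1]][cl$cysteine_positions] == "C"))
  expect_length(cl$cysteine_positions, 6)
  # signal peptide offset shifts reported coordinates
  padded <- paste0(strrep("M", 19), s)
  cl2 <- classify_obp(padded, signal_peptide_len = 19)
  expect_equal(cl2$obp_class, "classic")
  expect_equal(cl2$cysteine_positions, cl$cysteine_positions + 19)

  expect_equal(classify_obp("MKVLAC")$obp_class, "unclassified")
  expect_equal(classify_obp(strrep("A", 200))$obp_class, "unclassified")
  # wrong cysteine count: classic skeleton + 1 stray cysteine
  stray <- paste0(s, "AAAC")
  expect_equal(classify_obp(stray)$obp_class, "unclassified")
  expect_error(classify_obp("ACDZ"), "non-amino-acid")
})

test_that("PWE screening is restricted to the C-terminal window", {
  s <- synth_pr_clade(n = 1, n_with_motif = 1, length = 200, seed = 9)[[1]]
  hit <- detect_pwe(s)
  expect_true(hit$found)
  expect_equal(substring(s, hit$position, hit$position + 2), "PWE")
  expect_gt(hit$position, nchar(s) - 60)

  # motif only in the N-terminal half is invisible at window 60
  nterm <- paste0("AAPWE", strrep("L", 100))
  expect_false(detect_pwe(nterm, cterm_window = 60)$found)
  expect_true(detect_pwe(nterm, cterm_window = nchar(nterm))$found)

  # whole-sequence window is equivalent to plain substring search
  set.seed(11)
  for (i in 1:25) {
    x <- synth_pr_clade(n = 1, n_with_motif = i %% 2, length = 120,
                        seed = i)[[1]]
    expect_equal(detect_pwe(x, cterm_window = nchar(x))$found,
                 grepl("PWE", x, fixed = TRUE))
  }
})

test_that("pairwise identity behaves under global alignment", {
  expect_equal(pairwise_identity("MKVLIT", "MKVLIT"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIR"), 100 * 8 / 9,
               tolerance = 1e-9)
  a <- synth_protein_family(n = 2, length = 150, target_identity = 0.7,
                            seed = 4)
  expect_equal(pairwise_identity(a[[1]], a[[2]]),
               pairwise_identity(a[[2]], a[[1]]), tolerance = 1e-9)
  expect_error(pairwise_identity("ACDB", "ACD"), "non-amino-acid")
})

test_that("identity matrix is symmetric with unit diagonal", {
  fam <- synth_protein_family(n = 4, length = 200, target_identity = 0.61,
                              seed = 8)
  m <- identity_matrix(fam)
  expect_equal(unname(diag(m)), rep(100, 4))
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_equal(attr(m, "mean_offdiagonal"), mean(m[upper.tri(m)]))
  # programmed divergence recovered by the aligner
  expect_equal(attr(m, "mean_offdiagonal"), 61, tolerance = 0.08)
  expect_error(identity_matrix(fam[1]), "two sequences")
})
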