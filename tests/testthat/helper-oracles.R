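# Independent oracles used to cross-check package implementations. These
# stay deliberately naive: direct formula evaluation, enumeration, regex
# pattern matching -- never calls into the code paths they verify.

# Welch statistics straight from the textbook formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exact two-sided permutation test on the mean difference: enumerates every
# reassignment of the pooled values to groups of the original sizes.
permutation_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(diffs >= obs - 1e-12)
}

# Least-squares slope of log10(F) over a fixed cycle window.
lsq_efficiency_oracle <- function(fluorescence, cycles, window_idx,
                                  baseline = 0) {
  y <- log10(fluorescence[window_idx] - baseline)
  x <- cycles[window_idx]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  10^slope
}

# Brute-force OBP pattern oracle: builds an anchored regular expression for
# each class from the spacing config and tests the mature sequence against
# it, together with a plain cysteine count.
obp_regex_oracle <- function(residues, config = obp_spacing_config()) {
  n_c <- lengths(regmatches(residues, gregexpr("C", residues)))
  gap <- function(r) sprintf("[^C]{%d,%d}", r[1] - 1L, r[2] - 1L)
  skeleton <- function(ranges) {
    paste0("C", paste(vapply(ranges, gap, character(1)), collapse = "C"),
           "C")
  }
  classic_re <- paste0("^[^C]*", skeleton(config$gap_ranges), "[^C]*$")
  minus_re <- paste0("^[^C]*", skeleton(config$minus_ranges), "[^C]*$")
  # plus-C: classic skeleton somewhere (extra cysteines allowed around it),
  # proline within the window after its sixth cysteine
  plus_core <- skeleton(config$gap_ranges)
  if (grepl(classic_re, residues) && n_c == 6L) return("classic")
  if (grepl(minus_re, residues) && n_c == 4L) return("minus-C")
  if (n_c >= 6L + config$plus_c_min_extra) {
    m <- regexpr(plus_core, residues)
    if (m != -1L) {
      end <- as.integer(m) + attr(m, "match.length") - 1L
      window <- substring(residues, end + 1L,
                          min(end + config$proline_window, nchar(residues)))
      if (grepl("P", window)) return("plus-C")
    }
  }
  "unclassified"
}

# Tiny synthetic wells builder for hand-constructed quantification cases.
make_wells <- function(primer_id, sample_id, ct, efficiency, tech_rep = 1) {
  data.frame(primer_id = primer_id, sample_id = sample_id,
             tech_rep = tech_rep, ct = ct, efficiency = efficiency,
             stringsAsFactors = FALSE)
}
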