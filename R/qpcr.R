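#' Correct a Ct value to the reference efficiency scale
#'
#' Amplification efficiency varies between cDNA samples for the same primer
#' pair, so raw Ct values are not comparable across samples. Each Ct is
#' rescaled to the highest efficiency observed for that primer pair
#' (`e_max`) by solving `e_max^ct_corrected = e_sample^ct`, i.e.
#' `ct_corrected = ct * ln(e_sample) / ln(e_max)`. When the sample ran at
#' the maximum efficiency the Ct is returned unchanged.
#'
#' @param ct observed cycle threshold(s), >= 0.
#' @param e_sample amplification efficiency of this primer pair in this
#'   sample (per-cycle amplification factor, > 1; 2 is perfect doubling).
#' @param e_max highest efficiency of the primer pair across all samples
#'   (> 1).
#' @return corrected Ct value(s) on the `e_max` scale.
#' @examples
#' correct_ct(20, e_sample = 1.9, e_max = 2.0)  # 18.52...
#' @export
correct_ct <- function(ct, e_sample, e_max) {
  if (any(e_sample <= 1) || any(e_max <= 1)) {
    stop("amplification efficiencies must exceed 1", call. = FALSE)
  }
  if (any(ct < 0, na.rm = TRUE)) stop("ct must be >= 0", call. = FALSE)
  ct * (log(e_sample) / log(e_max))
}

#' Housekeeping normalization factor for one sample
#'
#' The normalization factor (NF) of a sample is the arithmetic mean of the
#' corrected Ct values of its housekeeping genes (actin, alpha-tubulin and
#' EF-1alpha in the reference design). A warning is recorded when fewer than
#' `expected` housekeeping genes contribute.
#'
#' @param corrected_hk_cts numeric vector of corrected housekeeping Cts
#'   (`NA` entries are dropped).
#' @param expected number of housekeeping genes the design calls for.
#' @return the NF, in cycles.
#' @export
normalization_factor <- function(corrected_hk_cts, expected = 3) {
  v <- corrected_hk_cts[!is.na(corrected_hk_cts)]
  if (length(v) == 0L) {
    stop("no housekeeping signal in sample", call. = FALSE)
  }
  if (length(v) < expected) {
    warning("normalization factor based on ", length(v), " of ", expected,
            " housekeeping genes", call. = FALSE)
  }
  mean(v)
}

#' Relative expression from a corrected Ct and normalization factor
#'
#' Expression relative to the housekeeping genes is `e_max^(nf -
#' ct_corrected)`: a transcript whose corrected Ct equals the NF is at
#' housekeeping level (1.0); each cycle earlier multiplies expression by
#' `e_max`. The statistic is strictly decreasing in `ct_corrected`.
#'
#' @inheritParams correct_ct
#' @param ct_corrected corrected Ct of the gene in this sample.
#' @param nf normalization factor of the sample (cycles).
#' @return fold change to reference genes (positive number).
#' @export
relative_expression <- function(e_max, ct_corrected, nf) {
  if (any(e_max <= 1)) stop("e_max must exceed 1", call. = FALSE)
  e_max^(nf - ct_corrected)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, as used for calling sex-biased expression between per-replicate
#' relative expression values. Degenerate inputs follow fixed conventions:
#' zero variance in both groups with equal means gives `p = 1`; zero
#' variance in both groups with unequal means gives the limiting `p = 0`,
#' flagged `degenerate`.
#'
#' @param a,b numeric vectors of at least two finite values each.
#' @return list with elements `t`, `df`, `p`, `degenerate`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_test needs at least two values per group", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("welch_test needs finite values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

## Default mapping from sample id to biological group: samples are named
## "<group>.<replicate>", e.g. "male_antenna.2".
.sample_group <- function(sample_id) sub("\\.[^.]*$", "", sample_id)

.check_wells <- function(wells) {
  need <- c("primer_id", "sample_id", "tech_rep", "ct", "efficiency")
  missing <- setdiff(need, names(wells))
  if (length(missing) > 0L) {
    stop("wells table is missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ok <- is.na(wells$ct) | wells$ct >= 1
  if (!all(ok)) stop("ct values must be >= 1 cycle or censored (NA)",
                     call. = FALSE)
  eff <- wells$efficiency[!is.na(wells$ct)]
  if (any(is.na(eff)) || any(eff <= 1) || any(eff > 2.2)) {
    stop("efficiencies of detected wells must lie in (1, 2.2]",
         call. = FALSE)
  }
  invisible(wells)
}

#' Load a long-format table of qPCR wells
#'
#' Columns: `primer_id`, `sample_id`, `tech_rep`, `ct` (a cycle number or
#' the token `BLD` for wells censored at the end of the run), `efficiency`
#' (per primer x sample amplification efficiency).
#'
#' @param path TSV file with header.
#' @return a `data.frame` suitable for [quantify_experiment()].
#' @export
load_wells <- function(path) {
  df <- .read_tsv_chr(path)
  .require_columns(df, c("primer_id", "sample_id", "tech_rep", "ct",
                         "efficiency"), path)
  df$tech_rep <- as.integer(df$tech_rep)
  ct <- rep(NA_real_, nrow(df))
  num <- df$ct != "BLD"
  ct[num] <- as.numeric(df$ct[num])
  df$ct <- ct
  df$efficiency <- suppressWarnings(as.numeric(df$efficiency))
  .check_wells(df)
  df
}

#' Efficiency-corrected relative quantification of a qPCR experiment
#'
#' Implements the modified delta-Ct chain for a full plate set:
#' \enumerate{
#'   \item Technical replicate wells of each primer x sample are combined
#'     (by default on the Ct scale, before correction; set
#'     `tech_rep_mode = "separate"` to correct each well first and average
#'     the corrected Cts).
#'   \item `E_MAX` is taken per primer pair as the maximum efficiency over
#'     all samples; every Ct is rescaled to that base with [correct_ct()].
#'   \item The normalization factor of each sample is the mean corrected Ct
#'     of the housekeeping genes ([normalization_factor()]).
#'   \item Relative expression `E_MAX^(NF - Ct_corrected)` is computed per
#'     biological replicate, then averaged within each biological group.
#' }
#' A gene x group combination is censored (`bld = TRUE`) only when every
#' one of its replicates is censored; if some replicates are detected those
#' are used and their number recorded.
#'
#' @param wells data.frame of wells (see [load_wells()]); censored wells
#'   carry `ct = NA`. Cts beyond `max_cycles` are treated as censored.
#' @param housekeeping_ids primer ids of the housekeeping genes.
#' @param sample_groups optional data.frame (`sample_id`, `group`) mapping
#'   biological replicates to groups; by default the group is the sample id
#'   minus its trailing `.<replicate>` suffix.
#' @param tech_rep_mode `"mean_ct"` (default) or `"separate"`.
#' @param max_cycles length of the run; Cts beyond it are censored
#'   (default 45).
#' @return data.frame of class `"relative_expression_table"` with one row
#'   per gene x group: `gene_id`, `group`, `mean_rel_expr`,
#'   `n_reps_aggregated`, `bld`, and a list column `rep_values` retaining
#'   the per-biological-replicate relative expressions.
#' @export
quantify_experiment <- function(wells, housekeeping_ids,
                                sample_groups = NULL,
                                tech_rep_mode = c("mean_ct", "separate"),
                                max_cycles = 45) {
  tech_rep_mode <- match.arg(tech_rep_mode)
  .check_wells(wells)
  wells$ct[!is.na(wells$ct) & wells$ct > max_cycles] <- NA_real_

  key <- interaction(wells$primer_id, wells$sample_id, drop = TRUE)
  groups <- split(seq_len(nrow(wells)), key)

  ps <- do.call(rbind, lapply(groups, function(idx) {
    w <- wells[idx, ]
    eff <- mean(w$efficiency[!is.na(w$efficiency)])
    detected <- !is.na(w$ct)
    data.frame(primer_id = w$primer_id[1], sample_id = w$sample_id[1],
               efficiency = eff,
               ct = if (any(detected)) mean(w$ct[detected]) else NA_real_,
               cts_list = I(list(w$ct[detected])),
               n_tech = sum(detected), stringsAsFactors = FALSE)
  }))
  rownames(ps) <- NULL

  e_max <- tapply(ps$efficiency, ps$primer_id, max, na.rm = TRUE)
  ps$e_max <- as.numeric(e_max[ps$primer_id])

  ps$ct_corr <- NA_real_
  det <- !is.na(ps$ct)
  if (tech_rep_mode == "mean_ct") {
    ps$ct_corr[det] <- correct_ct(ps$ct[det], ps$efficiency[det],
                                  ps$e_max[det])
  } else {
    ps$ct_corr[det] <- mapply(function(cts, e, em) {
      mean(correct_ct(cts, e, em))
    }, ps$cts_list[det], ps$efficiency[det], ps$e_max[det])
  }

  is_hk <- ps$primer_id %in% housekeeping_ids
  if (!any(is_hk)) stop("no housekeeping primers found in wells table",
                        call. = FALSE)
  nf <- vapply(split(ps$ct_corr[is_hk], ps$sample_id[is_hk]),
               normalization_factor, numeric(1))

  tg <- ps[!is_hk, , drop = FALSE]
  tg$nf <- nf[tg$sample_id]
  if (any(is.na(tg$nf))) {
    stop("sample(s) without housekeeping wells: ",
         paste(unique(tg$sample_id[is.na(tg$nf)]), collapse = ", "),
         call. = FALSE)
  }
  tg$rel <- ifelse(is.na(tg$ct_corr), NA_real_,
                   relative_expression(tg$e_max, tg$ct_corr, tg$nf))

  if (is.null(sample_groups)) {
    tg$group <- .sample_group(tg$sample_id)
  } else {
    tg$group <- sample_groups$group[match(tg$sample_id,
                                          sample_groups$sample_id)]
    if (any(is.na(tg$group))) stop("sample_groups does not cover all samples",
                                   call. = FALSE)
  }

  keys <- unique(tg[, c("primer_id", "group")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- tg$primer_id == keys$primer_id[i] & tg$group == keys$group[i]
    vals <- tg$rel[sel]
    det <- vals[!is.na(vals)]
    data.frame(gene_id = keys$primer_id[i], group = keys$group[i],
               mean_rel_expr = if (length(det) > 0L) mean(det) else NA_real_,
               n_reps_aggregated = length(det),
               bld = length(det) == 0L,
               rep_values = I(list(det)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("relative_expression_table", "data.frame")
  out
}

#' Call sex-biased antennal expression from a relative expression table
#'
#' For each gene, per-replicate relative expressions in male and female
#' antennae are compared with a Welch two-sample t-test at level `alpha`
#' (two-sided, no multiple-testing correction). Direction is `male` when
#' the male mean is greater and `p < alpha`, symmetrically `female`;
#' `none` when not significant; `undetermined` when either sex has fewer
#' than two detected replicates (e.g. entirely censored) — such genes are
#' reported, not tested.
#'
#' @param rel_table a `relative_expression_table` from
#'   [quantify_experiment()].
#' @param male_group,female_group group labels of the two antennal groups.
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `"bias_calls"`: `gene_id`, `direction`,
#'   `t`, `df`, `p`, `n_male`, `n_female`.
#' @export
call_sex_bias <- function(rel_table, male_group = "male_antenna",
                          female_group = "female_antenna", alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  genes <- unique(rel_table$gene_id)
  rows <- lapply(genes, function(g) {
    m <- rel_table$rep_values[rel_table$gene_id == g &
                              rel_table$group == male_group]
    f <- rel_table$rep_values[rel_table$gene_id == g &
                              rel_table$group == female_group]
    m <- if (length(m) > 0L) m[[1]] else numeric(0)
    f <- if (length(f) > 0L) f[[1]] else numeric(0)
    if (length(m) < 2L || length(f) < 2L) {
      return(data.frame(gene_id = g, direction = "undetermined",
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        n_male = length(m), n_female = length(f),
                        stringsAsFactors = FALSE))
    }
    wt <- welch_test(m, f)
    dir <- if (wt$p < alpha) {
      if (mean(m) > mean(f)) "male" else "female"
    } else "none"
    data.frame(gene_id = g, direction = dir, t = wt$t, df = wt$df,
               p = wt$p, n_male = length(m), n_female = length(f),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bias_calls", "data.frame")
  out
}

#' Estimate amplification efficiency from a raw fluorescence curve
#'
#' Window-of-linearity estimator: after subtracting a baseline (mean
#' fluorescence of `baseline_cycles`), the log-linear phase of the
#' amplification curve is found by sliding windows of `window` up to
#' `window + extra_width` cycles across the curve, fitting
#' `log10(F) ~ cycle` in each, and keeping the window with the highest r
#' squared among those reaching `r2_min` and spanning at least
#' `min_decades` log-decades of fluorescence. The efficiency is
#' `10^slope`. Curves with no qualifying window (flat curves, no
#' exponential phase above baseline) return a censored estimate rather
#' than an error.
#'
#' @param fluorescence per-cycle fluorescence readings (>= 15 cycles,
#'   non-negative).
#' @param cycles cycle numbers (default `seq_along(fluorescence)`).
#' @param window minimum window width in cycles (default 5).
#' @param extra_width widths up to `window + extra_width` are also tried,
#'   so low-efficiency curves can still span a full decade (default 3).
#' @param r2_min minimum r squared for a window to qualify (default 0.99).
#' @param min_decades minimum log10 span of baseline-subtracted
#'   fluorescence inside the window (default 1).
#' @param baseline_cycles cycles averaged for the baseline estimate
#'   (default 3:8).
#' @return list of class `"efficiency_estimate"`: `e`, `window_start`,
#'   `window_end` (cycle numbers), `r2`, `censored`.
#' @export
estimate_efficiency <- function(fluorescence, cycles = seq_along(fluorescence),
                                window = 5, extra_width = 3, r2_min = 0.99,
                                min_decades = 1, baseline_cycles = 3:8) {
  n <- length(fluorescence)
  if (n < 15L) stop("need at least 15 cycles", call. = FALSE)
  if (any(fluorescence < 0)) stop("fluorescence must be non-negative",
                                  call. = FALSE)
  stopifnot(length(cycles) == n)
  in_base <- cycles %in% baseline_cycles
  baseline <- if (any(in_base)) mean(fluorescence[in_base]) else 0
  g <- fluorescence - baseline

  best <- NULL
  for (w in window:(window + extra_width)) {
    if (w > n) break
    for (start in seq_len(n - w + 1L)) {
      idx <- start:(start + w - 1L)
      if (any(g[idx] <= 0)) next  # window rejected: log undefined
      y <- log10(g[idx])
      if (diff(range(y)) < min_decades) next
      fit <- stats::lm.fit(cbind(1, cycles[idx]), y)
      slope <- fit$coefficients[2]
      if (!is.finite(slope) || slope <= 0) next
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      if (r2 < r2_min) next
      if (is.null(best) || r2 > best$r2 ||
          (r2 == best$r2 && w > (best$window_end - best$window_start + 1))) {
        best <- list(e = unname(10^slope),
                     window_start = cycles[idx[1]],
                     window_end = cycles[idx[w]],
                     r2 = r2, censored = FALSE)
      }
    }
  }
  if (is.null(best)) {
    best <- list(e = NA_real_, window_start = NA_integer_,
                 window_end = NA_integer_, r2 = NA_real_, censored = TRUE)
  }
  class(best) <- "efficiency_estimate"
  best
}
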