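#' Flag RNAseq detection at an FPKM threshold
#'
#' A gene is detected when the larger of its two antennal FPKM values
#' exceeds the threshold — strictly (`>`, the default, mirroring the
#' "greater than one" convention) or non-strictly (`>=`). Both counts are
#' reported so the rounding sensitivity of published integer tables is
#' visible.
#'
#' @param catalog a `gene_catalog` or `or_table` with `fpkm_f_ant` and
#'   `fpkm_m_ant` columns.
#' @param threshold FPKM detection threshold (default 1).
#' @param strict use `>` (default) rather than `>=`.
#' @return list of class `"fpkm_detection"`: per-gene data.frame `flags`
#'   (`gene_id`, `detected_female`, `detected_male`, `detected`),
#'   `n_detected`, `n_undetected`, plus the count under the other
#'   strictness as `n_detected_alt`.
#' @export
fpkm_detection <- function(catalog, threshold = 1, strict = TRUE) {
  cmp <- if (strict) `>` else `>=`
  alt <- if (strict) `>=` else `>`
  f <- cmp(catalog$fpkm_f_ant, threshold)
  m <- cmp(catalog$fpkm_m_ant, threshold)
  flags <- data.frame(gene_id = catalog$gene_id, detected_female = f,
                      detected_male = m, detected = f | m,
                      stringsAsFactors = FALSE)
  out <- list(flags = flags,
              n_detected = sum(flags$detected),
              n_undetected = sum(!flags$detected),
              n_detected_alt = sum(alt(catalog$fpkm_f_ant, threshold) |
                                   alt(catalog$fpkm_m_ant, threshold)),
              threshold = threshold, strict = strict)
  class(out) <- "fpkm_detection"
  out
}

#' Pseudocounted log2 sex ratio of FPKM values
#'
#' `log2((fpkm_female + pseudocount) / (fpkm_male + pseudocount))`. The
#' pseudocount keeps ratios finite when one sex has zero FPKM (common for
#' strongly biased receptors in integer tables). Ratios with absolute value
#' below `min_effect` are called unbiased.
#'
#' @param fpkm_female,fpkm_male non-negative FPKM values (vectorised).
#' @param pseudocount added to both values before the ratio (default 1,
#'   matching the integer scale of the packaged tables; must be positive
#'   when any FPKM is zero).
#' @param min_effect minimum |log2 ratio| to call a direction (default 1,
#'   i.e. two-fold).
#' @return data.frame: `log2_ratio`, `direction`
#'   (`"female"`/`"male"`/`"none"`), `detected_female`, `detected_male`
#'   at an FPKM > 1 threshold.
#' @export
sex_ratio <- function(fpkm_female, fpkm_male, pseudocount = 1,
                      min_effect = 1) {
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  if (any(fpkm_female < 0) || any(fpkm_male < 0)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  lr <- log2((fpkm_female + pseudocount) / (fpkm_male + pseudocount))
  if (any(!is.finite(lr))) {
    stop("log2 ratio not finite; use a positive pseudocount", call. = FALSE)
  }
  dir <- ifelse(lr >= min_effect, "female",
                ifelse(lr <= -min_effect, "male", "none"))
  data.frame(log2_ratio = lr, direction = dir,
             detected_female = fpkm_female > 1,
             detected_male = fpkm_male > 1, stringsAsFactors = FALSE)
}

#' Per-gene sex ratios for a whole table
#'
#' @param catalog a `gene_catalog` or `or_table`.
#' @inheritParams sex_ratio
#' @return data.frame keyed by `gene_id` with the columns of [sex_ratio()].
#' @export
sex_ratio_table <- function(catalog, pseudocount = 1, min_effect = 1) {
  sr <- sex_ratio(catalog$fpkm_f_ant, catalog$fpkm_m_ant,
                  pseudocount = pseudocount, min_effect = min_effect)
  cbind(data.frame(gene_id = catalog$gene_id, stringsAsFactors = FALSE), sr)
}

#' Concordance of qPCR bias calls with RNAseq sex ratios
#'
#' For a chosen gene subset, compares the qPCR-called direction of
#' sex-biased antennal expression with the direction of the (pseudocounted)
#' FPKM ratio. Genes whose qPCR direction is `none` or `undetermined`
#' contribute nothing to the agreement fraction and are listed separately.
#'
#' @param bias_calls data.frame with `gene_id` and `direction` (e.g. from
#'   [call_sex_bias()], or a curated direction list).
#' @param sex_ratios data.frame from [sex_ratio_table()].
#' @param gene_subset gene ids to compare (must appear in both inputs).
#' @return list of class `"concordance_report"`: `per_gene` data.frame
#'   (`gene_id`, `qpcr_direction`, `fpkm_direction`, `agree`),
#'   `agreement_fraction` (`NA` with `undefined = TRUE` when no gene is
#'   comparable), `excluded_ids`.
#' @export
concordance <- function(bias_calls, sex_ratios, gene_subset) {
  miss <- setdiff(gene_subset, intersect(bias_calls$gene_id,
                                         sex_ratios$gene_id))
  if (length(miss) > 0L) {
    stop("gene(s) absent from inputs: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  qd <- bias_calls$direction[match(gene_subset, bias_calls$gene_id)]
  fd <- sex_ratios$direction[match(gene_subset, sex_ratios$gene_id)]
  comparable <- qd %in% c("male", "female")
  per_gene <- data.frame(gene_id = gene_subset, qpcr_direction = qd,
                         fpkm_direction = fd,
                         agree = ifelse(comparable, qd == fd, NA),
                         stringsAsFactors = FALSE)
  frac <- if (any(comparable)) mean(per_gene$agree[comparable]) else NA_real_
  out <- list(per_gene = per_gene, agreement_fraction = frac,
              undefined = !any(comparable),
              excluded_ids = gene_subset[!comparable])
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("qPCR / RNAseq direction concordance\n")
  print(x$per_gene, row.names = FALSE)
  if (x$undefined) {
    cat("agreement fraction: undefined (no comparable genes)\n")
  } else {
    cat(sprintf("agreement fraction: %.3f over %d comparable genes\n",
                x$agreement_fraction, sum(!is.na(x$per_gene$agree))))
  }
  invisible(x)
}

#' The odorant receptors with significant sex-biased antennal expression
#'
#' Curated gene lists used in the reproduction report: four male-biased
#' receptors (two inside, two outside the pheromone-receptor clade) and
#' five female-biased receptors, as established by Welch tests on the
#' original replicate-level data.
#'
#' @return list with character vectors `male` and `female`.
#' @export
epos_sex_biased_ors <- function() {
  list(male = c("EposOR6", "EposOR7", "EposOR30", "EposOR34"),
       female = c("EposOR19", "EposOR22", "EposOR31", "EposOR36",
                  "EposOR40"))
}

#' The pheromone-receptor-clade odorant receptors
#'
#' The eight receptors falling into the lepidopteran pheromone-receptor
#' clade; most members of that clade carry a 'PWE' motif near the final
#' transmembrane domain.
#'
#' @return character vector of eight gene ids.
#' @export
epos_pr_clade_ors <- function() {
  c("EposOR1", "EposOR6", "EposOR7", "EposOR21", "EposOR22", "EposOR41",
    "EposOR43", "EposOR45")
}

#' qPCR-derived direction of antennal sex bias from tabled fold changes
#'
#' When only mean fold changes per tissue are available (as in the packaged
#' OR table), direction is the sign of the male vs female antennal mean;
#' genes censored in either antennal slot are `undetermined`.
#'
#' @param or_table an `or_table`.
#' @return data.frame `gene_id`, `direction` suitable for [concordance()].
#' @export
qpcr_direction_from_table <- function(or_table) {
  stopifnot(inherits(or_table, "or_table"))
  m <- or_table$qpcr_m_ant
  f <- or_table$qpcr_f_ant
  dir <- ifelse(is.na(m) | is.na(f), "undetermined",
                ifelse(m > f, "male", ifelse(f > m, "female", "none")))
  data.frame(gene_id = or_table$gene_id, direction = dir,
             stringsAsFactors = FALSE)
}
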