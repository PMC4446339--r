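#' Validated analysis configuration
#'
#' Collects every tunable the analysis stages expose, validates all fields
#' up front (before any stage runs), and is echoed into report output so
#' every result records the settings that produced it.
#'
#' @param alpha Welch-test significance level, in (0, 1) (default 0.05;
#'   two-sided, no multiple-testing correction).
#' @param fpkm_threshold RNAseq detection threshold (default 1).
#' @param strict use strict `>` for FPKM detection (default TRUE).
#' @param pseudocount pseudocount for FPKM sex ratios (default 1).
#' @param min_effect minimum |log2 ratio| for an FPKM direction call
#'   (default 1).
#' @param efficiency_window,efficiency_r2 window-of-linearity estimator
#'   settings (defaults 5 cycles, 0.99).
#' @param pwe_window C-terminal window for the 'PWE' screen (default 60).
#' @param gap_open,gap_extend alignment gap penalties (defaults 10, 0.5).
#' @param spacing an [obp_spacing_config()].
#' @param seed default RNG seed for any simulation stage (default 1).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(alpha = 0.05, fpkm_threshold = 1, strict = TRUE,
                       pseudocount = 1, min_effect = 1,
                       efficiency_window = 5, efficiency_r2 = 0.99,
                       pwe_window = 60, gap_open = 10, gap_extend = 0.5,
                       spacing = obp_spacing_config(), seed = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("validation error: alpha must be a number in (0, 1)", call. = FALSE)
  }
  if (fpkm_threshold < 0) stop("validation error: fpkm_threshold must be >= 0",
                               call. = FALSE)
  if (pseudocount < 0) stop("validation error: pseudocount must be >= 0",
                            call. = FALSE)
  if (min_effect < 0) stop("validation error: min_effect must be >= 0",
                           call. = FALSE)
  if (efficiency_window < 3) stop("validation error: efficiency_window < 3",
                                  call. = FALSE)
  if (efficiency_r2 <= 0 || efficiency_r2 > 1) {
    stop("validation error: efficiency_r2 must be in (0, 1]", call. = FALSE)
  }
  if (pwe_window < 3) stop("validation error: pwe_window < 3", call. = FALSE)
  if (gap_open <= 0 || gap_extend < 0) {
    stop("validation error: gap penalties out of range", call. = FALSE)
  }
  stopifnot(inherits(spacing, "obp_spacing_config"))
  out <- list(alpha = alpha, fpkm_threshold = fpkm_threshold,
              strict = strict, pseudocount = pseudocount,
              min_effect = min_effect,
              efficiency_window = efficiency_window,
              efficiency_r2 = efficiency_r2, pwe_window = pwe_window,
              gap_open = gap_open, gap_extend = gap_extend,
              spacing = spacing, seed = seed)
  class(out) <- "run_config"
  out
}

#' Reproduction report over the packaged expression tables
#'
#' Aggregates the module outputs into one report: catalog and family
#' counts, the qPCR detection summary, the FPKM detection recount (with
#' its strict/non-strict sensitivity), and the qPCR/RNAseq direction
#' concordance table for the sex-biased receptors. When a FASTA of
#' receptor proteins is supplied, the 'PWE' screen and the pairwise
#' identity of the four-member receptor radiation are added; otherwise
#' those sections are marked skipped (they require the supplementary
#' protein sequences, which are distributed separately from the expression
#' tables).
#'
#' @param table1 non-OR catalog (default: the packaged table).
#' @param table2 OR expression table (default: the packaged table).
#' @param or_fasta optional path to a protein FASTA with the receptor
#'   sequences (ids matching the gene ids).
#' @param config a [run_config()]; validated before any computation.
#' @return list of class `"reproduction_report"`.
#' @export
run_report <- function(table1 = epos_table1(), table2 = epos_table2(),
                       or_fasta = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  fam <- family_counts(table1)
  counts <- list(
    n_non_or = nrow(table1),
    n_or = nrow(table2),
    n_total = nrow(table1) + nrow(table2),
    family_counts = fam,
    obp_superfamily = obp_superfamily_count(table1)
  )
  detection <- qpcr_detection_summary(table2)
  fpkm_strict <- fpkm_detection(table2, threshold = config$fpkm_threshold,
                                strict = TRUE)
  fpkm_loose <- fpkm_detection(table2, threshold = config$fpkm_threshold,
                               strict = FALSE)

  biased <- epos_sex_biased_ors()
  conc <- concordance(
    qpcr_direction_from_table(table2),
    sex_ratio_table(table2, pseudocount = config$pseudocount,
                    min_effect = config$min_effect),
    c(biased$male, biased$female)
  )

  motifs <- NULL
  if (!is.null(or_fasta)) {
    seqs <- read_protein_fasta(or_fasta)
    pr_ids <- intersect(epos_pr_clade_ors(), names(seqs))
    pwe <- vapply(seqs[pr_ids], function(s) {
      detect_pwe(s, cterm_window = config$pwe_window)$found
    }, logical(1))
    rad_ids <- intersect(c("EposOR1", "EposOR41", "EposOR43", "EposOR45"),
                         names(seqs))
    idm <- if (length(rad_ids) >= 2L) {
      identity_matrix(seqs[rad_ids], gap_open = config$gap_open,
                      gap_extend = config$gap_extend)
    } else NULL
    motifs <- list(pr_clade_ids = pr_ids, pwe_found = pwe,
                   n_pwe = sum(pwe), identity = idm)
  }

  out <- list(counts = counts, detection = detection,
              fpkm_strict = fpkm_strict, fpkm_loose = fpkm_loose,
              concordance = conc, motifs = motifs, config = config)
  class(out) <- "reproduction_report"
  out
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("== Antennal chemosensory repertoire: reproduction report ==\n\n")
  cat(sprintf("Catalog: %d chemosensory genes (%d non-OR + %d OR)\n",
              x$counts$n_total, x$counts$n_non_or, x$counts$n_or))
  cat(sprintf("OBP super-family (OBP+PBP+GOBP+ABPX): %d\n",
              x$counts$obp_superfamily))
  cat("Family counts:\n")
  print(x$counts$family_counts)
  cat("\n")
  print(x$detection)
  cat(sprintf("\nFPKM detection at threshold %g: %d (strict >), %d (>=)\n",
              x$fpkm_strict$threshold, x$fpkm_strict$n_detected,
              x$fpkm_loose$n_detected))
  cat("  (published table FPKM are rounded integers; the strict/non-strict\n",
      "  counts bracket the published detection figure)\n", sep = "")
  cat("\n")
  print(x$concordance)
  cat("\n")
  if (is.null(x$motifs)) {
    cat("PWE screen / identity matrix: skipped",
        "(requires supplementary protein sequences)\n")
  } else {
    cat(sprintf("PWE motif: %d of %d PR-clade receptors\n",
                x$motifs$n_pwe, length(x$motifs$pwe_found)))
    if (!is.null(x$motifs$identity)) print(x$motifs$identity)
  }
  invisible(x)
}
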