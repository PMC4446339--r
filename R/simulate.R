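## Run expr with a private RNG stream seeded by `seed`, restoring the
## caller's .Random.seed afterwards so simulations never perturb user code.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Ground truth for a simulated qPCR experiment
#'
#' Encodes the study design the generators emulate: three biological
#' replicates per group, triplicate wells, three housekeeping genes whose
#' expression defines the normalization factor (truth 1.0 by definition),
#' per primer x sample amplification efficiencies drawn uniformly from a
#' plausible range, Gaussian Ct replicate noise, and right-censoring of
#' wells beyond the run length.
#'
#' @param fold_changes numeric matrix, genes x groups: true expression
#'   relative to the housekeeping genes (must be positive). Row and column
#'   names name the genes and groups.
#' @param n_bio biological replicates per group (default 3).
#' @param n_tech technical (well) replicates (default 3).
#' @param efficiency_range range of true amplification efficiencies
#'   (default `c(1.7, 2.0)`).
#' @param ct_noise_sd per-well Gaussian Ct noise, in cycles (default 0.2).
#' @param bld_cycle run length; wells with Ct beyond it are censored
#'   (default 45).
#' @param nf_true true normalization factor, in cycles (default 22).
#' @param housekeeping_ids names of the housekeeping primers.
#' @param seed RNG seed; the same seed yields byte-identical tables.
#' @return list of class `"simulation_truth"` holding all of the above plus
#'   the drawn per primer x sample efficiencies.
#' @export
simulation_truth <- function(fold_changes,
                             n_bio = 3, n_tech = 3,
                             efficiency_range = c(1.7, 2.0),
                             ct_noise_sd = 0.2, bld_cycle = 45,
                             nf_true = 22,
                             housekeeping_ids = c("actin", "tubulin", "ef1a"),
                             seed = 1) {
  fold_changes <- as.matrix(fold_changes)
  if (any(fold_changes <= 0)) {
    stop("true fold changes must be positive", call. = FALSE)
  }
  if (is.null(rownames(fold_changes))) {
    rownames(fold_changes) <- paste0("gene", seq_len(nrow(fold_changes)))
  }
  if (is.null(colnames(fold_changes))) {
    colnames(fold_changes) <- paste0("group", seq_len(ncol(fold_changes)))
  }
  if (any(rownames(fold_changes) %in% housekeeping_ids)) {
    stop("gene names collide with housekeeping ids", call. = FALSE)
  }
  stopifnot(ct_noise_sd >= 0, bld_cycle > 0, nf_true > 0,
            length(efficiency_range) == 2L,
            efficiency_range[1] > 1, efficiency_range[2] <= 2.2)

  samples <- as.vector(outer(colnames(fold_changes), seq_len(n_bio),
                             function(g, k) paste0(g, ".", k)))
  primers <- c(housekeeping_ids, rownames(fold_changes))
  eff <- .with_seed(seed, {
    matrix(stats::runif(length(primers) * length(samples),
                        efficiency_range[1], efficiency_range[2]),
           nrow = length(primers),
           dimnames = list(primers, samples))
  })
  out <- list(fold_changes = fold_changes, n_bio = n_bio, n_tech = n_tech,
              efficiency = eff, ct_noise_sd = ct_noise_sd,
              bld_cycle = bld_cycle, nf_true = nf_true,
              housekeeping_ids = housekeeping_ids, samples = samples,
              seed = seed)
  class(out) <- "simulation_truth"
  out
}

#' Simulate a table of qPCR wells from recorded truth
#'
#' Cts are generated by inverting the quantification chain: the true
#' corrected Ct of a gene in a sample is `NF_true - log_Emax(expression)`
#' (housekeeping genes sit exactly at `NF_true`), mapped back to the raw
#' scale through the sample's own efficiency
#' (`ct = ct_corr * ln(Emax) / ln(E_sample)`), with independent Gaussian
#' noise per well. Wells whose Ct exceeds the run length are emitted
#' censored (`ct = NA`). With zero noise the full analysis pipeline
#' recovers the programmed fold changes exactly.
#'
#' @param truth a [simulation_truth()].
#' @param seed RNG seed for the well noise (default: `truth$seed + 1`).
#' @return data.frame of wells (`primer_id`, `sample_id`, `tech_rep`,
#'   `ct`, `efficiency`) for [quantify_experiment()].
#' @export
synth_qpcr <- function(truth, seed = truth$seed + 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  genes <- rownames(truth$fold_changes)
  primers <- c(truth$housekeeping_ids, genes)
  e_max <- apply(truth$efficiency, 1, max)

  grid <- expand.grid(primer_id = primers, sample_id = truth$samples,
                      tech_rep = seq_len(truth$n_tech),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  group <- .sample_group(grid$sample_id)
  expr <- rep(1, nrow(grid))  # housekeeping defines the NF: truth 1.0
  is_gene <- grid$primer_id %in% genes
  expr[is_gene] <- truth$fold_changes[cbind(grid$primer_id[is_gene],
                                            group[is_gene])]
  em <- e_max[grid$primer_id]
  es <- truth$efficiency[cbind(grid$primer_id, grid$sample_id)]
  ct_corr <- truth$nf_true - log(expr) / log(em)
  ct <- ct_corr * log(em) / log(es)
  if (truth$ct_noise_sd > 0) {
    ct <- ct + .with_seed(seed, stats::rnorm(length(ct), 0,
                                             truth$ct_noise_sd))
  }
  censored <- ct > truth$bld_cycle
  ct[censored] <- NA_real_
  data.frame(primer_id = grid$primer_id, sample_id = grid$sample_id,
             tech_rep = grid$tech_rep, ct = ct, efficiency = es,
             stringsAsFactors = FALSE)
}

#' Simulate an amplification fluorescence curve
#'
#' Logistic curve `F(c) = baseline + f_max / (1 + exp(-(c - c_mid) *
#' ln(e)))`: its early exponential phase grows by a factor `e` per cycle,
#' so [estimate_efficiency()] applied to the curve should recover `e`.
#'
#' @param e true amplification efficiency (> 1).
#' @param n_cycles run length (default 45).
#' @param c_mid inflection cycle (default 25).
#' @param f_max plateau fluorescence (default 10).
#' @param baseline additive background fluorescence (default 0.02).
#' @param noise_sd multiplicative log-normal noise sd on the signal
#'   (default 0 = noise-free).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return numeric vector of per-cycle fluorescence.
#' @export
synth_amp_curve <- function(e, n_cycles = 45, c_mid = 25, f_max = 10,
                            baseline = 0.02, noise_sd = 0, seed = 1) {
  stopifnot(e > 1, n_cycles >= 15)
  cycles <- seq_len(n_cycles)
  signal <- f_max / (1 + exp(-(cycles - c_mid) * log(e)))
  if (noise_sd > 0) {
    signal <- signal * .with_seed(seed, exp(stats::rnorm(n_cycles, 0,
                                                         noise_sd)))
  }
  baseline + signal
}

#' Simulate an FPKM catalog with programmed sex-bias factors
#'
#' Per-gene base means are drawn log-normally; per-sex FPKM is a
#' gamma-mixed (negative binomial) count with the female mean multiplied
#' by the gene's bias factor, emulating unreplicated RNAseq abundance
#' tables. The programmed truth is attached for parameter-recovery tests.
#'
#' @param n_genes number of genes.
#' @param bias_factors length-`n_genes` (or scalar) multiplicative
#'   female/male bias on the mean (1 = unbiased; must be positive).
#' @param dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2; must be positive).
#' @param base_meanlog,base_sdlog log-normal parameters of per-gene base
#'   means (defaults 4 and 1.5, spanning the 1-10^5 FPKM range of real
#'   antennal tables).
#' @param seed RNG seed.
#' @return `gene_catalog`-like data.frame (`gene_id`, `family`,
#'   `fpkm_f_ant`, `fpkm_m_ant`) with attribute `truth` (list:
#'   `base_mean`, `bias_factors`, `dispersion`, `seed`).
#' @export
synth_fpkm <- function(n_genes, bias_factors = 1, dispersion = 0.05,
                       base_meanlog = 4, base_sdlog = 1.5, seed = 1) {
  if (any(bias_factors <= 0)) stop("bias factors must be positive",
                                   call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  bias_factors <- rep_len(bias_factors, n_genes)
  out <- .with_seed(seed, {
    base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    f <- stats::rnbinom(n_genes, mu = base * bias_factors,
                        size = 1 / dispersion)
    m <- stats::rnbinom(n_genes, mu = base, size = 1 / dispersion)
    data.frame(gene_id = sprintf("SynGene%03d", seq_len(n_genes)),
               family = "unclassified", fpkm_f_ant = as.numeric(f),
               fpkm_m_ant = as.numeric(m), stringsAsFactors = FALSE)
  })
  attr(out, "truth") <- list(bias_factors = bias_factors,
                             dispersion = dispersion, seed = seed)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

## Background residues for synthetic proteins: no cysteine (skeleton control)
## and no proline (the plus-C proline is placed deliberately).
.background_aa <- setdiff(.aa_alphabet, c("C", "P", "X"))

#' Generate an OBP-like protein with a controlled cysteine skeleton
#'
#' Builds a random background sequence and plants cysteines (and, for
#' plus-C, extra cysteines and the conserved proline) according to a class
#' blueprint, guaranteed classifiable as the requested class by
#' [classify_obp()] under the same spacing configuration.
#'
#' @param class `"classic"`, `"minus-C"` or `"plus-C"`.
#' @param gaps five gaps between consecutive skeleton cysteines (classic /
#'   plus-C) or `NULL` to draw them uniformly from the configured ranges.
#'   For `"minus-C"`, three gaps of the reduced skeleton (or `NULL`).
#' @param extra_c extra cysteines appended after the proline for plus-C
#'   (default 2).
#' @param lead residues before the first skeleton cysteine (default 10).
#' @param tail_len residues after the last planted feature (default 15).
#' @param config an [obp_spacing_config()].
#' @param seed RNG seed.
#' @return named character vector of length one (the residue string), name
#'   encoding the blueprint.
#' @export
synth_obp <- function(class = c("classic", "minus-C", "plus-C"),
                      gaps = NULL, extra_c = 2L, lead = 10L, tail_len = 15L,
                      config = obp_spacing_config(), seed = 1) {
  class <- match.arg(class)
  ranges <- if (class == "minus-C") config$minus_ranges else config$gap_ranges
  gaps <- .with_seed(seed, {
    if (is.null(gaps)) {
      vapply(ranges, function(r) {
        if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
      }, numeric(1))
    } else gaps
  })
  if (length(gaps) != length(ranges)) {
    stop("expected ", length(ranges), " gaps for class ", class,
         call. = FALSE)
  }
  ok <- mapply(function(g, r) g >= r[1] && g <= r[2], gaps, ranges)
  if (!all(ok)) stop("gaps incompatible with class ", class, call. = FALSE)
  if (class == "plus-C" && extra_c < config$plus_c_min_extra) {
    stop("plus-C needs at least ", config$plus_c_min_extra,
         " extra cysteines", call. = FALSE)
  }

  .with_seed(seed + 1L, {
    bg <- function(n) sample(.background_aa, n, replace = TRUE)
    chars <- bg(lead)
    for (g in gaps) chars <- c(chars, "C", bg(g - 1L))
    chars <- c(chars, "C")
    if (class == "plus-C") {
      p_off <- sample(seq_len(config$proline_window), 1L)
      chars <- c(chars, bg(p_off - 1L), "P")
      for (k in seq_len(extra_c)) chars <- c(chars, bg(3L), "C")
    }
    chars <- c(chars, bg(tail_len))
    seq <- paste(chars, collapse = "")
    names(seq) <- sprintf("synOBP_%s_seed%d", class, seed)
    seq
  })
}

#' Generate a synthetic protein family with programmed mean identity
#'
#' Builds a random ancestor and derives `n` descendants by substituting
#' each position independently with probability chosen so that the expected
#' pairwise identity between descendants equals `target_identity`. Used as
#' a clearly synthetic stand-in when exercising [identity_matrix()] on a
#' paralog group.
#'
#' @param n number of sequences (>= 2).
#' @param length sequence length (default 400).
#' @param target_identity expected pairwise identity fraction (default
#'   0.61).
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
synth_protein_family <- function(n = 4, length = 400, target_identity = 0.61,
                                 seed = 1) {
  stopifnot(n >= 2, length >= 10, target_identity > 0, target_identity < 1)
  alphabet <- setdiff(.aa_alphabet, "X")
  k <- base::length(alphabet)
  ## Identity between two descendants, each mutated at rate m: both
  ## untouched, or both redrawn (uniform over the k-1 non-ancestral
  ## letters) to the same residue.
  pid <- function(m) (1 - m)^2 + m^2 / (k - 1)
  m <- stats::uniroot(function(x) pid(x) - target_identity,
                      c(1e-6, 1 - 1e-6))$root
  .with_seed(seed, {
    anc <- sample(alphabet, length, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      mut <- stats::runif(length) < m
      child <- anc
      child[mut] <- vapply(which(mut), function(p) {
        sample(setdiff(alphabet, anc[p]), 1L)
      }, character(1))
      paste(child, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("synFam%d", seq_len(n))
    seqs
  })
}

#' Generate pheromone-receptor-like stand-in sequences for motif screening
#'
#' Builds `n` random receptor-length proteins of which `n_with_motif` carry
#' a 'PWE' tripeptide inside the C-terminal window; the rest are guaranteed
#' motif-free. Synthetic stand-ins for exercising [detect_pwe()] when real
#' receptor sequences are not at hand.
#'
#' @param n number of sequences (default 8).
#' @param n_with_motif how many carry the motif (default 7).
#' @param length sequence length (default 400).
#' @param cterm_window window within which the motif is planted
#'   (default 60).
#' @param seed RNG seed.
#' @return named character vector; names end in `_PWE` when the motif was
#'   planted.
#' @export
synth_pr_clade <- function(n = 8, n_with_motif = 7, length = 400,
                           cterm_window = 60, seed = 1) {
  stopifnot(n_with_motif <= n, length > cterm_window + 3)
  ## W only planted deliberately, so no accidental PWE anywhere.
  alphabet <- setdiff(.aa_alphabet, c("W", "X"))
  .with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      chars <- sample(alphabet, length, replace = TRUE)
      if (i <= n_with_motif) {
        at <- sample(seq(length - cterm_window + 1L, length - 2L), 1L)
        chars[at:(at + 2L)] <- c("P", "W", "E")
      }
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("synPR%d%s", seq_len(n),
                           ifelse(seq_len(n) <= n_with_motif, "_PWE", ""))
    seqs
  })
}
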