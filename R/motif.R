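## Amino-acid alphabet accepted in protein inputs: the 20 standard residues
## plus X for unknowns.
.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.check_protein <- function(residues, seq_id = "<sequence>") {
  if (nchar(residues) < 1L) stop("empty sequence: ", seq_id, call. = FALSE)
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), .aa_alphabet)
  if (length(bad) > 0L) {
    stop("validation error: non-amino-acid character(s) ",
         paste(bad, collapse = ""), " in ", seq_id, call. = FALSE)
  }
  invisible(chars)
}

#' Read a multi-record protein FASTA file
#'
#' Wrapped lines are supported. Sequences are upper-cased and validated
#' against the 20 standard amino acids plus X.
#'
#' @param path FASTA file.
#' @return named character vector of residue strings.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  for (i in seq_along(seqs)) .check_protein(seqs[[i]], names(seqs)[i])
  seqs
}

#' Cysteine-skeleton spacing configuration for OBP classification
#'
#' Gap ranges between consecutive skeleton cysteines, counted as the
#' difference of their residue positions. The defaults follow the canonical
#' insect-OBP skeleton: C1-C2 spacing 15-45, the invariant C2-C3 spacing of
#' exactly 3, C3-C4 spacing 20-50, C4-C5 spacing 7-14 and the invariant
#' C5-C6 spacing of exactly 8. The minus-C skeleton (cysteines 2 and 5
#' absent) uses the merged ranges implied by deleting those positions.
#'
#' @param gap_ranges list of five length-2 integer vectors (min, max gap
#'   between consecutive skeleton cysteines).
#' @param plus_c_min_extra minimum number of cysteines beyond the six of
#'   the classic skeleton for a plus-C call (default 2).
#' @param proline_window a plus-C sequence must carry a proline within this
#'   many residues after the sixth skeleton cysteine (default 12).
#' @return list of class `"obp_spacing_config"`.
#' @export
obp_spacing_config <- function(gap_ranges = list(c(15L, 45L), c(3L, 3L),
                                                 c(20L, 50L), c(7L, 14L),
                                                 c(8L, 8L)),
                               plus_c_min_extra = 2L,
                               proline_window = 12L) {
  stopifnot(length(gap_ranges) == 5L,
            all(vapply(gap_ranges, length, 1L) == 2L),
            plus_c_min_extra >= 1L, proline_window >= 1L)
  g <- gap_ranges
  minus_ranges <- list(g[[1]] + g[[2]], g[[3]], g[[4]] + g[[5]])
  out <- list(gap_ranges = g, minus_ranges = minus_ranges,
              plus_c_min_extra = plus_c_min_extra,
              proline_window = proline_window)
  class(out) <- "obp_spacing_config"
  out
}

## Earliest (lexicographically first) ordered subset of `positions` whose
## consecutive gaps fall inside `ranges`; NULL if none. Depth-first over the
## sorted cysteine positions, so the first full match is the earliest one.
.find_skeleton <- function(positions, ranges) {
  k <- length(ranges) + 1L
  n <- length(positions)
  if (n < k) return(NULL)
  recurse <- function(chosen, next_idx) {
    if (length(chosen) == k) return(chosen)
    if (next_idx > n) return(NULL)
    level <- length(chosen)  # choosing cysteine level + 1
    for (i in next_idx:n) {
      if (level > 0L) {
        gap <- positions[i] - chosen[level]
        rng <- ranges[[level]]
        if (gap < rng[1]) next
        if (gap > rng[2]) break  # positions sorted: later ones only larger
      }
      hit <- recurse(c(chosen, positions[i]), i + 1L)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  recurse(integer(0), 1L)
}

#' Classify an odorant binding protein by its cysteine skeleton
#'
#' Insect OBPs fall into subgroups by their disulphide-forming cysteine
#' pattern: the *classic* group carries six well-conserved cysteines with
#' characteristic spacing; the *minus-C* group lacks two of them (positions
#' 2 and 5 of the skeleton); the *plus-C* group carries the classic
#' skeleton plus extra cysteines and a conserved proline shortly after the
#' sixth skeleton cysteine. Sequences matching none of these patterns are
#' `unclassified`.
#'
#' Rules, applied to the mature region (residues after
#' `signal_peptide_len`): \emph{classic} — exactly six cysteines forming a
#' skeleton within the configured gap ranges; \emph{minus-C} — exactly four
#' cysteines forming the reduced skeleton (merged gap ranges); \emph{plus-C}
#' — a classic skeleton present, at least `6 + plus_c_min_extra` cysteines
#' in total, and a proline within `proline_window` residues after the sixth
#' skeleton cysteine. The earliest matching skeleton is reported.
#'
#' @param residues amino-acid string (or one element of
#'   [read_protein_fasta()] output).
#' @param seq_id identifier used in the report.
#' @param signal_peptide_len residues to skip before the mature region
#'   (default 0 = whole sequence).
#' @param config an [obp_spacing_config()].
#' @return list of class `"obp_classification"`: `seq_id`, `obp_class`
#'   (`"classic"`, `"minus-C"`, `"plus-C"` or `"unclassified"`),
#'   `cysteine_positions` (1-based, full-sequence coordinates; skeleton
#'   cysteines when classified, all cysteines otherwise), `reason`.
#' @export
classify_obp <- function(residues, seq_id = "<sequence>",
                         signal_peptide_len = 0,
                         config = obp_spacing_config()) {
  chars <- .check_protein(residues, seq_id)
  if (signal_peptide_len >= length(chars)) {
    stop("signal peptide length >= sequence length for ", seq_id,
         call. = FALSE)
  }
  mature <- chars[(signal_peptide_len + 1L):length(chars)]
  cys <- which(mature == "C")
  n_c <- length(cys)

  result <- function(class, skeleton, reason = NA_character_) {
    pos <- if (is.null(skeleton)) cys else skeleton
    out <- list(seq_id = seq_id, obp_class = class,
                cysteine_positions = pos + signal_peptide_len,
                n_cysteines = n_c, reason = reason)
    class(out) <- "obp_classification"
    out
  }

  min_span <- sum(vapply(config$gap_ranges, `[`, 1L, 1L)) + 1L
  if (length(mature) < min_span) {
    return(result("unclassified", NULL, "sequence shorter than skeleton span"))
  }

  skel6 <- .find_skeleton(cys, config$gap_ranges)
  if (!is.null(skel6)) {
    if (n_c == 6L) return(result("classic", skel6))
    if (n_c >= 6L + config$plus_c_min_extra) {
      after <- (skel6[6] + 1L):min(skel6[6] + config$proline_window,
                                   length(mature))
      if (any(mature[after] == "P")) return(result("plus-C", skel6))
      return(result("unclassified", skel6,
                    "extra cysteines but no conserved proline"))
    }
    return(result("unclassified", skel6,
                  "classic skeleton with unexpected cysteine count"))
  }
  if (n_c == 4L) {
    skel4 <- .find_skeleton(cys, config$minus_ranges)
    if (!is.null(skel4)) return(result("minus-C", skel4))
  }
  result("unclassified", NULL, "no skeleton match")
}

#' Classify a set of proteins
#'
#' @param seqs named character vector (e.g. from [read_protein_fasta()]).
#' @inheritParams classify_obp
#' @return data.frame: `seq_id`, `obp_class`, `n_cysteines`,
#'   `cysteine_positions` (comma-separated).
#' @export
classify_obp_set <- function(seqs, signal_peptide_len = 0,
                             config = obp_spacing_config()) {
  rows <- lapply(seq_along(seqs), function(i) {
    cl <- classify_obp(seqs[[i]], names(seqs)[i],
                       signal_peptide_len = signal_peptide_len,
                       config = config)
    data.frame(seq_id = cl$seq_id, obp_class = cl$obp_class,
               n_cysteines = cl$n_cysteines,
               cysteine_positions = paste(cl$cysteine_positions,
                                          collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen for the pheromone-receptor-clade 'PWE' motif
#'
#' Moth odorant receptors of the pheromone-receptor clade characteristically
#' carry a 'PWE' tripeptide within the final transmembrane domain. As a
#' topology-free proxy, the motif is searched as an exact substring within
#' the C-terminal `cterm_window` residues.
#'
#' @param residues amino-acid string (length >= 3).
#' @param cterm_window number of C-terminal residues searched (default 60;
#'   use `nchar(residues)` for a whole-sequence search).
#' @return list `found` (logical), `position` (1-based index of the first
#'   in-window occurrence in the full sequence, or `NA`).
#' @export
detect_pwe <- function(residues, cterm_window = 60) {
  .check_protein(residues)
  n <- nchar(residues)
  if (n < 3L) stop("sequence shorter than the motif", call. = FALSE)
  start <- max(1L, n - as.integer(cterm_window) + 1L)
  tail_seq <- substring(residues, start, n)
  hit <- regexpr("PWE", tail_seq, fixed = TRUE)
  if (hit == -1L) return(list(found = FALSE, position = NA_integer_))
  list(found = TRUE, position = start + as.integer(hit) - 1L)
}

#' Percent identity of two proteins under global alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (BLOSUM62,
#' gap opening 10, gap extension 0.5 by default). Identity is the fraction
#' of alignment columns with identical residues, over all columns of the
#' pairwise alignment, times 100. Symmetric in its arguments.
#'
#' @param a,b amino-acid strings.
#' @param substitution_matrix scoring matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  .check_protein(a, "first sequence")
  .check_protein(b, "second sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- !(pa == "-" & sa == "-")
  100 * sum(pa[keep] == sa[keep]) / sum(keep)
}

#' Pairwise identity matrix for a set of proteins
#'
#' @param seqs named character vector of at least two sequences.
#' @inheritParams pairwise_identity
#' @return symmetric numeric matrix (diagonal 100) of class
#'   `"identity_matrix"` with attribute `mean_offdiagonal`.
#' @export
identity_matrix <- function(seqs, substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  ids <- if (is.null(names(seqs))) paste0("seq", seq_len(n)) else names(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- pairwise_identity(seqs[[i]], seqs[[j]],
                               substitution_matrix = substitution_matrix,
                               gap_open = gap_open, gap_extend = gap_extend)
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  attr(m, "mean_offdiagonal") <- mean(m[upper.tri(m)])
  class(m) <- c("identity_matrix", class(m))
  m
}

#' @export
print.identity_matrix <- function(x, ...) {
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(round(y, 2))
  cat(sprintf("mean off-diagonal identity: %.2f%%\n",
              attr(x, "mean_offdiagonal")))
  invisible(x)
}
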