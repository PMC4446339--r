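#' @keywords internal
"_PACKAGE"

## Family prefix table for Epos-style gene identifiers. Longest prefix wins,
## so EposPBP* is never swallowed by a shorter match and EposIgluR is kept
## distinct from EposIR*. Orco is the OR co-receptor and belongs to the OR
## family.
.family_prefixes <- c(
  ABPX = "ABPX", CSP = "CSP", CXE = "CXE", CYP = "CYP", GOBP = "GOBP",
  GR = "GR", GST = "GST", IgluR = "IgluR-like", IR = "IR", OBP = "OBP",
  Orco = "OR", OR = "OR", PBP = "PBP", SNMP = "SNMP", TO = "TO"
)

.known_families <- c(
  "ABPX", "CSP", "CXE", "CYP", "GOBP", "GR", "GST", "IR", "IgluR-like",
  "OBP", "OR", "PBP", "SNMP", "TO"
)

## Subfamilies pooled into the odorant-binding-protein super-family.
.obp_superfamily <- c("OBP", "PBP", "GOBP", "ABPX")

#' Assign a chemosensory gene family from a gene identifier
#'
#' Families are encoded in the gene name itself (e.g. `EposOBP13b` is an
#' odorant binding protein). Assignment strips the species prefix and takes
#' the longest matching family prefix, so `EposPBP1` is a PBP, not matched by
#' any shorter prefix, and `EposIgluR` maps to `"IgluR-like"` rather than IR.
#' Orco (the obligate odorant receptor co-receptor) is assigned to the OR
#' family. Identifiers with no known prefix return `"unclassified"`.
#'
#' @param gene_id character vector of gene identifiers.
#' @param species_prefix leading tag shared by all identifiers (default
#'   `"Epos"` for *Epiphyas postvittana*).
#' @return character vector of family labels.
#' @examples
#' assign_family(c("EposOBP13b", "EposPBP1", "EposIgluR", "EposOrco"))
#' @export
assign_family <- function(gene_id, species_prefix = "Epos") {
  stub <- sub(paste0("^", species_prefix), "", gene_id)
  prefixes <- names(.family_prefixes)
  vapply(stub, function(s) {
    hit <- prefixes[startsWith(s, prefixes)]
    if (length(hit) == 0L) return("unclassified")
    .family_prefixes[[hit[which.max(nchar(hit))]]]
  }, character(1), USE.NAMES = FALSE)
}

.read_tsv_chr <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  df
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.as_fpkm <- function(x, gene_id, column) {
  if (any(x == "BLD")) {
    stop("validation error: 'BLD' not permitted in FPKM column ", column,
         " (row ", gene_id[match("BLD", x)], ")", call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v < 0)
  if (length(bad) > 0L) {
    stop("validation error: non-numeric or negative FPKM in column ", column,
         " (row ", gene_id[bad[1]], ")", call. = FALSE)
  }
  v
}

## qPCR columns: numeric or the literal censoring token "BLD" (-> NA).
.as_qpcr <- function(x, gene_id, column) {
  v <- rep(NA_real_, length(x))
  num <- x != "BLD"
  v[num] <- suppressWarnings(as.numeric(x[num]))
  bad <- which(num & (is.na(v) | v < 0))
  if (length(bad) > 0L) {
    stop("validation error: qPCR column ", column,
         " must be non-negative or 'BLD' (row ", gene_id[bad[1]], ")",
         call. = FALSE)
  }
  v
}

#' Load a chemosensory gene catalog or OR expression table
#'
#' Reads the tab-separated table dialect used throughout the package. Two
#' schemas are recognised by their headers:
#' \describe{
#'   \item{gene catalog}{columns `gene_id`, `family`, `fpkm_f_ant`,
#'     `fpkm_m_ant` — one row per non-OR chemosensory gene with antennal FPKM
#'     for each sex.}
#'   \item{OR expression table}{columns `gene_id`, `qpcr_f_ant`,
#'     `qpcr_f_body`, `qpcr_m_ant`, `qpcr_m_body`, `fpkm_f_ant`,
#'     `fpkm_m_ant` — odorant receptors with mean qPCR fold change to
#'     reference genes in four tissues (the token `BLD`, below limit of
#'     detection, is stored as `NA`) plus antennal FPKM.}
#' }
#' Row order is preserved; gene identifiers must be unique. FPKM must be
#' non-negative and numeric; `BLD` is only permitted in qPCR columns.
#'
#' @param path path to a TSV file with a header row.
#' @return a `data.frame` of class `"gene_catalog"` or `"or_table"`.
#' @seealso [epos_table1()], [epos_table2()] for the packaged tables,
#'   [write_catalog()] for the inverse operation.
#' @export
load_catalog <- function(path) {
  df <- .read_tsv_chr(path)
  or_cols <- c("gene_id", "qpcr_f_ant", "qpcr_f_body", "qpcr_m_ant",
               "qpcr_m_body", "fpkm_f_ant", "fpkm_m_ant")
  cat_cols <- c("gene_id", "family", "fpkm_f_ant", "fpkm_m_ant")
  is_or <- all(or_cols %in% names(df))
  .require_columns(df, if (is_or) or_cols else cat_cols, path)

  if (anyDuplicated(df$gene_id)) {
    stop("validation error: duplicated gene_id '",
         df$gene_id[anyDuplicated(df$gene_id)], "'", call. = FALSE)
  }

  out <- data.frame(gene_id = df$gene_id, stringsAsFactors = FALSE)
  if (is_or) {
    for (col in c("qpcr_f_ant", "qpcr_f_body", "qpcr_m_ant", "qpcr_m_body")) {
      out[[col]] <- .as_qpcr(df[[col]], df$gene_id, col)
    }
    for (col in c("fpkm_f_ant", "fpkm_m_ant")) {
      out[[col]] <- .as_fpkm(df[[col]], df$gene_id, col)
    }
    class(out) <- c("or_table", "data.frame")
  } else {
    out$family <- df$family
    for (col in c("fpkm_f_ant", "fpkm_m_ant")) {
      out[[col]] <- .as_fpkm(df[[col]], df$gene_id, col)
    }
    class(out) <- c("gene_catalog", "data.frame")
  }
  out
}

#' Write a catalog or OR table back to TSV
#'
#' Inverse of [load_catalog()]: censored qPCR cells are written as the
#' literal token `BLD`, qPCR fold changes with five decimals (the precision
#' of the source tables) and FPKM as integers, so that
#' `write_catalog(load_catalog(x))` reproduces the input cell for cell.
#'
#' @param x a `gene_catalog` or `or_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path) {
  df <- as.data.frame(x)
  fmt_q <- function(v) ifelse(is.na(v), "BLD",
                              formatC(v, format = "f", digits = 5))
  fmt_i <- function(v) formatC(v, format = "d")
  for (col in grep("^qpcr_", names(df), value = TRUE)) df[[col]] <- fmt_q(df[[col]])
  for (col in grep("^fpkm_", names(df), value = TRUE)) df[[col]] <- fmt_i(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged antennal expression tables for Epiphyas postvittana
#'
#' `epos_table1()` returns the catalog of 191 non-OR chemosensory genes
#' (odorant binding proteins, chemosensory proteins, degrading enzymes,
#' ionotropic and gustatory receptors, ...) with antennal FPKM for each sex.
#' `epos_table2()` returns the 70 odorant receptors with mean qPCR fold
#' change to reference genes in four tissues and antennal FPKM. Values are
#' typed exactly as published (integer FPKM, five-decimal fold changes,
#' `BLD` censoring).
#'
#' @return a `gene_catalog` (`epos_table1`) or `or_table` (`epos_table2`).
#' @export
epos_table1 <- function() {
  load_catalog(system.file("extdata", "table1_nonOR.tsv",
                           package = "antennaquant", mustWork = TRUE))
}

#' @rdname epos_table1
#' @export
epos_table2 <- function() {
  load_catalog(system.file("extdata", "table2_OR.tsv",
                           package = "antennaquant", mustWork = TRUE))
}

#' Count catalog entries per chemosensory gene family
#'
#' Counts partition the catalog: every record lands in exactly one family
#' (records whose identifier matches no known prefix are reported under
#' `"unclassified"`, never dropped). With `merge_iglur = TRUE` (default) the
#' single ionotropic-glutamate-receptor-like gene is counted inside the IR
#' family total, the convention used when the repertoire is summarised.
#'
#' @param catalog a `gene_catalog` or `or_table` (the latter counts as all
#'   OR). A `family` column is used when present, otherwise families are
#'   assigned from `gene_id` via [assign_family()].
#' @param merge_iglur count `IgluR-like` within `IR`?
#' @return named integer vector over all families present (plus all known
#'   families at zero), summing to `nrow(catalog)`.
#' @export
family_counts <- function(catalog, merge_iglur = TRUE) {
  fam <- if (!is.null(catalog$family)) catalog$family
         else assign_family(catalog$gene_id)
  if (merge_iglur) fam[fam == "IgluR-like"] <- "IR"
  levels <- setdiff(.known_families, if (merge_iglur) "IgluR-like" else NULL)
  levels <- union(levels, unique(fam))
  tab <- table(factor(fam, levels = levels))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Size of the odorant-binding-protein super-family
#'
#' The OBP super-family pools the OBP, PBP (pheromone binding), GOBP
#' (general odorant binding) and ABPX (antennal binding protein X)
#' subfamilies.
#'
#' @param catalog a `gene_catalog`.
#' @return integer count.
#' @export
obp_superfamily_count <- function(catalog) {
  counts <- family_counts(catalog)
  sum(counts[intersect(.obp_superfamily, names(counts))])
}

#' Summarise qPCR detection across tissues for an OR table
#'
#' A gene is *detected* when at least one of its four tissue slots (female or
#' male antenna or body) holds a numeric fold change; genes censored (`BLD`)
#' in all four slots are *undetected*. A detected gene is
#' *antenna-exclusive* when it is numeric in at least one antennal slot and
#' censored in both body slots.
#'
#' @param or_table an `or_table` from [load_catalog()]/[epos_table2()].
#' @return a list of class `"qpcr_detection"` with character vectors
#'   `detected_ids`, `undetected_ids`, `antenna_exclusive_ids`.
#' @export
qpcr_detection_summary <- function(or_table) {
  stopifnot(inherits(or_table, "or_table"))
  q <- as.matrix(or_table[, c("qpcr_f_ant", "qpcr_f_body",
                              "qpcr_m_ant", "qpcr_m_body")])
  any_num <- rowSums(!is.na(q)) > 0L
  ant_num <- !is.na(q[, "qpcr_f_ant"]) | !is.na(q[, "qpcr_m_ant"])
  body_bld <- is.na(q[, "qpcr_f_body"]) & is.na(q[, "qpcr_m_body"])
  out <- list(
    detected_ids = or_table$gene_id[any_num],
    undetected_ids = or_table$gene_id[!any_num],
    antenna_exclusive_ids = or_table$gene_id[ant_num & body_bld]
  )
  class(out) <- "qpcr_detection"
  out
}

#' @export
print.qpcr_detection <- function(x, ...) {
  cat("qPCR detection summary\n")
  cat("  detected:          ", length(x$detected_ids), "\n")
  cat("  undetected:        ", length(x$undetected_ids),
      if (length(x$undetected_ids) > 0L)
        paste0(" (", paste(x$undetected_ids, collapse = ", "), ")") else "",
      "\n", sep = "")
  cat("  antenna-exclusive: ", length(x$antenna_exclusive_ids), "\n")
  invisible(x)
}
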