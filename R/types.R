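#' Build a clonotype table
#'
#' A clonotype is one CDR3beta rearrangement: the junction amino-acid
#' sequence (one-letter code, conventionally starting at the conserved
#' cysteine and ending at the conserved phenylalanine), optional
#' nucleotide junction, TRBV/TRBJ gene calls and a read/template count.
#' Within-sample frequencies are recomputed from the counts unless the
#' counts are all zero, in which case supplied frequencies are kept.
#'
#' @param junction_aa character vector of CDR3beta amino-acid sequences.
#' @param v_call,j_call TRBV/TRBJ gene names (IMGT style, allele suffix
#'   already stripped). `NA` allowed.
#' @param count non-negative integer read/template counts.
#' @param junction_nt optional nucleotide junctions.
#' @param frequency optional frequencies; recomputed from `count` when any
#'   count is positive.
#' @return a tibble with columns `junction_aa`, `junction_nt`, `v_call`,
#'   `j_call`, `count`, `frequency`.
#' @export
clonotype_table <- function(junction_aa, v_call = NA_character_,
                            j_call = NA_character_, count = 1L,
                            junction_nt = NA_character_,
                            frequency = NULL) {
  tbl <- tibble(
    junction_aa = as.character(junction_aa),
    junction_nt = as.character(junction_nt),
    v_call = as.character(v_call),
    j_call = as.character(j_call),
    count = as.numeric(count)
  )
  if (!is.null(frequency)) tbl$frequency <- as.numeric(frequency)
  validate_clonotypes(normalize_frequencies(tbl))
}

#' Recompute within-sample clonotype frequencies
#'
#' @param clonotypes a clonotype tibble.
#' @return the tibble with `frequency = count / sum(count)` (unchanged if
#'   total count is zero and frequencies are present; zero rows allowed).
#' @export
normalize_frequencies <- function(clonotypes) {
  if (nrow(clonotypes) == 0) {
    clonotypes$frequency <- numeric(0)
    return(clonotypes)
  }
  total <- sum(clonotypes$count)
  if (total > 0) {
    clonotypes$frequency <- clonotypes$count / total
  } else if (!"frequency" %in% names(clonotypes)) {
    clonotypes$frequency <- rep(0, nrow(clonotypes))
  }
  clonotypes
}

#' Validate a clonotype table against its invariants
#'
#' Junctions must be non-empty strings over the 20 amino-acid alphabet of
#' length at least 5, counts non-negative, frequencies in \[0, 1\].
#'
#' @param clonotypes a clonotype tibble.
#' @return the table, invisibly unchanged, or an error.
#' @export
validate_clonotypes <- function(clonotypes) {
  stopifnot(is.data.frame(clonotypes))
  required <- c("junction_aa", "v_call", "j_call", "count", "frequency")
  missing <- setdiff(required, names(clonotypes))
  if (length(missing) > 0) {
    abort(paste0("clonotype table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(clonotypes) == 0) return(clonotypes)
  ok_aa <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", clonotypes$junction_aa)
  if (!all(ok_aa)) {
    abort(paste0(sum(!ok_aa), " junction(s) contain non-amino-acid ",
                 "characters (stop codons, frameshifts?)"))
  }
  if (any(nchar(clonotypes$junction_aa) < 5)) {
    abort("junction_aa shorter than 5 residues")
  }
  if (any(clonotypes$count < 0)) abort("negative clonotype count")
  if (any(clonotypes$frequency < -1e-12 | clonotypes$frequency > 1 + 1e-12)) {
    abort("clonotype frequency outside [0, 1]")
  }
  clonotypes
}

#' Construct a repertoire sample
#'
#' One donor x condition clonotype repertoire: either an
#' antigen-stimulated sample (FVIII, OVA, the 18-peptide pool, KLH) or
#' the paired unstimulated CONTROL used for background subtraction.
#'
#' @param donor_id donor identifier.
#' @param antigen one of `r paste(ANTIGEN_LEVELS, collapse = ", ")`.
#' @param clonotypes a clonotype tibble (see [clonotype_table()]).
#' @return an object of class `repertoire_sample`.
#' @export
repertoire_sample <- function(donor_id, antigen, clonotypes) {
  antigen <- match.arg(antigen, ANTIGEN_LEVELS)
  clonotypes <- validate_clonotypes(normalize_frequencies(as_tibble(clonotypes)))
  structure(
    list(donor_id = as.character(donor_id), antigen = antigen,
         clonotypes = clonotypes),
    class = "repertoire_sample"
  )
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf("<repertoire_sample> donor %s, antigen %s: %d clonotypes\n",
              x$donor_id, x$antigen, nrow(x$clonotypes)))
  if (nrow(x$clonotypes) > 0) {
    print(head(dplyr::arrange(x$clonotypes, dplyr::desc(.data$frequency)), 5))
  }
  invisible(x)
}

#' Clonotype identity keys
#'
#' Within-donor operations key clonotypes on the triple
#' (junction_aa, v_call, j_call) (`"vjaa"`); cross-donor public-clonotype
#' analysis keys on the bare CDR3beta amino-acid string (`"aa"`), the form
#' in which public sequences are reported.
#'
#' @param clonotypes clonotype tibble.
#' @param key `"vjaa"` or `"aa"`.
#' @return character vector of keys, one per row.
#' @export
clonotype_key <- function(clonotypes, key = c("vjaa", "aa")) {
  key <- match.arg(key)
  if (key == "aa") return(clonotypes$junction_aa)
  paste(clonotypes$junction_aa, clonotypes$v_call, clonotypes$j_call,
        sep = "|")
}

#' Construct an ELISPOT plate result
#'
#' @param donor_id donor identifier.
#' @param antigen stimulating antigen.
#' @param lines tibble with columns `line_id`, `spots_stimulated`
#'   (mean of duplicate wells, with antigen), `spots_control` (without
#'   antigen) and optionally `positive`.
#' @param cells_per_well CD4 T cells seeded per well (the study used
#'   200,000).
#' @return object of class `plate_result`.
#' @export
plate_result <- function(donor_id, antigen, lines, cells_per_well = 200000L) {
  lines <- as_tibble(lines)
  required <- c("line_id", "spots_stimulated", "spots_control")
  missing <- setdiff(required, names(lines))
  if (length(missing) > 0) {
    abort(paste0("plate lines lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(lines$spots_stimulated < 0) || any(lines$spots_control < 0)) {
    abort("spot counts must be non-negative")
  }
  cells_per_well <- as.integer(cells_per_well)
  if (is.na(cells_per_well) || cells_per_well <= 0) {
    abort("cells_per_well must be a positive integer")
  }
  if (!"positive" %in% names(lines)) lines$positive <- NA
  antigen <- match.arg(antigen, ANTIGEN_LEVELS)
  structure(
    list(donor_id = as.character(donor_id), antigen = antigen,
         lines = lines, cells_per_well = cells_per_well),
    class = "plate_result"
  )
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf(
    "<plate_result> donor %s, antigen %s: %d lines, %d cells/well\n",
    x$donor_id, x$antigen, nrow(x$lines), x$cells_per_well))
  invisible(x)
}

#' Validate an HLA percentile-rank score matrix
#'
#' Rows are peptides, columns HLA class II alleles, entries NetMHCIIpan
#' style percentile ranks in \[0, 100\] (lower = stronger predicted
#' binding). No missing cells allowed.
#'
#' @param scores numeric matrix with dimnames.
#' @return the matrix, or an error.
#' @export
validate_score_matrix <- function(scores) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    abort("score matrix needs peptide rownames and allele colnames")
  }
  if (anyNA(scores)) abort("score matrix contains missing cells")
  if (any(scores < 0 | scores > 100)) {
    abort("percentile ranks must lie in [0, 100]")
  }
  scores
}

#' Validate a donor x peptide response matrix
#'
#' Entries are counts of antigen-specific (ELISPOT-positive) T-cell lines
#' per donor and peptide; non-negative integers.
#'
#' @param responses numeric matrix with dimnames (rows donors, columns
#'   peptides).
#' @return the matrix, or an error.
#' @export
validate_response_matrix <- function(responses) {
  stopifnot(is.matrix(responses), is.numeric(responses))
  if (is.null(rownames(responses)) || is.null(colnames(responses))) {
    abort("response matrix needs donor rownames and peptide colnames")
  }
  if (anyNA(responses)) abort("response matrix contains missing cells")
  if (any(responses < 0)) abort("negative response count")
  if (any(responses != round(responses))) {
    abort("response counts must be integers")
  }
  responses
}
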