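#' Read an AIRR Rearrangement TSV into a repertoire sample
#'
#' Expects at minimum the AIRR columns `junction_aa`, `v_call`, `j_call`
#' and `duplicate_count`. Rows whose junction is empty or contains
#' non-amino-acid characters (out-of-frame junctions, stop codons) are
#' dropped and counted; the count is attached as attribute `n_rejected`
#' and reported via a message. Frequencies are computed as
#' count / total count.
#'
#' @param path path to the TSV file.
#' @param donor_id,antigen sample annotations; defaults are parsed from
#'   nothing and fall back to the file name / FVIII.
#' @return a [repertoire_sample()] with attribute `n_rejected`.
#' @export
read_airr <- function(path, donor_id = NULL, antigen = "FVIII") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("junction_aa", "v_call", "j_call", "duplicate_count")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("AIRR file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  build_sample_from_columns(
    junction_aa = raw$junction_aa,
    junction_nt = if ("junction" %in% names(raw)) raw$junction else NA,
    v_call = raw$v_call, j_call = raw$j_call,
    count = suppressWarnings(as.numeric(raw$duplicate_count)),
    donor_id = donor_id %||% sub("\\.[^.]*$", "", basename(path)),
    antigen = antigen
  )
}

#' Read a clonotype export in AIRR or MiXCR dialect
#'
#' The `mixcr` dialect maps the MiXCR clone-table columns `aaSeqCDR3`,
#' `allVHitsWithScore`, `allJHitsWithScore` and `cloneCount`; gene calls
#' are truncated to gene level (the best hit is taken and the allele
#' suffix and alignment score, e.g. `"*00(123)"`, are stripped, so
#' `"TRBV7-4*00(123)"` becomes `"TRBV7-4"`). The `airr` dialect is
#' identical to [read_airr()].
#'
#' @inheritParams read_airr
#' @param dialect `"airr"` or `"mixcr"`.
#' @return a [repertoire_sample()] with attribute `n_rejected`.
#' @export
read_clonotype_export <- function(path, dialect = c("airr", "mixcr"),
                                  donor_id = NULL, antigen = "FVIII") {
  dialect <- match.arg(dialect)
  if (dialect == "airr") return(read_airr(path, donor_id, antigen))
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("aaSeqCDR3", "allVHitsWithScore", "allJHitsWithScore",
                "cloneCount")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("MiXCR export lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  build_sample_from_columns(
    junction_aa = raw$aaSeqCDR3,
    junction_nt = if ("nSeqCDR3" %in% names(raw)) raw$nSeqCDR3 else NA,
    v_call = strip_allele(raw$allVHitsWithScore),
    j_call = strip_allele(raw$allJHitsWithScore),
    count = suppressWarnings(as.numeric(raw$cloneCount)),
    donor_id = donor_id %||% sub("\\.[^.]*$", "", basename(path)),
    antigen = antigen
  )
}

# Truncate "TRBV7-4*00(123.4),TRBV7-2*00(80)" to the best hit's gene name.
strip_allele <- function(x) {
  first <- sub(",.*$", "", x)
  sub("\\*.*$", "", first)
}

build_sample_from_columns <- function(junction_aa, junction_nt, v_call,
                                      j_call, count, donor_id, antigen) {
  junction_aa <- as.character(junction_aa)
  ok <- !is.na(junction_aa) &
    grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", junction_aa) &
    nchar(junction_aa) >= 5 &
    !is.na(count) & count >= 0
  ok[is.na(ok)] <- FALSE
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    inform(sprintf("dropped %d malformed clonotype row(s)", n_rejected))
  }
  tbl <- clonotype_table(
    junction_aa = junction_aa[ok],
    v_call = as.character(v_call)[ok],
    j_call = as.character(j_call)[ok],
    count = count[ok],
    junction_nt = as.character(junction_nt)[if (length(junction_nt) == 1)
      rep(1, sum(ok)) else ok]
  )
  out <- repertoire_sample(donor_id, antigen, tbl)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a repertoire sample as an AIRR Rearrangement TSV
#'
#' @param sample a [repertoire_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(sample, path) {
  stopifnot(inherits(sample, "repertoire_sample"))
  cl <- sample$clonotypes
  readr::write_tsv(
    tibble(junction_aa = cl$junction_aa,
           junction = cl$junction_nt,
           v_call = cl$v_call, j_call = cl$j_call,
           duplicate_count = cl$count),
    path
  )
  invisible(path)
}

#' Parse a peptide table
#'
#' Reads 20-mer candidate T cell epitopes in the study's tabular form:
#' a position token `P<start>-<end>` (1-based inclusive coordinates on
#' the FVIII precursor, signal peptide included), the peptide sequence
#' and the FVIII domain label (A1, a1, A2, A3, B, C1, C2, or a compound
#' such as `"C1/C2"`). Without a `path` the packaged table of the 18
#' immunodominant FVIII peptides is returned.
#'
#' @param path TSV with columns `peptide_id`, `sequence`, `domain`
#'   (default: the packaged 18-peptide fixture).
#' @return tibble with columns `peptide_id`, `start`, `end`, `sequence`,
#'   `domain`.
#' @export
parse_peptide_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fviii_peptides_table1.tsv",
                                package = "repdominance", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("peptide_id", "sequence", "domain")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("peptide table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- regmatches(raw$peptide_id,
                  regexec("^P([0-9]+)-([0-9]+)$", raw$peptide_id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("unparseable position token: ",
                 paste(raw$peptide_id[bad], collapse = ", ")))
  }
  out <- tibble(
    peptide_id = raw$peptide_id,
    start = as.integer(vapply(m, `[`, "", 2)),
    end = as.integer(vapply(m, `[`, "", 3)),
    sequence = toupper(raw$sequence),
    domain = raw$domain
  )
  span <- out$end - out$start + 1L
  mism <- span != nchar(out$sequence) | nchar(out$sequence) != 20L
  if (any(mism)) {
    abort(paste0("coordinate span and sequence length disagree (or not a ",
                 "20-mer) for: ", paste(out$peptide_id[mism], collapse = ", ")))
  }
  if (any(out$start < 1L)) abort("peptide start before residue 1")
  out
}

#' Load the packaged FVIII precursor reference
#'
#' The packaged reference is a *synthetic scaffold*: a 2351-residue
#' sequence in which the 18 packaged peptides are embedded at their
#' stated precursor coordinates and all other positions carry
#' deterministic filler residues. It supports coordinate validation of
#' the packaged peptide set; it is not the true P00451 sequence outside
#' the peptide windows.
#'
#' @param path FASTA path (default: the packaged scaffold).
#' @return a single amino-acid string.
#' @export
load_reference_sequence <- function(path = NULL) {
  path <- path %||% system.file("extdata", "P00451_synthetic_scaffold.fasta",
                                package = "repdominance", mustWork = TRUE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1) abort("reference FASTA holds no sequence")
  as.character(set[[1]])
}

#' Validate peptides against a reference sequence
#'
#' For each peptide, compares `substr(reference, start, end)` with the
#' stated sequence. Peptides extending past the end of the reference are
#' flagged out-of-range rather than raising an error.
#'
#' @param peptides tibble from [parse_peptide_table()].
#' @param reference amino-acid string (default: packaged scaffold via
#'   [load_reference_sequence()]).
#' @return the peptide tibble with logical columns `in_range` and
#'   `matches_reference`, plus attribute `n_mismatch`.
#' @export
validate_peptides_against_reference <- function(peptides, reference = NULL) {
  reference <- reference %||% load_reference_sequence()
  ref_len <- nchar(reference)
  in_range <- peptides$start >= 1L & peptides$end <= ref_len
  got <- ifelse(in_range,
                substr(rep(reference, nrow(peptides)),
                       peptides$start, peptides$end),
                NA_character_)
  matches <- !is.na(got) & got == peptides$sequence
  out <- peptides
  out$in_range <- in_range
  out$matches_reference <- matches
  attr(out, "n_mismatch") <- sum(!matches)
  out
}

#' Read / write peptide-by-allele and donor-by-peptide matrices
#'
#' CSV layout: first column holds row names (peptides for a score
#' matrix, donors for a response matrix), remaining columns one per
#' allele / peptide. `type` selects the validator applied after reading.
#'
#' @param path CSV path.
#' @param type `"score"` (percentile ranks in \[0,100\]) or `"response"`
#'   (non-negative integer counts).
#' @return a validated numeric matrix.
#' @export
read_matrix <- function(path, type = c("score", "response")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  mat <- as.matrix(raw)
  storage.mode(mat) <- "numeric"
  if (type == "score") validate_score_matrix(mat) else
    validate_response_matrix(mat)
}

#' @rdname read_matrix
#' @param mat matrix to write.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat))
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
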