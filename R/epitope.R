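#' Select promiscuous MHC class II binder peptides
#'
#' A peptide is a predicted promiscuous binder when its percentile rank
#' is strictly below `threshold` on at least `min_alleles` HLA class II
#' alleles (the selection that yielded the study's 63 candidate 20-mers:
#' below the 10th percentile on at least 4 of 15 preponderant HLA-DR
#' alleles). "Below" is read strictly; a rank exactly equal to the
#' threshold does not count.
#'
#' @param scores peptide x allele percentile-rank matrix, see
#'   [validate_score_matrix()].
#' @param threshold percentile cut in (0, 100\] (default 10).
#' @param min_alleles minimum number of alleles under the cut
#'   (default 4).
#' @return character vector of selected peptide ids (row order
#'   preserved).
#' @export
select_promiscuous <- function(scores, threshold = 10, min_alleles = 4) {
  scores <- validate_score_matrix(scores)
  if (threshold <= 0 || threshold > 100) {
    abort("threshold must lie in (0, 100]")
  }
  if (min_alleles < 1) abort("min_alleles must be >= 1")
  hits <- rowSums(scores < threshold)
  rownames(scores)[hits >= min_alleles]
}

# "P<start>-<end>" -> start coordinate, NA when not in that form.
peptide_start_position <- function(peptide_id) {
  m <- regexec("^P([0-9]+)-[0-9]+$", peptide_id)
  vapply(regmatches(peptide_id, m), function(g) {
    if (length(g) == 2) as.numeric(g[2]) else NA_real_
  }, numeric(1))
}

#' Rank epitopes by immunodominance and donor coverage
#'
#' Orders peptides by total positive T-cell lines (response intensity)
#' descending, breaking ties by responding-donor count descending and
#' then by peptide position ascending (parsed from `P<start>-<end>`
#' ids; lexicographic id otherwise). Reports, at each rank, the
#' cumulative fraction of the total response and the cumulative
#' fraction of donors covered (a donor is covered by any peptide with
#' at least one positive line), and the two headline sizes:
#' `k_response`, the smallest prefix carrying at least
#' `response_target` of the total response, and `k_coverage`, the
#' smallest prefix covering all responding donors.
#'
#' @param responses donor x peptide count matrix, see
#'   [validate_response_matrix()].
#' @param response_target target cumulative response fraction
#'   (default 0.5).
#' @return list of class `epitope_ranking`: `ranking` tibble
#'   (`rank`, `peptide_id`, `total_lines`, `n_donors_responding`,
#'   `cum_response_fraction`, `cum_donor_coverage`), `k_response`,
#'   `k_coverage` (NA if full coverage is never reached), `n_donors`,
#'   `grand_total`.
#' @export
rank_epitopes <- function(responses, response_target = 0.5) {
  responses <- validate_response_matrix(responses)
  if (response_target <= 0 || response_target > 1) {
    abort("response_target must lie in (0, 1]")
  }
  grand_total <- sum(responses)
  if (grand_total == 0) abort("all-zero response matrix")
  totals <- colSums(responses)
  donors_resp <- colSums(responses > 0)
  pos <- peptide_start_position(colnames(responses))
  ord <- order(-totals, -donors_resp,
               ifelse(is.na(pos), Inf, pos),
               colnames(responses))
  responses <- responses[, ord, drop = FALSE]
  totals <- totals[ord]
  donors_resp <- donors_resp[ord]
  cum_resp <- unname(cumsum(totals)) / grand_total
  covered <- matrix(FALSE, nrow(responses), ncol(responses))
  acc <- rep(FALSE, nrow(responses))
  coverage <- numeric(ncol(responses))
  for (r in seq_len(ncol(responses))) {
    acc <- acc | responses[, r] > 0
    coverage[r] <- mean(acc)
  }
  k_response <- which(cum_resp >= response_target - 1e-12)[1]
  k_coverage <- which(coverage >= 1 - 1e-12)[1]
  structure(
    list(
      ranking = tibble(
        rank = seq_len(ncol(responses)),
        peptide_id = colnames(responses),
        total_lines = as.numeric(totals),
        n_donors_responding = as.integer(donors_resp),
        cum_response_fraction = cum_resp,
        cum_donor_coverage = coverage
      ),
      k_response = as.integer(k_response),
      k_coverage = if (is.na(k_coverage)) NA_integer_
                   else as.integer(k_coverage),
      n_donors = nrow(responses),
      grand_total = grand_total
    ),
    class = "epitope_ranking"
  )
}

#' @export
print.epitope_ranking <- function(x, ...) {
  cat(sprintf(
    "<epitope_ranking> %d peptides, %d donors, %g positive lines\n",
    nrow(x$ranking), x$n_donors, x$grand_total))
  cat(sprintf("  k_response = %d, k_coverage = %s\n", x$k_response,
              ifelse(is.na(x$k_coverage), "not reached", x$k_coverage)))
  invisible(x)
}

#' Count selected peptides per FVIII domain
#'
#' @param peptides tibble from [parse_peptide_table()].
#' @param selected_ids peptide ids to summarise; all must exist in the
#'   table. Compound domain labels (e.g. `"C1/C2"`) count once under
#'   the compound label.
#' @return named integer vector, domain -> count (empty for an empty
#'   selection).
#' @export
domain_summary <- function(peptides, selected_ids) {
  unknown <- setdiff(selected_ids, peptides$peptide_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown peptide id(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(selected_ids) == 0) return(integer(0))
  dom <- peptides$domain[match(selected_ids, peptides$peptide_id)]
  tab <- table(dom)
  setNames(as.integer(tab), names(tab))
}
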