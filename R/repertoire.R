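#' Remove culture background clonotypes
#'
#' Clonotypes shared between an antigen-stimulated sample and its paired
#' unstimulated control reflect culture expansion rather than antigen
#' specificity; every clonotype whose key occurs in the control is
#' removed and the survivors' frequencies are renormalized to sum to 1.
#'
#' @param stim antigen-stimulated [repertoire_sample()].
#' @param ctrl paired unstimulated control from the same donor.
#' @param key clonotype identity, see [clonotype_key()].
#' @return the filtered sample (possibly empty) with attribute
#'   `n_removed`.
#' @export
subtract_background <- function(stim, ctrl, key = c("vjaa", "aa")) {
  key <- match.arg(key)
  stopifnot(inherits(stim, "repertoire_sample"),
            inherits(ctrl, "repertoire_sample"))
  if (!identical(stim$donor_id, ctrl$donor_id)) {
    abort("background subtraction requires samples from the same donor")
  }
  keep <- !(clonotype_key(stim$clonotypes, key) %in%
              clonotype_key(ctrl$clonotypes, key))
  n_removed <- sum(!keep)
  out <- repertoire_sample(stim$donor_id, stim$antigen,
                           stim$clonotypes[keep, , drop = FALSE])
  attr(out, "n_removed") <- n_removed
  out
}

#' Gini-Simpson clonality index
#'
#' \eqn{1 - \sum_i p_i^2} over clonotype frequencies: 0 for a
#' monoclonal sample, approaching 1 for a highly diverse one.
#'
#' @param sample a [repertoire_sample()] or clonotype tibble with at
#'   least one clonotype.
#' @return a number in \[0, 1\].
#' @export
gini_simpson <- function(sample) {
  p <- sample_frequencies(sample)
  if (length(p) == 0) abort("Gini-Simpson index undefined on empty sample")
  1 - sum(p^2)
}

sample_frequencies <- function(sample) {
  cl <- if (inherits(sample, "repertoire_sample")) sample$clonotypes
        else as_tibble(sample)
  cl$frequency
}

sample_clonotypes <- function(sample) {
  if (inherits(sample, "repertoire_sample")) sample$clonotypes
  else validate_clonotypes(as_tibble(sample))
}

#' Clonotypes covering the top fraction of the repertoire
#'
#' Sorts clonotypes by frequency descending (ties broken
#' lexicographically on the junction sequence for determinism) and
#' returns the smallest prefix whose cumulative frequency reaches
#' `fraction` — e.g. the "top 50%" dominance statistic.
#'
#' @param sample a [repertoire_sample()] or clonotype tibble.
#' @param fraction target cumulative frequency in (0, 1\].
#' @return list with `clonotypes` (the prefix tibble) and `k` (its size).
#' @export
top_fraction <- function(sample, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  cl <- sample_clonotypes(sample)
  if (nrow(cl) == 0) abort("top_fraction undefined on empty sample")
  ord <- order(-cl$frequency, cl$junction_aa)
  cl <- cl[ord, , drop = FALSE]
  cum <- cumsum(cl$frequency)
  k <- which(cum >= fraction - 1e-12)[1]
  if (is.na(k)) k <- nrow(cl)  # degenerate: frequencies not normalized
  list(clonotypes = cl[seq_len(k), , drop = FALSE], k = as.integer(k))
}

#' CDR3 length distribution
#'
#' @param clonotypes a [repertoire_sample()] or clonotype tibble.
#' @param weighting `"unweighted"` counts each clonotype once;
#'   `"frequency"` weights by clonal frequency.
#' @return tibble with columns `length` and `fraction` (sums to 1).
#' @export
length_distribution <- function(clonotypes,
                                weighting = c("unweighted", "frequency")) {
  weighting <- match.arg(weighting)
  cl <- sample_clonotypes(clonotypes)
  if (nrow(cl) == 0) abort("length distribution undefined on empty input")
  w <- if (weighting == "frequency") cl$frequency else rep(1, nrow(cl))
  len <- nchar(cl$junction_aa)
  agg <- tapply(w, len, sum)
  tibble(length = as.integer(names(agg)),
         fraction = as.numeric(agg) / sum(w))
}

#' Deterministic anchor alignment of CDR3 sequences
#'
#' Positional composition summaries need sequences of different lengths
#' on a common coordinate system. This scheme exploits the strongly
#' conserved junction ends: the first `anchor` and last `anchor`
#' residues (default 4, covering the C...F anchors and their immediate
#' neighbours) are fixed at the block edges, and the interior residues
#' are centred between them with gap (`-`) padding to the longest
#' interior. Block width is therefore `2 * anchor + max interior
#' length`. Sequences shorter than `2 * anchor` are left-anchored with
#' right gaps and flagged. The result is a positional summary device,
#' deterministic by construction, not a homology claim; a block produced
#' by an external aligner can be passed directly to
#' [composition_profile()] instead.
#'
#' @param sequences character vector of CDR3 amino-acid sequences.
#' @param anchor residues fixed at each edge (default 4).
#' @return character vector of gapped rows (equal width), with attribute
#'   `short` flagging rows shorter than `2 * anchor`.
#' @export
align_cdr3 <- function(sequences, anchor = 4L) {
  if (length(sequences) == 0 || any(nchar(sequences) == 0)) {
    abort("align_cdr3 requires non-empty sequences")
  }
  anchor <- as.integer(anchor)
  len <- nchar(sequences)
  short <- len < 2L * anchor
  interior_len <- pmax(len - 2L * anchor, 0L)
  width <- 2L * anchor + max(interior_len, 0L)
  pad <- function(n) strrep("-", n)
  rows <- character(length(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    if (short[i]) {
      rows[i] <- paste0(s, pad(width - len[i]))
    } else {
      left <- substr(s, 1L, anchor)
      right <- substr(s, len[i] - anchor + 1L, len[i])
      inner <- if (interior_len[i] > 0)
        substr(s, anchor + 1L, len[i] - anchor) else ""
      gaps <- width - 2L * anchor - interior_len[i]
      lg <- gaps %/% 2L
      rows[i] <- paste0(left, pad(lg), inner, pad(gaps - lg), right)
    }
  }
  structure(rows, short = short)
}

#' Positional amino-acid and chemical-class composition
#'
#' Per-position relative amino-acid frequencies over an aligned block
#' (gaps excluded from each position's denominator), optionally weighted
#' by clonal frequency, plus the same table collapsed onto the five
#' chemical classes (hydrophobic, polar, basic, acidic, neutral).
#'
#' @param aligned gapped rows from [align_cdr3()] (equal width).
#' @param weights optional non-negative weights, one per row.
#' @return list of class `composition_profile`: `aa` (positions x 20
#'   matrix), `classes` (positions x 5), `alignment_length`.
#' @export
composition_profile <- function(aligned, weights = NULL) {
  if (length(aligned) == 0) abort("composition profile of empty input")
  width <- unique(nchar(aligned))
  if (length(width) != 1) abort("aligned rows must have equal width")
  weights <- weights %||% rep(1, length(aligned))
  if (length(weights) != length(aligned) || any(weights < 0)) {
    abort("weights must be non-negative, one per sequence")
  }
  chars <- matrix(unlist(strsplit(aligned, "")), ncol = width, byrow = TRUE)
  aa <- matrix(0, nrow = width, ncol = length(AA_ALPHABET),
               dimnames = list(NULL, AA_ALPHABET))
  for (pos in seq_len(width)) {
    col <- chars[, pos]
    keep <- col != "-"
    if (!any(keep)) next
    tot <- tapply(weights[keep], factor(col[keep], levels = AA_ALPHABET), sum)
    tot[is.na(tot)] <- 0
    denom <- sum(tot)
    if (denom > 0) aa[pos, ] <- tot / denom
  }
  classes <- vapply(AA_CLASSES,
                    function(set) rowSums(aa[, set, drop = FALSE]),
                    numeric(width))
  structure(list(aa = aa, classes = classes, alignment_length = width),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %d aligned positions\n",
              x$alignment_length))
  invisible(x)
}

#' Hydrophobic-doublet fraction at junction positions 6-7
#'
#' Fraction of clonotypes whose residues at positions 6 and 7 (1-based
#' from the conserved cysteine) are both hydrophobic
#' (`r paste(HYDROPHOBIC_AA, collapse = "")`), a reported signature of
#' self-reactive CD4 T cell receptors. Sequences shorter than 7 residues
#' are excluded and counted in attribute `n_excluded`.
#'
#' @inheritParams length_distribution
#' @return a fraction in \[0, 1\] (NaN when no sequence is long enough).
#' @export
hydrophobic_p6p7_fraction <- function(clonotypes,
                                      weighting = c("unweighted",
                                                    "frequency")) {
  weighting <- match.arg(weighting)
  cl <- sample_clonotypes(clonotypes)
  long_enough <- nchar(cl$junction_aa) >= 7
  n_excluded <- sum(!long_enough)
  cl <- cl[long_enough, , drop = FALSE]
  w <- if (weighting == "frequency") cl$frequency else rep(1, nrow(cl))
  p6 <- substr(cl$junction_aa, 6, 6)
  p7 <- substr(cl$junction_aa, 7, 7)
  hit <- p6 %in% HYDROPHOBIC_AA & p7 %in% HYDROPHOBIC_AA
  out <- if (sum(w) > 0) sum(w[hit]) / sum(w) else NaN
  structure(out, n_excluded = n_excluded)
}

#' V/J gene usage and pairing
#'
#' Gene usage fractions and the joint V-J pairing distribution,
#' frequency-weighted by default (usage "of the total repertoire" is a
#' mass-weighted statement); clonotype-count weighting is available.
#' Clonotypes lacking either gene call are excluded and counted; the
#' remaining mass is renormalized.
#'
#' @inheritParams length_distribution
#' @param weighting `"frequency"` (default) or `"unweighted"`.
#' @return list of class `vj_pairing`: tibbles `v_usage` (`v_call`,
#'   `fraction`), `j_usage`, `pairing` (`v_call`, `j_call`, `fraction`),
#'   and `n_excluded`.
#' @export
vj_pairing <- function(clonotypes,
                       weighting = c("frequency", "unweighted")) {
  weighting <- match.arg(weighting)
  cl <- sample_clonotypes(clonotypes)
  has_genes <- !is.na(cl$v_call) & !is.na(cl$j_call) &
    cl$v_call != "" & cl$j_call != ""
  n_excluded <- sum(!has_genes)
  cl <- cl[has_genes, , drop = FALSE]
  if (nrow(cl) == 0) abort("no clonotypes with V and J calls")
  w <- if (weighting == "frequency") cl$frequency else rep(1, nrow(cl))
  if (sum(w) <= 0) abort("total weight is zero")
  w <- w / sum(w)
  usage <- function(gene) {
    agg <- tapply(w, gene, sum)
    tibble(gene = names(agg), fraction = as.numeric(agg)) |>
      dplyr::arrange(dplyr::desc(.data$fraction), .data$gene)
  }
  v_usage <- usage(cl$v_call); names(v_usage)[1] <- "v_call"
  j_usage <- usage(cl$j_call); names(j_usage)[1] <- "j_call"
  pair_key <- paste(cl$v_call, cl$j_call, sep = "\r")
  agg <- tapply(w, pair_key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  pairing <- tibble(
    v_call = vapply(parts, `[`, "", 1),
    j_call = vapply(parts, `[`, "", 2),
    fraction = as.numeric(agg)
  ) |> dplyr::arrange(dplyr::desc(.data$fraction), .data$v_call,
                      .data$j_call)
  structure(list(v_usage = v_usage, j_usage = j_usage, pairing = pairing,
                 n_excluded = n_excluded),
            class = "vj_pairing")
}

#' @export
print.vj_pairing <- function(x, ...) {
  cat(sprintf("<vj_pairing> %d V genes, %d J genes, %d pairs\n",
              nrow(x$v_usage), nrow(x$j_usage), nrow(x$pairing)))
  invisible(x)
}

#' Clonotypes shared between two samples
#'
#' @param sample_a,sample_b [repertoire_sample()] objects or clonotype
#'   tibbles.
#' @param key clonotype identity, see [clonotype_key()]; cross-sample
#'   comparisons default to the bare CDR3 sequence.
#' @return character vector of shared keys, sorted.
#' @export
shared_clonotypes <- function(sample_a, sample_b, key = c("aa", "vjaa")) {
  key <- match.arg(key)
  a <- clonotype_key(sample_clonotypes(sample_a), key)
  b <- clonotype_key(sample_clonotypes(sample_b), key)
  sort(intersect(a, b))
}

#' Public clonotypes across donors
#'
#' A public clonotype is a CDR3beta amino-acid sequence observed in at
#' least `min_donors` different donors' repertoires. For each, the
#' sharing degree, the per-donor frequencies and the maximum per-donor
#' frequency are reported, sorted by sharing degree then maximum
#' frequency, both descending (ties lexicographic on the sequence).
#'
#' @param samples named list of [repertoire_sample()] objects (or
#'   clonotype tibbles), one per donor; names are donor ids.
#' @param min_donors minimum number of donors (>= 2).
#' @return tibble with columns `junction_aa`, `sharing_degree`, `donors`
#'   (list), `frequencies` (list, parallel to `donors`),
#'   `max_frequency`.
#' @export
public_clonotypes <- function(samples, min_donors = 2L) {
  if (length(samples) < 2) abort("public clonotype analysis needs >= 2 donors")
  if (min_donors < 2) abort("min_donors must be >= 2")
  donor_ids <- names(samples) %||% as.character(seq_along(samples))
  if (is.null(names(samples))) names(samples) <- donor_ids
  per_donor <- purrr::imap(samples, function(s, id) {
    cl <- sample_clonotypes(s)
    if (nrow(cl) == 0) {
      return(tibble(junction_aa = character(), donor_id = character(),
                    frequency = numeric()))
    }
    # a donor counts once per sequence; mass summed over V/J variants
    agg <- tapply(cl$frequency, cl$junction_aa, sum)
    tibble(junction_aa = names(agg), donor_id = id,
           frequency = as.numeric(agg))
  })
  all <- dplyr::bind_rows(per_donor)
  if (nrow(all) == 0) return(empty_public_table())
  out <- all |>
    dplyr::group_by(.data$junction_aa) |>
    dplyr::summarise(
      sharing_degree = dplyr::n_distinct(.data$donor_id),
      donors = list(.data$donor_id),
      frequencies = list(.data$frequency),
      max_frequency = max(.data$frequency),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$sharing_degree >= min_donors) |>
    dplyr::arrange(dplyr::desc(.data$sharing_degree),
                   dplyr::desc(.data$max_frequency), .data$junction_aa)
  if (nrow(out) == 0) empty_public_table() else out
}

empty_public_table <- function() {
  tibble(junction_aa = character(), sharing_degree = integer(),
         donors = list(), frequencies = list(), max_frequency = numeric())
}
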