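#' ELISPOT positivity call for a T-cell line
#'
#' A line is antigen-specific when its spot count with antigen is at
#' least `fold` times the count without antigen AND exceeds it by at
#' least `min_diff` spots. With a zero control the fold condition is
#' treated as satisfied (any positive count is infinitely many folds
#' above zero); the absolute floor still gates plate noise.
#'
#' @param spots_stimulated,spots_control non-negative spot counts (means
#'   of duplicate wells); vectorized.
#' @param fold fold-change threshold (default 2).
#' @param min_diff minimum absolute spot excess (default 25).
#' @return logical vector.
#' @examples
#' call_positive(60, 25)   # TRUE: 60 >= 50 and 35 >= 25
#' call_positive(300, 200) # FALSE: 300 < 400
#' @export
call_positive <- function(spots_stimulated, spots_control,
                          fold = 2, min_diff = 25) {
  if (any(spots_stimulated < 0, na.rm = TRUE) ||
      any(spots_control < 0, na.rm = TRUE)) {
    abort("spot counts must be non-negative")
  }
  (spots_stimulated >= fold * spots_control) &
    (spots_stimulated - spots_control >= min_diff)
}

#' Limiting-dilution precursor-frequency estimate
#'
#' Under the Poisson model for specific precursors seeded across wells,
#' the fraction of non-responding lines estimates the zero-class
#' probability, giving
#' \deqn{f = -\ln\left(\frac{n_{total} - n_{positive}}{n_{total}}\right)
#'       / \text{cells per well}.}
#' The estimate is returned per million CD4 T cells. An all-positive
#' plate is saturated (log of zero) and raises an error.
#'
#' @param n_positive number of antigen-specific lines.
#' @param n_total total lines seeded.
#' @param cells_per_well CD4 T cells per well (the study used 200,000).
#' @return object of class `frequency_estimate`: a list with
#'   `n_positive`, `n_total`, `cells_per_well`, `frequency_per_million`.
#' @examples
#' precursor_frequency(69, 96, 200000) # ~6.3/M, rounds to 6
#' precursor_frequency(58, 96, 200000) # ~4.6/M, rounds to 5
#' @export
precursor_frequency <- function(n_positive, n_total, cells_per_well) {
  if (n_total <= 0) abort("n_total must be positive")
  if (n_positive < 0 || n_positive > n_total) {
    abort("n_positive must lie in [0, n_total]")
  }
  if (cells_per_well <= 0) abort("cells_per_well must be positive")
  if (n_positive == n_total) {
    abort(paste0("saturated plate (", n_positive, "/", n_total,
                 " positive): the limiting-dilution estimator is undefined"),
          class = "repdominance_saturation_error")
  }
  f <- -log((n_total - n_positive) / n_total) / cells_per_well * 1e6
  structure(
    list(n_positive = as.integer(n_positive),
         n_total = as.integer(n_total),
         cells_per_well = as.integer(cells_per_well),
         frequency_per_million = f),
    class = "frequency_estimate"
  )
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf(
    "<frequency_estimate> %d/%d positive lines at %d cells/well: %.2f/M (~%d cells/M)\n",
    x$n_positive, x$n_total, x$cells_per_well,
    x$frequency_per_million, round(x$frequency_per_million)))
  invisible(x)
}

#' Parametric bootstrap interval for the precursor frequency
#'
#' Resamples the positive-line count as
#' Binomial(`n_total`, `n_positive / n_total`), re-estimates the
#' frequency for each draw (saturated draws clipped to `n_total - 1`)
#' and returns the 2.5-97.5 percentile interval.
#'
#' @inheritParams precursor_frequency
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @return named numeric vector `c(low, high)` in cells per million.
#' @export
frequency_interval <- function(n_positive, n_total, cells_per_well,
                               n_boot = 2000, seed = 1) {
  if (n_boot < 100) abort("n_boot must be at least 100")
  est <- precursor_frequency(n_positive, n_total, cells_per_well)
  p_hat <- n_positive / n_total
  withr::with_seed(seed, {
    draws <- rbinom(n_boot, n_total, p_hat)
    draws <- pmin(draws, n_total - 1L)
    boot <- -log((n_total - draws) / n_total) / cells_per_well * 1e6
    q <- quantile(boot, c(0.025, 0.975), names = FALSE)
    c(low = q[1], high = q[2])
  })
}

#' Call positivity across a plate and estimate the precursor frequency
#'
#' Applies [call_positive()] to every line, then
#' [precursor_frequency()] to the tallies. A saturated plate (all lines
#' positive) keeps its positivity calls but carries `saturated = TRUE`
#' and no frequency estimate; an all-negative plate estimates zero.
#'
#' @param plate a [plate_result()].
#' @inheritParams call_positive
#' @return the plate with `lines$positive` filled, plus elements
#'   `n_positive`, `saturated` and `estimate` (a `frequency_estimate`
#'   or `NULL`).
#' @export
call_plate <- function(plate, fold = 2, min_diff = 25) {
  stopifnot(inherits(plate, "plate_result"))
  if (nrow(plate$lines) < 1) abort("plate has no lines")
  pos <- call_positive(plate$lines$spots_stimulated,
                       plate$lines$spots_control, fold, min_diff)
  plate$lines$positive <- pos
  n_pos <- sum(pos)
  n_tot <- length(pos)
  plate$n_positive <- n_pos
  plate$saturated <- n_pos == n_tot
  plate$estimate <- if (plate$saturated) NULL else
    precursor_frequency(n_pos, n_tot, plate$cells_per_well)
  plate
}

#' Aggregate precursor-frequency estimates across donors
#'
#' `"mean"` averages the per-donor estimates (the reporting convention
#' used for cross-donor summary values); `"pooled"` sums positives and
#' totals across donors and estimates once.
#'
#' @param estimates list of `frequency_estimate` objects.
#' @param method `"mean"` or `"pooled"`.
#' @return frequency in cells per million.
#' @export
aggregate_frequency <- function(estimates, method = c("mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(estimates) > 0,
            all(vapply(estimates, inherits, TRUE, "frequency_estimate")))
  if (method == "mean") {
    return(mean(vapply(estimates, `[[`, 1, "frequency_per_million")))
  }
  n_pos <- sum(vapply(estimates, `[[`, 1L, "n_positive"))
  n_tot <- sum(vapply(estimates, `[[`, 1L, "n_total"))
  cells <- unique(vapply(estimates, `[[`, 1L, "cells_per_well"))
  if (length(cells) != 1) {
    abort("pooled aggregation needs a common cells_per_well")
  }
  precursor_frequency(n_pos, n_tot, cells)$frequency_per_million
}
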