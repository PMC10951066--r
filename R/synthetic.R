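#' Configuration for the synthetic repertoire generator
#'
#' Defaults emulate the sequenced FVIII-specific repertoires: about 535
#' detected clonotypes per donor, a geometric clone-size decay
#' calibrated so roughly a dozen clonotypes cover half the repertoire
#' (Gini-Simpson near 0.97), CDR3 lengths 10-19 with the mode at 12-13,
#' strongly skewed V usage dominated by TRBV7-4 and TRBV7-3, and a
#' hydrophobic composition bias at the junction core.
#'
#' @param n_clonotypes clonotypes per sample.
#' @param clonality geometric decay rate `c` in (0, 1): ranked clone
#'   frequencies follow `p_r` proportional to `(1 - c)^r`. The top-k
#'   coverage of the untruncated law is `1 - (1 - c)^k`.
#' @param length_distribution named probability vector over CDR3 lengths
#'   (names are lengths, values sum to 1).
#' @param hydrophobic_bias excess probability mass in \[0, 1\] placed on
#'   hydrophobic residues at core positions (positions 5 to L-4).
#' @param v_usage,j_usage named probability vectors over TRBV/TRBJ genes.
#' @param n_public number of public sequences planted across donors.
#' @param n_background per-donor sequences planted in both the antigen
#'   and CONTROL sample (culture background).
#' @param total_reads template count scale per sample.
#' @param seed integer RNG seed.
#' @return list of class `repertoire_config`.
#' @export
repertoire_config <- function(n_clonotypes = 535L,
                              clonality = 0.052,
                              length_distribution = default_length_distribution(),
                              hydrophobic_bias = 0.2,
                              v_usage = default_v_usage(),
                              j_usage = default_j_usage(),
                              n_public = 0L,
                              n_background = 25L,
                              total_reads = 100000L,
                              seed = 1L) {
  cfg <- list(n_clonotypes = as.integer(n_clonotypes),
              clonality = clonality,
              length_distribution = length_distribution,
              hydrophobic_bias = hydrophobic_bias,
              v_usage = v_usage, j_usage = j_usage,
              n_public = as.integer(n_public),
              n_background = as.integer(n_background),
              total_reads = as.integer(total_reads),
              seed = as.integer(seed))
  if (cfg$n_clonotypes <= 0) abort("n_clonotypes must be positive")
  if (cfg$clonality <= 0 || cfg$clonality >= 1) {
    abort("clonality must lie in (0, 1)")
  }
  if (cfg$hydrophobic_bias < 0 || cfg$hydrophobic_bias > 1) {
    abort("hydrophobic_bias must lie in [0, 1]")
  }
  for (nm in c("length_distribution", "v_usage", "j_usage")) {
    p <- cfg[[nm]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(paste0(nm, " must be a named probability vector summing to 1"))
    }
  }
  if (cfg$n_public + cfg$n_background > cfg$n_clonotypes) {
    abort("n_public + n_background exceeds n_clonotypes")
  }
  structure(cfg, class = "repertoire_config")
}

#' @rdname repertoire_config
#' @export
default_length_distribution <- function() {
  setNames(c(0.04, 0.10, 0.22, 0.22, 0.14, 0.10, 0.07, 0.05, 0.04, 0.02),
           10:19)
}

#' @rdname repertoire_config
#' @export
default_v_usage <- function() {
  c("TRBV7-4" = 0.60, "TRBV7-3" = 0.25, "TRBV4-1" = 0.05,
    "TRBV12-3" = 0.05, "TRBV20-1" = 0.05)
}

#' @rdname repertoire_config
#' @export
default_j_usage <- function() {
  c("TRBJ1-2" = 0.30, "TRBJ2-7" = 0.20, "TRBJ2-5" = 0.16,
    "TRBJ2-1" = 0.10, "TRBJ1-1" = 0.09, "TRBJ2-2" = 0.08,
    "TRBJ1-5" = 0.07)
}

# Draw n CDR3beta sequences: conserved C...F anchors, interior residues
# from a composition with hydrophobic bias at core positions (5..L-4).
# `avoid` is a set of sequences that must not be duplicated.
gen_cdr3_sequences <- function(n, length_distribution, hydrophobic_bias,
                               avoid = character()) {
  if (n == 0) return(character(0))
  lengths <- as.integer(names(length_distribution))
  base <- rep(1 / 20, 20)
  hydro <- as.numeric(AA_ALPHABET %in% HYDROPHOBIC_AA) /
    length(HYDROPHOBIC_AA)
  core_probs <- (1 - hydrophobic_bias) * base + hydrophobic_bias * hydro
  draw_batch <- function(m) {
    L <- sample(lengths, m, replace = TRUE, prob = length_distribution)
    max_inner <- max(L) - 2L
    # residue pools for edge vs core positions; pick per cell by L
    edge <- matrix(sample(AA_ALPHABET, m * max_inner, replace = TRUE,
                          prob = base), m, max_inner)
    core <- matrix(sample(AA_ALPHABET, m * max_inner, replace = TRUE,
                          prob = core_probs), m, max_inner)
    vapply(seq_len(m), function(i) {
      inner_len <- L[i] - 2L
      full_pos <- seq_len(inner_len) + 1L
      is_core <- full_pos >= 5L & full_pos <= L[i] - 4L
      inner <- ifelse(is_core, core[i, seq_len(inner_len)],
                      edge[i, seq_len(inner_len)])
      paste0("C", paste(inner, collapse = ""), "F")
    }, character(1))
  }
  out <- character(0)
  seen <- avoid
  while (length(out) < n) {
    batch <- unique(draw_batch(n - length(out)))
    batch <- batch[!(batch %in% seen)]
    out <- c(out, batch)
    seen <- c(seen, batch)
  }
  out
}

# Ranked geometric clone frequencies, truncated and renormalized.
geometric_frequencies <- function(n, clonality) {
  p <- (1 - clonality)^(seq_len(n))
  p / sum(p)
}

# Draw full clones (junction + V/J). A planted clone keeps its gene
# calls wherever it re-appears: a background clone must be the same
# rearrangement in the antigen and CONTROL samples, and a public clone
# the same in every donor carrying it.
gen_clones <- function(n, config, avoid = character()) {
  tibble(
    junction_aa = gen_cdr3_sequences(n, config$length_distribution,
                                     config$hydrophobic_bias, avoid),
    v_call = sample(names(config$v_usage), n, replace = TRUE,
                    prob = config$v_usage),
    j_call = sample(names(config$j_usage), n, replace = TRUE,
                    prob = config$j_usage)
  )
}

#' Generate a multi-donor repertoire set with planted ground truth
#'
#' For each donor, an antigen-stimulated sample and a paired CONTROL
#' sample are generated. Ranked clone frequencies follow the geometric
#' law of the config; counts are the expected template counts at the
#' config's read scale (minimum 1). Planted structure:
#' * each of `n_public` public sequences is inserted into the antigen
#'   samples of a random subset of at least 2 donors;
#' * each donor receives `n_background` background sequences present in
#'   both its antigen and CONTROL sample (what background subtraction
#'   must remove).
#' All sequences are generated collision-free so the planted sets are
#' exactly recoverable. Deterministic for a fixed config seed.
#'
#' @param config a [repertoire_config()].
#' @param n_donors number of donors (>= 2 when `n_public > 0`).
#' @param antigen label for the stimulated samples.
#' @return list with `samples` (per donor: list `antigen`, `control`)
#'   and `truth` (list: `public` tibble of `junction_aa` + `donors`,
#'   `background` tibble of `donor_id` + `junction_aa`).
#' @export
gen_repertoire_set <- function(config, n_donors, antigen = "FVIII") {
  stopifnot(inherits(config, "repertoire_config"))
  if (n_donors < 1) abort("n_donors must be >= 1")
  if (config$n_public > 0 && n_donors < 2) {
    abort("planting public clonotypes needs >= 2 donors")
  }
  withr::with_seed(config$seed, {
    donor_ids <- sprintf("D%02d", seq_len(n_donors))
    public <- gen_clones(config$n_public, config)
    public_donors <- lapply(seq_len(config$n_public), function(i) {
      size <- sample(2:n_donors, 1)
      sort(sample(donor_ids, size))
    })
    reserved <- public$junction_aa
    background <- list()
    samples <- list()
    for (d in donor_ids) {
      bg <- gen_clones(config$n_background, config, avoid = reserved)
      reserved <- c(reserved, bg$junction_aa)
      background[[d]] <- bg
      pub_here <- public[vapply(public_donors,
                                function(ds) d %in% ds, TRUE), ,
                         drop = FALSE]
      samples[[d]] <- list(
        antigen = gen_one_sample(config, d, antigen,
                                 planted = dplyr::bind_rows(pub_here, bg),
                                 reserved = reserved),
        control = gen_one_sample(config, d, "CONTROL",
                                 planted = bg, reserved = reserved)
      )
    }
    truth <- list(
      public = tibble(junction_aa = public$junction_aa,
                      donors = public_donors),
      background = dplyr::bind_rows(lapply(donor_ids, function(d) {
        tibble(donor_id = d, junction_aa = background[[d]]$junction_aa)
      }))
    )
    list(samples = samples, truth = truth)
  })
}

# One sample: planted clones occupy random ranks of the geometric law.
gen_one_sample <- function(config, donor_id, antigen, planted, reserved) {
  n <- config$n_clonotypes
  free <- gen_clones(n - nrow(planted), config, avoid = reserved)
  clones <- dplyr::bind_rows(free, planted)
  ranks_planted <- sample(n, nrow(planted))
  ord <- integer(n)
  ord[ranks_planted] <- nrow(free) + seq_len(nrow(planted))
  ord[setdiff(seq_len(n), ranks_planted)] <- seq_len(nrow(free))
  clones <- clones[ord, , drop = FALSE]
  p <- geometric_frequencies(n, config$clonality)
  counts <- pmax(1, round(p * config$total_reads))
  repertoire_sample(donor_id, antigen,
                    clonotype_table(junction_aa = clones$junction_aa,
                                    v_call = clones$v_call,
                                    j_call = clones$j_call,
                                    count = counts))
}

#' Simulate an ELISPOT plate under the Poisson seeding model
#'
#' Each line receives `k ~ Binomial(cells_per_well, f)` specific
#' precursors (`f` the true per-cell frequency); its control well draws
#' from a Poisson baseline and its stimulated well from an independent
#' baseline draw plus, when `k > 0`, a Poisson signal. A noise-free
#' plate (`baseline_mean = 0`) makes positivity exactly equivalent to
#' well occupancy.
#'
#' @param true_frequency_per_million true precursor frequency in cells
#'   per million.
#' @param cells_per_well CD4 T cells seeded per well.
#' @param n_lines number of T-cell lines (wells).
#' @param spot_model list with `baseline_mean` (default 10) and
#'   `signal_mean` (default 100).
#' @param seed integer RNG seed.
#' @param donor_id,antigen plate annotations.
#' @return a [plate_result()] with attribute `truth` recording `f` and
#'   the per-line occupancy `k`.
#' @export
gen_elispot_plate <- function(true_frequency_per_million, cells_per_well,
                              n_lines, spot_model = list(), seed = 1L,
                              donor_id = "SIM", antigen = "FVIII") {
  if (true_frequency_per_million < 0) abort("frequency must be >= 0")
  if (n_lines < 1) abort("n_lines must be >= 1")
  baseline <- spot_model$baseline_mean %||% 10
  signal <- spot_model$signal_mean %||% 100
  f <- true_frequency_per_million / 1e6
  withr::with_seed(seed, {
    k <- rbinom(n_lines, cells_per_well, f)
    ctrl <- rpois(n_lines, baseline)
    stim <- rpois(n_lines, baseline) + ifelse(k > 0,
                                              rpois(n_lines, signal), 0)
    lines <- tibble(line_id = sprintf("L%03d", seq_len(n_lines)),
                    spots_stimulated = as.numeric(stim),
                    spots_control = as.numeric(ctrl))
    plate <- plate_result(donor_id, antigen, lines, cells_per_well)
    attr(plate, "truth") <- list(
      frequency_per_million = true_frequency_per_million, occupancy = k)
    plate
  })
}

#' Simulate an HLA percentile-rank matrix with planted promiscuity
#'
#' Planted promiscuous peptides receive percentile ranks strictly below
#' 10 on at least four alleles; every other peptide gets at most three
#' such alleles, so the standard selection rule (< 10 on >= 4 alleles)
#' recovers exactly the planted set.
#'
#' @param n_peptides,n_alleles matrix dimensions.
#' @param promiscuous_ids peptide ids to plant (subset of
#'   `P001..P<n>`, or indices).
#' @param seed integer RNG seed.
#' @return list with `scores` (validated matrix) and `truth`
#'   (`promiscuous_ids`).
#' @export
gen_score_matrix <- function(n_peptides, n_alleles, promiscuous_ids = NULL,
                             seed = 1L) {
  peptide_ids <- sprintf("P%03d", seq_len(n_peptides))
  allele_ids <- sprintf("HLA-DRB1*%02d:01", seq_len(n_alleles))
  if (is.numeric(promiscuous_ids)) {
    promiscuous_ids <- peptide_ids[promiscuous_ids]
  }
  promiscuous_ids <- promiscuous_ids %||% character(0)
  if (!all(promiscuous_ids %in% peptide_ids)) {
    abort("promiscuous_ids must be a subset of the peptide ids")
  }
  if (length(promiscuous_ids) > 0 && n_alleles < 4) {
    abort("planting promiscuity needs >= 4 alleles")
  }
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n_peptides * n_alleles, 15, 100),
                nrow = n_peptides,
                dimnames = list(peptide_ids, allele_ids))
    for (p in peptide_ids) {
      if (p %in% promiscuous_ids) {
        n_hit <- sample(4:n_alleles, 1)
        hits <- sample(n_alleles, n_hit)
        m[p, hits] <- stats::runif(n_hit, 0, 9.9)
      } else {
        n_hit <- sample(0:min(3, n_alleles), 1)
        if (n_hit > 0) {
          hits <- sample(n_alleles, n_hit)
          m[p, hits] <- stats::runif(n_hit, 0, 9.9)
        }
      }
    }
    list(scores = validate_score_matrix(m),
         truth = list(promiscuous_ids = sort(promiscuous_ids)))
  })
}

#' Simulate a donor x peptide response matrix with planted dominance
#'
#' The planted dominant peptide set carries at least `mass_fraction` of
#' the total positive-line count (each dominant peptide's total strictly
#' exceeds every non-dominant total) and together covers every donor.
#' Construction: the grand total `total_lines` is split into
#' `ceiling(mass_fraction * total_lines)` dominant counts (spread as
#' evenly as possible over the dominant peptides) and the remainder over
#' the others, capped below the smallest dominant total; each peptide's
#' total is then distributed over donors multinomially, with one
#' dominant line per donor pre-assigned to guarantee coverage.
#'
#' @param n_donors,n_peptides matrix dimensions.
#' @param dominant_ids peptide ids (or indices) to plant as dominant.
#' @param mass_fraction fraction of total response mass carried by the
#'   dominant set, in (0, 1).
#' @param total_lines grand total of positive T-cell lines (default
#'   emulates the mapping study's scale: ~870 lines over 16 donors).
#' @param seed integer RNG seed.
#' @return list with `responses` (validated matrix) and `truth`
#'   (`dominant_ids`, `mass_fraction`).
#' @export
gen_response_matrix <- function(n_donors, n_peptides, dominant_ids,
                                mass_fraction = 0.5, total_lines = 872L,
                                seed = 1L) {
  if (mass_fraction <= 0 || mass_fraction >= 1) {
    abort("mass_fraction must lie in (0, 1)")
  }
  donor_ids <- sprintf("D%02d", seq_len(n_donors))
  peptide_ids <- sprintf("P%03d", seq_len(n_peptides))
  if (is.numeric(dominant_ids)) dominant_ids <- peptide_ids[dominant_ids]
  if (length(dominant_ids) == 0 ||
      !all(dominant_ids %in% peptide_ids)) {
    abort("dominant_ids must be a non-empty subset of the peptide ids")
  }
  k_dom <- length(dominant_ids)
  dom_total <- as.integer(ceiling(mass_fraction * total_lines))
  if (dom_total < k_dom + n_donors) {
    abort("total_lines too small to plant the dominant set")
  }
  withr::with_seed(seed, {
    # per-dominant-peptide totals, as even as possible
    base <- dom_total %/% k_dom
    dom_totals <- rep(base, k_dom)
    extra <- dom_total - base * k_dom
    if (extra > 0) dom_totals[seq_len(extra)] <- base + 1L
    names(dom_totals) <- dominant_ids
    # non-dominant totals: strictly below the smallest dominant total
    others <- setdiff(peptide_ids, dominant_ids)
    rest_total <- total_lines - dom_total
    cap <- min(dom_totals) - 1L
    other_totals <- setNames(integer(length(others)), others)
    if (length(others) > 0 && rest_total > 0) {
      w <- stats::runif(length(others))
      alloc <- floor(rest_total * w / sum(w))
      # round-robin the remainder under the cap
      alloc <- pmin(alloc, cap)
      short <- rest_total - sum(alloc)
      i <- 1L
      while (short > 0 && any(alloc < cap)) {
        if (alloc[i] < cap) { alloc[i] <- alloc[i] + 1L; short <- short - 1L }
        i <- if (i == length(others)) 1L else i + 1L
      }
      other_totals[] <- alloc
    }
    m <- matrix(0L, n_donors, n_peptides,
                dimnames = list(donor_ids, peptide_ids))
    # guarantee donor coverage by the dominant set
    cover_pep <- sample(dominant_ids, n_donors, replace = TRUE)
    spent <- table(factor(cover_pep, levels = dominant_ids))
    for (i in seq_len(n_donors)) m[i, cover_pep[i]] <- 1L
    for (p in peptide_ids) {
      tot <- if (p %in% dominant_ids) {
        max(dom_totals[p] - as.integer(spent[p]), 0L)
      } else other_totals[p]
      if (tot > 0) {
        add <- as.integer(rmultinom(1, tot, rep(1, n_donors)))
        m[, p] <- m[, p] + add
      }
    }
    list(responses = validate_response_matrix(m),
         truth = list(dominant_ids = sort(dominant_ids),
                      mass_fraction = mass_fraction))
  })
}
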