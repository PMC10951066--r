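#' Assemble a pipeline run configuration
#'
#' All analysis thresholds default to the study's rules: ELISPOT
#' positivity at 2-fold and 25 spots, promiscuity at percentile < 10 on
#' >= 4 alleles, immunodominance at 50% of the total response, repertoire
#' dominance at the top 50%.
#'
#' @param repertoires named list (by donor) of lists with paths `stim`
#'   and `ctrl` (AIRR TSVs).
#' @param plates named list (by donor) of plate CSV paths (columns
#'   `line_id`, `antigen`, `spots_stim`, `spots_ctrl`).
#' @param scores,responses,peptides CSV/TSV paths (peptides defaults to
#'   the packaged table when `NULL`).
#' @param key clonotype key for background subtraction.
#' @param fold,min_diff,percentile_threshold,min_alleles,response_target,top_fraction
#'   analysis thresholds.
#' @param cells_per_well CD4 T cells per well.
#' @param seed integer seed for any stochastic step (bootstrap).
#' @param out_dir output directory for the report bundle.
#' @return list of class `run_config`.
#' @export
run_config <- function(repertoires = NULL, plates = NULL, scores = NULL,
                       responses = NULL, peptides = NULL,
                       key = c("vjaa", "aa"), fold = 2, min_diff = 25,
                       percentile_threshold = 10, min_alleles = 4,
                       response_target = 0.5, top_fraction = 0.5,
                       cells_per_well = 200000L, seed = 1L,
                       out_dir = tempfile("repdominance_run_")) {
  key <- match.arg(key)
  stopifnot(fold > 0, min_diff > 0, percentile_threshold > 0,
            min_alleles > 0, response_target > 0, top_fraction > 0,
            cells_per_well > 0)
  structure(
    list(repertoires = repertoires, plates = plates, scores = scores,
         responses = responses, peptides = peptides, key = key,
         fold = fold, min_diff = min_diff,
         percentile_threshold = percentile_threshold,
         min_alleles = min_alleles, response_target = response_target,
         top_fraction = top_fraction,
         cells_per_well = as.integer(cells_per_well),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

#' Read an ELISPOT plate CSV
#'
#' Expected columns: `line_id`, `antigen`, `spots_stim`, `spots_ctrl`.
#'
#' @param path CSV path.
#' @param cells_per_well CD4 T cells per well.
#' @param donor_id donor annotation.
#' @return a [plate_result()] (antigen taken from the first row).
#' @export
read_plate_csv <- function(path, cells_per_well = 200000L,
                           donor_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  required <- c("line_id", "antigen", "spots_stim", "spots_ctrl")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("plate CSV lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  plate_result(
    donor_id %||% sub("\\.[^.]*$", "", basename(path)),
    raw$antigen[1],
    tibble(line_id = as.character(raw$line_id),
           spots_stimulated = as.numeric(raw$spots_stim),
           spots_control = as.numeric(raw$spots_ctrl)),
    cells_per_well
  )
}

#' Write a full synthetic study to disk
#'
#' Generates every input the pipeline consumes — per-donor AIRR TSVs
#' (antigen + CONTROL), one ELISPOT plate CSV per donor, a percentile
#' score matrix, a response matrix, the packaged peptide table copied
#' alongside — plus a `ground_truth.json` sidecar recording the planted
#' structure.
#'
#' @param out_dir output directory (created).
#' @param n_donors donors to simulate.
#' @param seed master seed; per-component seeds are derived from it.
#' @param config optional [repertoire_config()] (seed overridden from
#'   `seed`).
#' @param true_frequency_per_million,n_lines ELISPOT simulation truth.
#' @param n_peptides,n_promiscuous,n_dominant,mass_fraction epitope
#'   simulation knobs.
#' @return invisible list of generated paths and the ground truth.
#' @export
simulate_study <- function(out_dir, n_donors = 3L, seed = 1L,
                           config = NULL,
                           true_frequency_per_million = 6,
                           n_lines = 96L, n_peptides = 63L,
                           n_promiscuous = 18L, n_dominant = 18L,
                           mass_fraction = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- config %||% repertoire_config(n_public = 5L, seed = seed)
  config$seed <- as.integer(seed)
  rep_set <- gen_repertoire_set(config, n_donors)
  paths <- list()
  for (d in names(rep_set$samples)) {
    stim_path <- file.path(out_dir, paste0(d, "_FVIII.airr.tsv"))
    ctrl_path <- file.path(out_dir, paste0(d, "_CONTROL.airr.tsv"))
    write_airr(rep_set$samples[[d]]$antigen, stim_path)
    write_airr(rep_set$samples[[d]]$control, ctrl_path)
    paths$repertoires[[d]] <- list(stim = stim_path, ctrl = ctrl_path)
    plate <- gen_elispot_plate(true_frequency_per_million, 200000L,
                               n_lines, seed = seed + match(d, names(rep_set$samples)))
    plate_path <- file.path(out_dir, paste0(d, "_plate.csv"))
    utils::write.csv(
      data.frame(line_id = plate$lines$line_id, antigen = "FVIII",
                 spots_stim = plate$lines$spots_stimulated,
                 spots_ctrl = plate$lines$spots_control),
      plate_path, row.names = FALSE, quote = FALSE)
    paths$plates[[d]] <- plate_path
  }
  sm <- gen_score_matrix(n_peptides, 15L,
                         promiscuous_ids = seq_len(n_promiscuous),
                         seed = seed + 101L)
  rm_ <- gen_response_matrix(n_donors, n_peptides,
                             dominant_ids = seq_len(n_dominant),
                             mass_fraction = mass_fraction,
                             seed = seed + 202L)
  paths$scores <- file.path(out_dir, "scores.csv")
  paths$responses <- file.path(out_dir, "responses.csv")
  write_matrix(sm$scores, paths$scores)
  write_matrix(rm_$responses, paths$responses)
  truth <- list(
    public = list(junction_aa = rep_set$truth$public$junction_aa,
                  donors = rep_set$truth$public$donors),
    background = rep_set$truth$background,
    frequency_per_million = true_frequency_per_million,
    promiscuous_ids = sm$truth$promiscuous_ids,
    dominant_ids = rm_$truth$dominant_ids
  )
  paths$ground_truth <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, truth = truth))
}

#' Run the full analysis pipeline
#'
#' Executes whichever stages the configuration provides inputs for:
#' ELISPOT positivity calling and precursor-frequency estimation per
#' donor plus the cross-donor mean; background subtraction and
#' repertoire statistics (Gini-Simpson, clonotypes covering the top
#' fraction, length distribution, hydrophobic-doublet fraction, V/J
#' pairing) per donor; cross-donor public clonotypes; promiscuous
#' peptide selection and immunodominance ranking. Writes stage CSVs and
#' a JSON report to the configured output directory. Any stage failure
#' is re-raised with the stage name attached.
#'
#' @param config a [run_config()].
#' @return the report list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }
  if (!is.null(config$plates)) {
    report$elispot <- stage("elispot", {
      per_donor <- purrr::imap(config$plates, function(path, d) {
        plate <- call_plate(read_plate_csv(path, config$cells_per_well, d),
                            config$fold, config$min_diff)
        list(donor_id = d, n_positive = plate$n_positive,
             n_total = nrow(plate$lines), saturated = plate$saturated,
             frequency_per_million = if (plate$saturated) NA_real_
             else plate$estimate$frequency_per_million)
      })
      freqs <- vapply(per_donor, `[[`, 1, "frequency_per_million")
      list(per_donor = unname(per_donor),
           mean_frequency_per_million = mean(freqs, na.rm = TRUE))
    })
  }
  if (!is.null(config$repertoires)) {
    report$repertoire <- stage("repertoire", {
      filtered <- purrr::imap(config$repertoires, function(p, d) {
        stim <- read_airr(p$stim, donor_id = d)
        ctrl <- read_airr(p$ctrl, donor_id = d, antigen = "CONTROL")
        subtract_background(stim, ctrl, key = config$key)
      })
      stats_tbl <- purrr::imap(filtered, function(s, d) {
        tf <- top_fraction(s, config$top_fraction)
        tibble(donor_id = d,
               n_clonotypes = nrow(s$clonotypes),
               n_background_removed = attr(s, "n_removed"),
               gini_simpson = gini_simpson(s),
               k_top = tf$k,
               p6p7_hydrophobic =
                 as.numeric(hydrophobic_p6p7_fraction(s)))
      }) |> dplyr::bind_rows()
      readr::write_csv(stats_tbl,
                       file.path(config$out_dir, "repertoire_stats.csv"))
      pub <- public_clonotypes(filtered)
      pub_flat <- dplyr::mutate(
        pub,
        donors = vapply(.data$donors, paste, "", collapse = ";"),
        frequencies = vapply(.data$frequencies,
                             function(x) paste(signif(x, 6), collapse = ";"),
                             ""))
      readr::write_csv(pub_flat,
                       file.path(config$out_dir, "public_clonotypes.csv"))
      list(per_donor = stats_tbl,
           mean_gini_simpson = mean(stats_tbl$gini_simpson),
           mean_k_top = mean(stats_tbl$k_top),
           n_public = nrow(pub),
           public = pub_flat)
    })
  }
  if (!is.null(config$responses)) {
    report$epitopes <- stage("epitopes", {
      peptides <- parse_peptide_table(config$peptides)
      out <- list()
      if (!is.null(config$scores)) {
        scores <- read_matrix(config$scores, "score")
        out$promiscuous <- select_promiscuous(
          scores, config$percentile_threshold, config$min_alleles)
      }
      ranking <- rank_epitopes(read_matrix(config$responses, "response"),
                               config$response_target)
      readr::write_csv(ranking$ranking,
                       file.path(config$out_dir, "epitope_ranking.csv"))
      top_ids <- ranking$ranking$peptide_id[seq_len(ranking$k_response)]
      out$k_response <- ranking$k_response
      out$k_coverage <- ranking$k_coverage
      out$grand_total <- ranking$grand_total
      out$top_set <- top_ids
      out$domains <- if (all(top_ids %in% peptides$peptide_id)) {
        as.list(domain_summary(peptides, top_ids))
      } else NULL
      out
    })
  }
  make_report(report, file.path(config$out_dir, "report.json"))
  invisible(report)
}

#' Write the machine-readable run report
#'
#' Validates that the bundle carries at least one known stage and only
#' known stages, then serializes it as JSON.
#'
#' @param report named list of stage outputs (`elispot`, `repertoire`,
#'   `epitopes`).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
make_report <- function(report, path) {
  known <- c("elispot", "repertoire", "epitopes")
  extra <- setdiff(names(report), known)
  if (length(extra) > 0) {
    abort(paste0("unknown report stage(s): ", paste(extra, collapse = ", ")))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
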