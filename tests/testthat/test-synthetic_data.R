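test_that("ranked clone frequencies follow the geometric law", {
  cfg <- repertoire_config(n_clonotypes = 100, clonality = 0.5,
                           n_background = 0, total_reads = 1e7, seed = 2)
  rs <- gen_repertoire_set(cfg, 1)
  cl <- rs$samples$D01$antigen$clonotypes
  # closed form: p_1 = (1-c) / sum (1-c)^r -> c for large n
  expect_gt(max(cl$frequency), 0.49)
  expect_equal(sum(cl$frequency), 1, tolerance = 1e-9)
})

test_that("generated samples satisfy every clonotype invariant", {
  cfg <- repertoire_config(n_clonotypes = 200, n_public = 5,
                           n_background = 20, seed = 5)
  rs <- gen_repertoire_set(cfg, 3)
  for (d in names(rs$samples)) {
    for (cond in c("antigen", "control")) {
      cl <- rs$samples[[d]][[cond]]$clonotypes
      expect_silent(validate_clonotypes(cl))
      expect_true(all(grepl("^C", cl$junction_aa)))
      expect_true(all(grepl("F$", cl$junction_aa)))
      expect_true(all(nchar(cl$junction_aa) >= 10 &
                        nchar(cl$junction_aa) <= 19))
      expect_equal(sum(cl$frequency), 1, tolerance = 1e-9)
      expect_false(anyDuplicated(cl$junction_aa) > 0)
    }
  }
})

test_that("planted public and background structure is exactly as declared", {
  cfg <- repertoire_config(n_clonotypes = 150, n_public = 5,
                           n_background = 10, seed = 9)
  rs <- gen_repertoire_set(cfg, 3)
  truth <- rs$truth
  expect_equal(nrow(truth$public), 5)
  for (i in seq_len(5)) {
    donors <- truth$public$donors[[i]]
    expect_gte(length(donors), 2)
    for (d in donors) {
      expect_true(truth$public$junction_aa[i] %in%
                    rs$samples[[d]]$antigen$clonotypes$junction_aa)
    }
  }
  for (d in names(rs$samples)) {
    bg <- truth$background$junction_aa[truth$background$donor_id == d]
    expect_length(bg, 10)
    ant <- rs$samples[[d]]$antigen$clonotypes
    ctl <- rs$samples[[d]]$control$clonotypes
    # the background clone is the same rearrangement in both samples
    key_a <- clonotype_key(ant[ant$junction_aa %in% bg, ])
    key_c <- clonotype_key(ctl[ctl$junction_aa %in% bg, ])
    expect_setequal(key_a, key_c)
  }
})

test_that("repertoire generation is deterministic for a fixed seed", {
  cfg <- repertoire_config(n_clonotypes = 60, n_public = 3,
                           n_background = 5, seed = 42)
  expect_identical(gen_repertoire_set(cfg, 3), gen_repertoire_set(cfg, 3))
})

test_that("impossible repertoire configs are rejected", {
  expect_error(repertoire_config(n_clonotypes = 10, n_public = 8,
                                 n_background = 5), "exceeds")
  expect_error(repertoire_config(clonality = 0), "clonality")
  expect_error(repertoire_config(
    length_distribution = c("12" = 0.5, "13" = 0.4)), "summing to 1")
  cfg <- repertoire_config(n_public = 2)
  expect_error(gen_repertoire_set(cfg, 1), ">= 2 donors")
})

test_that("ELISPOT simulator matches Poisson well-occupancy", {
  # f = 6/M at 200,000 cells/well: occupancy rate 1 - exp(-1.2)
  plate <- gen_elispot_plate(6, 200000, 10000, seed = 3,
                             spot_model = list(baseline_mean = 0))
  k <- attr(plate, "truth")$occupancy
  p_occ <- 1 - exp(-1.2)
  se <- sqrt(p_occ * (1 - p_occ) / 10000)
  expect_lt(abs(mean(k > 0) - p_occ), 3 * se)
  # with a noise-free spot model, positivity == occupancy
  called <- call_plate(plate)
  expect_equal(called$n_positive, sum(k > 0))
})

test_that("zero-frequency plates only fire at the rule's false-positive rate", {
  plate <- gen_elispot_plate(0, 200000, 500, seed = 4)
  expect_true(all(attr(plate, "truth")$occupancy == 0))
  called <- call_plate(plate)
  # Poisson(10) stim vs Poisson(10) ctrl almost never clears 2x + 25
  expect_lt(called$n_positive / 500, 0.01)
})

test_that("plate simulation is deterministic for a fixed seed", {
  expect_identical(gen_elispot_plate(6, 2e5, 96, seed = 7),
                   gen_elispot_plate(6, 2e5, 96, seed = 7))
})

test_that("score-matrix generator plants exactly the promiscuous set", {
  sm <- gen_score_matrix(10, 15, promiscuous_ids = c(2, 5, 9), seed = 6)
  expect_setequal(select_promiscuous(sm$scores), sm$truth$promiscuous_ids)
  empty <- gen_score_matrix(10, 15, seed = 6)
  expect_length(select_promiscuous(empty$scores), 0)
  expect_identical(gen_score_matrix(10, 15, 1:3, seed = 1),
                   gen_score_matrix(10, 15, 1:3, seed = 1))
  expect_error(gen_score_matrix(5, 15, promiscuous_ids = "P999"), "subset")
})

test_that("response-matrix generator plants dominance mass and coverage", {
  rm_ <- gen_response_matrix(8, 20, dominant_ids = 1:5,
                             mass_fraction = 0.5, total_lines = 400,
                             seed = 8)
  m <- rm_$responses
  dom <- rm_$truth$dominant_ids
  expect_gte(sum(m[, dom]) / sum(m), 0.5)
  # every dominant total strictly exceeds every other total
  expect_gt(min(colSums(m[, dom])), max(colSums(m[, setdiff(colnames(m), dom)])))
  # the dominant set covers all donors
  expect_true(all(rowSums(m[, dom, drop = FALSE]) > 0))
  expect_error(gen_response_matrix(2, 5, 1:2, mass_fraction = 1.2),
               "mass_fraction")
  expect_identical(gen_response_matrix(4, 10, 1:3, seed = 2),
                   gen_response_matrix(4, 10, 1:3, seed = 2))
})

test_that("single dominant peptide with all mass ranks trivially first", {
  rm_ <- gen_response_matrix(1, 1, dominant_ids = 1, mass_fraction = 0.99,
                             total_lines = 50, seed = 1)
  rk <- rank_epitopes(rm_$responses)
  expect_equal(rk$ranking$peptide_id[1], "P001")
  expect_equal(rk$k_response, 1L)
})
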