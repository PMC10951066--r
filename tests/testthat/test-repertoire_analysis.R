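test_that("background subtraction removes control-shared clonotypes and renormalizes", {
  stim <- make_sample(c("CASSAEQFF", "CASSGLAFF", "CASSCNTLYF"),
                      counts = c(5, 3, 2))
  # stim frequencies 0.5 / 0.3 / 0.2; remove the 0.2-mass clonotype:
  # survivors renormalize to 0.5/0.8 and 0.3/0.8
  ctrl <- make_sample("CASSCNTLYF", donor = "D01", antigen = "CONTROL")
  out <- subtract_background(stim, ctrl)
  expect_equal(attr(out, "n_removed"), 1)
  expect_equal(sort(out$clonotypes$frequency), c(0.375, 0.625))
  expect_equal(sum(out$clonotypes$frequency), 1)

  disjoint <- make_sample("CASSWWQFF", donor = "D01", antigen = "CONTROL")
  same <- subtract_background(stim, disjoint)
  expect_equal(attr(same, "n_removed"), 0)
  expect_equal(same$clonotypes, stim$clonotypes)

  all_gone <- subtract_background(stim, repertoire_sample(
    "D01", "CONTROL", stim$clonotypes))
  expect_equal(nrow(all_gone$clonotypes), 0)
  expect_equal(attr(all_gone, "n_removed"), 3)
})

test_that("background subtraction respects the clonotype key", {
  stim <- make_sample("CASSLGQFF", v = "TRBV7-4")
  ctrl_other_v <- make_sample("CASSLGQFF", v = "TRBV7-3",
                              antigen = "CONTROL")
  # same junction, different V: distinct under vjaa, shared under aa
  expect_equal(attr(subtract_background(stim, ctrl_other_v, "vjaa"),
                    "n_removed"), 0)
  expect_equal(attr(subtract_background(stim, ctrl_other_v, "aa"),
                    "n_removed"), 1)
  expect_error(subtract_background(stim, make_sample("CASSLGQFF",
                                                     donor = "D02")),
               "same donor")
})

test_that("Gini-Simpson matches hand values and its bounds", {
  expect_equal(gini_simpson(make_sample("CASSLGQFF")), 0)
  expect_equal(gini_simpson(make_sample(c("CASSLGQFF", "CASSPTLYF"),
                                        counts = c(1, 1))), 0.5)
  expect_equal(gini_simpson(make_sample(
    c("CASSLGQFF", "CASSPTLYF", "CASRNTEAFF"), counts = c(2, 1, 1))),
    0.625)
  expect_error(gini_simpson(make_clonotypes(character(0))), "empty")
})

test_that("top_fraction returns the smallest qualifying prefix", {
  s <- make_sample(sprintf("CASS%sEQFF", c("A", "G", "L", "S")),
                   counts = c(1, 1, 1, 1))
  expect_equal(top_fraction(s, 0.5)$k, 2)
  s2 <- make_sample(c("CASSAEQFF", "CASSGEQFF", "CASSLEQFF"),
                    counts = c(6, 2, 2))
  expect_equal(top_fraction(s2, 0.5)$k, 1)
  s3 <- make_sample(sprintf("CASS%sEQFF", c("A", "G", "L", "S")),
                    counts = c(3, 3, 2, 2))
  expect_equal(top_fraction(s3, 0.5)$k, 2)
  expect_error(top_fraction(s, 0), "fraction")
})

test_that("repertoire statistics agree with brute-force oracles", {
  withr::local_seed(101)
  vegan_ok <- requireNamespace("vegan", quietly = TRUE)
  for (rep in 1:200) {
    cl <- random_clonotypes(sample(2:20, 1))
    # Gini-Simpson
    expect_equal(gini_simpson(cl), oracle_gini_simpson(cl$frequency))
    if (vegan_ok && rep <= 20) {
      expect_equal(gini_simpson(cl),
                   unname(vegan::diversity(cl$count, "simpson")))
    }
    # top fraction
    frac <- runif(1, 0.1, 1)
    expect_equal(top_fraction(cl, frac)$k,
                 oracle_top_fraction_k(cl$frequency, cl$junction_aa, frac))
    # V/J usage and pairing
    vj <- vj_pairing(cl)
    ov <- oracle_vj_usage(cl$v_call, cl$frequency)
    expect_equal(setNames(vj$v_usage$fraction, vj$v_usage$v_call)[names(ov)],
                 ov)
    op <- oracle_pairing(cl$v_call, cl$j_call, cl$frequency)
    got <- setNames(vj$pairing$fraction,
                    paste(vj$pairing$v_call, vj$pairing$j_call, sep = "|"))
    expect_equal(got[names(op)], op)
  }
})

test_that("top_fraction prefixes are minimal (brute force on small instances)", {
  withr::local_seed(7)
  for (rep in 1:50) {
    cl <- random_clonotypes(sample(2:20, 1))
    frac <- runif(1, 0.1, 0.9)
    tf <- top_fraction(cl, frac)
    expect_gte(sum(tf$clonotypes$frequency), frac - 1e-12)
    if (tf$k > 1) {
      expect_lt(sum(tf$clonotypes$frequency[seq_len(tf$k - 1)]), frac)
    }
  }
})

test_that("shared and public clonotypes match the dictionary oracle", {
  withr::local_seed(23)
  for (rep in 1:200) {
    a <- random_clonotypes(sample(2:20, 1))
    b <- random_clonotypes(sample(2:20, 1))
    expect_equal(shared_clonotypes(a, b),
                 oracle_shared(a$junction_aa, b$junction_aa))
    expect_equal(shared_clonotypes(a, b), shared_clonotypes(b, a))
  }
  for (rep in 1:40) {
    n_donors <- sample(2:5, 1)
    samples <- setNames(
      lapply(seq_len(n_donors), function(i) random_clonotypes(sample(2:20, 1))),
      paste0("D", seq_len(n_donors)))
    pub <- public_clonotypes(samples)
    expect_equal(sort(pub$junction_aa), oracle_public(samples))
    expect_true(all(pub$sharing_degree >= 2))
    expect_true(all(pub$sharing_degree ==
                      vapply(pub$donors, length, 1L)))
  }
})

test_that("public clonotype edge cases behave", {
  a <- make_clonotypes(c("CASSAEQFF", "CASSGEQFF"))
  b <- make_clonotypes(c("CASSLEQFF", "CASSSEQFF"))
  expect_equal(nrow(public_clonotypes(list(D1 = a, D2 = b))), 0)
  c3 <- list(D1 = a, D2 = a, D3 = a)
  pub <- public_clonotypes(c3)
  expect_true(all(pub$sharing_degree == 3))
  expect_error(public_clonotypes(list(D1 = a)), ">= 2")
})

test_that("shared_clonotypes of a sample with itself is its key set", {
  a <- make_clonotypes(c("CASSAEQFF", "CASSGEQFF"))
  expect_equal(shared_clonotypes(a, a), sort(a$junction_aa))
})

test_that("length distribution honours weighting", {
  cl <- make_clonotypes(c("CASSAEQFFLPT", "CASSGEQFFLPT", "CASSLEQFFLPTAY"),
                        counts = c(8, 1, 1))
  un <- length_distribution(cl, "unweighted")
  expect_equal(un$fraction[un$length == 12], 2 / 3)
  expect_equal(un$fraction[un$length == 14], 1 / 3)
  wt <- length_distribution(cl, "frequency")
  expect_equal(wt$fraction[wt$length == 12], 0.9)
  expect_equal(sum(un$fraction), 1)
  single <- length_distribution(make_clonotypes("CASSLGQFF"))
  expect_equal(single$fraction, 1)
  expect_error(length_distribution(make_clonotypes(character(0))), "empty")
})

test_that("anchor alignment centers interiors and flags short sequences", {
  rows <- align_cdr3(c("CASSF", "CASSF"), anchor = 2)
  expect_equal(rows[1], rows[2])
  seqs <- c("CASSAF", "CASSGGAF")
  al <- align_cdr3(seqs, anchor = 2)
  # block width = 4 + max interior (4); shorter interior centred
  expect_equal(unique(nchar(al)), 8)
  expect_equal(al[2], "CASSGGAF")
  expect_equal(al[1], "CA-SS-AF")
  full <- align_cdr3(c("CASSLGQFF", "CASSPPLNTLYF", "CASRF"))
  expect_equal(unique(nchar(full)), 8 + max(nchar(c("CASSLGQFF",
                                                    "CASSPPLNTLYF"))) - 8)
  expect_true(attr(full, "short")[3])
  expect_match(full[3], "^CASRF-+$")
  expect_error(align_cdr3(character(0)))
})

test_that("composition profile is a weighted positional distribution", {
  al <- align_cdr3(c("CASSLGQFF", "CASSLGQFF"))
  prof <- composition_profile(al)
  occupied <- rowSums(prof$aa) > 0
  expect_true(all(apply(prof$aa[occupied, ], 1, max) == 1))
  # two sequences differing at one position split 0.5/0.5
  al2 <- align_cdr3(c("CASSLGQFF", "CASSAGQFF"))
  prof2 <- composition_profile(al2)
  pos5 <- prof2$aa[5, ]
  expect_equal(unname(pos5[c("L", "A")]), c(0.5, 0.5))
  # class rows are the partition of the aa rows
  expect_equal(unname(rowSums(prof2$classes)), unname(rowSums(prof2$aa)))
  # frequency weighting shifts the split
  prof3 <- composition_profile(al2, weights = c(3, 1))
  expect_equal(unname(prof3$aa[5, "L"]), 0.75)
  expect_error(composition_profile(character(0)))
})

test_that("hydrophobic doublet fraction inspects junction positions 6 and 7", {
  expect_equal(as.numeric(
    hydrophobic_p6p7_fraction(make_clonotypes("CASSLLGTEAFF"))), 0)
  expect_equal(as.numeric(
    hydrophobic_p6p7_fraction(make_clonotypes("CASSFLLTEAFF"))), 1)
  mixed <- make_clonotypes(c("CASSFLLTEAFF", "CASSLLGTEAFF"),
                           counts = c(3, 1))
  expect_equal(as.numeric(hydrophobic_p6p7_fraction(mixed, "unweighted")),
               0.5)
  expect_equal(as.numeric(hydrophobic_p6p7_fraction(mixed, "frequency")),
               0.75)
  short <- make_clonotypes(c("CASSFLLTEAFF", "CSSLF"))
  out <- hydrophobic_p6p7_fraction(short)
  expect_equal(as.numeric(out), 1)
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("V/J pairing marginals equal the usage vectors", {
  withr::local_seed(31)
  for (rep in 1:20) {
    cl <- random_clonotypes(sample(3:20, 1))
    vj <- vj_pairing(cl)
    for (v in vj$v_usage$v_call) {
      mass <- sum(vj$pairing$fraction[vj$pairing$v_call == v])
      expect_equal(mass, vj$v_usage$fraction[vj$v_usage$v_call == v],
                   tolerance = 1e-9)
    }
    for (j in vj$j_usage$j_call) {
      mass <- sum(vj$pairing$fraction[vj$pairing$j_call == j])
      expect_equal(mass, vj$j_usage$fraction[vj$j_usage$j_call == j],
                   tolerance = 1e-9)
    }
    expect_equal(sum(vj$pairing$fraction), 1)
  }
  single <- vj_pairing(make_clonotypes("CASSLGQFF", v = "TRBV7-4",
                                       j = "TRBJ1-2"))
  expect_equal(single$v_usage$fraction, 1)
  expect_equal(single$pairing$fraction, 1)
})

test_that("clonotypes lacking gene calls are excluded and counted", {
  cl <- clonotype_table(c("CASSLGQFF", "CASSPTLYF"),
                        v_call = c("TRBV7-4", NA),
                        j_call = c("TRBJ1-2", "TRBJ2-7"),
                        count = c(1, 1))
  vj <- vj_pairing(cl)
  expect_equal(vj$n_excluded, 1)
  expect_equal(vj$v_usage$fraction, 1)
})
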