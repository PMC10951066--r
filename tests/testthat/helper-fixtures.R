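# Small in-code fixtures shared across test files.

# A clonotype table from junctions and counts (valid >= 5 aa junctions).
make_clonotypes <- function(junctions, counts = rep(1, length(junctions)),
                            v = "TRBV7-4", j = "TRBJ1-2") {
  clonotype_table(junction_aa = junctions, v_call = v, j_call = j,
                  count = counts)
}

make_sample <- function(junctions, counts = rep(1, length(junctions)),
                        donor = "D01", antigen = "FVIII",
                        v = "TRBV7-4", j = "TRBJ1-2") {
  repertoire_sample(donor, antigen, make_clonotypes(junctions, counts, v, j))
}

# Random small clonotype table for property tests (valid junctions drawn
# from a tiny alphabet so cross-sample collisions actually occur).
random_clonotypes <- function(n, seq_pool = NULL) {
  pool <- seq_pool %||% apply(
    expand.grid("CAS", c("A", "G", "L", "S"), c("A", "G", "L", "S"),
                c("EQFF", "NTLYF", "PLAFF")),
    1, paste, collapse = "")
  junctions <- sample(pool, n, replace = FALSE)
  make_clonotypes(
    junctions,
    counts = sample(1:50, n, replace = TRUE),
    v = sample(c("TRBV7-4", "TRBV7-3", "TRBV4-1"), n, replace = TRUE),
    j = sample(c("TRBJ1-2", "TRBJ2-7"), n, replace = TRUE)
  )
}

write_airr_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
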