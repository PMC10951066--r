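# Independent brute-force implementations used to cross-check the
# package's repertoire statistics. Deliberately naive: explicit loops,
# no shared code with the implementations under test.

oracle_gini_simpson <- function(freqs) {
  acc <- 0
  for (p in freqs) acc <- acc + p * p
  1 - acc
}

# Smallest prefix of the (-frequency, junction) ordering reaching the
# target fraction, found by scanning every prefix.
oracle_top_fraction_k <- function(freqs, junctions, fraction) {
  ord <- order(-freqs, junctions)
  freqs <- freqs[ord]
  for (k in seq_along(freqs)) {
    if (sum(freqs[seq_len(k)]) >= fraction - 1e-12) return(k)
  }
  length(freqs)
}

oracle_vj_usage <- function(v_calls, weights) {
  weights <- weights / sum(weights)
  genes <- sort(unique(v_calls))
  out <- numeric(length(genes))
  names(out) <- genes
  for (i in seq_along(v_calls)) {
    out[v_calls[i]] <- out[v_calls[i]] + weights[i]
  }
  out
}

oracle_pairing <- function(v_calls, j_calls, weights) {
  weights <- weights / sum(weights)
  out <- list()
  for (i in seq_along(v_calls)) {
    k <- paste(v_calls[i], j_calls[i], sep = "|")
    out[[k]] <- (out[[k]] %||% 0) + weights[i]
  }
  unlist(out)
}

oracle_shared <- function(keys_a, keys_b) {
  out <- character(0)
  for (k in unique(keys_a)) {
    if (any(keys_b == k)) out <- c(out, k)
  }
  sort(out)
}

# Dictionary-count public clonotype oracle: sequence -> set of donors.
oracle_public <- function(samples, min_donors = 2) {
  dict <- new.env(parent = emptyenv())
  for (d in names(samples)) {
    cl <- if (inherits(samples[[d]], "repertoire_sample"))
      samples[[d]]$clonotypes else samples[[d]]
    for (s in unique(cl$junction_aa)) {
      assign(s, union(get0(s, dict, ifnotfound = character(0)), d), dict)
    }
  }
  seqs <- ls(dict)
  degree <- vapply(seqs, function(s) length(get(s, dict)), 1L)
  sort(seqs[degree >= min_donors])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
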