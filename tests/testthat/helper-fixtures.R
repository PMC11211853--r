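# shared fixtures: schemes, noiseless spectra, brute-force oracles

static_scheme <- function() {
  mod_scheme(variable = numeric(0), nterm = numeric(0))
}

# spectrum containing exactly the singly charged b/y fragments of a peptide,
# with unit intensities and an exact precursor
noiseless_spectrum <- function(peptide, charge = 2L, id = "fx") {
  fr <- theoretical_fragments(peptide, ions = c("b", "y"))
  M <- peptide_mass(peptide)
  spectrum(id, (M + charge * 1.00727646688) / charge, charge,
           fr$mz, rep(1, nrow(fr)))
}

# O(N * 151) double-loop cross-correlation, offsets -75..75 excluding 0
naive_xcorr <- function(u, v) {
  n <- length(u)
  bg <- 0
  for (r in setdiff(-75:75, 0)) {
    for (i in seq_len(n)) {
      j <- i - r
      if (j >= 1 && j <= n) bg <- bg + v[i] * u[j]
    }
  }
  sum(u * v) - bg / 150
}

# exact binomial tail P(X >= k), X ~ Binom(n, p), by direct summation
exact_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# fragment set with one theoretical peak per 100-Da window, so top-q
# filtering never removes a matched peak and k is fully controlled
spread_fragments <- function(n) {
  data.frame(series = "b", index = seq_len(n), charge = 1L,
             mz = 150 + 100 * (seq_len(n) - 1L))
}

# random scored-candidate table for TDC oracle tests
random_scored <- function(n_spectra, max_cand, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_spectra), function(i) {
    k <- sample.int(max_cand, 1)
    data.frame(spectrum_id = sprintf("s%03d", i),
               peptide = sprintf("PEP%03d", sample.int(40, k)),
               score = round(stats::runif(k), 2),
               is_decoy = sample(c(TRUE, FALSE), k, replace = TRUE),
               precursor_mz = stats::runif(1, 300, 1400),
               charge = 2L)
  })
  out <- do.call(rbind, rows)
  out$pair_id <- as.integer(sub("PEP", "", out$peptide))
  out
}
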