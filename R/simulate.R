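# Ground-truthed synthetic data: random proteomes, fragment spectra with
# controllable coverage/noise/jitter, and null spectra whose generating
# peptides are guaranteed absent from the searched database.

#' Simulate a random proteome FASTA
#'
#' Proteins are drawn uniformly over the 20 residues; output is
#' deterministic for a given seed.
#'
#' @param n_proteins number of proteins.
#' @param protein_length residues per protein.
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return data.frame as from [read_fasta()]; written to \code{path} if
#'   given.
#' @export
simulate_proteome <- function(n_proteins = 50, protein_length = 300,
                              seed = 1L, path = NULL) {
  st <- local_rng_state(); on.exit(restore_rng_state(st))
  set.seed(seed)
  seqs <- vapply(seq_len(n_proteins), function(i)
    paste(sample(names(AA_MASS), protein_length, replace = TRUE),
          collapse = ""), character(1))
  prot <- data.frame(id = sprintf("sim_prot_%03d", seq_len(n_proteins)),
                     description = sprintf("sim_prot_%03d synthetic protein",
                                           seq_len(n_proteins)),
                     sequence = seqs, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    writeLines(paste0(">", prot$description, "\n", prot$sequence), path)
  }
  prot
}

# static-modified form of a plain digest peptide (no variable/N-term mods)
apply_static <- function(sequence, scheme) {
  res <- strsplit(sequence, "")[[1]]
  paste(vapply(res, function(r) {
    if (r %in% names(scheme$static))
      paste0(r, "[", fmt_delta(scheme$static[[r]]), "]") else r
  }, character(1)), collapse = "")
}

# one synthetic spectrum from a (modified) peptide string
gen_spectrum <- function(peptide, id, fragment_coverage, noise_peaks,
                         mz_jitter_ppm, intensity_meanlog, intensity_sdlog,
                         charge, precursor_tol_ppm) {
  fr <- theoretical_fragments(peptide, ions = c("b", "y"))
  keep <- stats::runif(nrow(fr)) < fragment_coverage
  mz <- fr$mz[keep]
  mz <- mz * (1 + stats::rnorm(length(mz), 0, mz_jitter_ppm) * 1e-6)
  int <- stats::rlnorm(length(mz), intensity_meanlog, intensity_sdlog)
  if (noise_peaks > 0) {
    med <- if (length(int)) stats::median(int) else 1
    nmz <- stats::runif(noise_peaks, 100, max(fr$mz) + 50)
    nint <- stats::runif(noise_peaks, 0, med)
    mz <- c(mz, nmz); int <- c(int, nint)
  }
  M <- peptide_mass(peptide)
  pm <- (M + charge * MASS_PROTON) / charge
  pm <- pm * (1 + stats::runif(1, -precursor_tol_ppm / 2,
                               precursor_tol_ppm / 2) * 1e-6)
  spectrum(id, pm, charge, mz, int)
}

# digest a proteome to unique static-modified peptide strings
digest_pool <- function(proteins, rule, scheme, min_len, max_len) {
  seqs <- unique(unlist(lapply(proteins$sequence, function(p)
    digest(p, rule)$sequence)))
  len <- nchar(seqs)
  seqs <- seqs[len >= min_len & len <= max_len]
  seqs <- seqs[!grepl(paste0("[", paste(AMBIGUOUS_RESIDUES, collapse = ""),
                             "]"), seqs)]
  vapply(seqs, apply_static, character(1), scheme = scheme,
         USE.NAMES = FALSE)
}

#' Simulate annotated MS2 spectra from a proteome
#'
#' Samples distinct tryptic peptides from the digested proteome and emits,
#' for each, singly charged b/y fragment peaks retained with probability
#' \code{fragment_coverage}, log-normal intensities, Gaussian ppm m/z
#' jitter, and uniform noise peaks; the precursor m/z is back-computed from
#' the peptide mass and charge with jitter within half the precursor
#' tolerance. A truth table maps each spectrum to its generating peptide.
#'
#' @param proteins FASTA path or data.frame from [read_fasta()].
#' @param n_spectra number of spectra to generate.
#' @param fragment_coverage probability each fragment peak is observed.
#' @param noise_peaks uniform noise peaks per spectrum.
#' @param mz_jitter_ppm standard deviation of fragment m/z jitter (ppm).
#' @param intensity_meanlog,intensity_sdlog log-normal intensity parameters.
#' @param charges,charge_probs precursor charge distribution.
#' @param precursor_tol_ppm precursor tolerance the jitter must respect.
#' @param rule [cleavage_rule()] used to pick true peptides.
#' @param scheme [mod_scheme()]; static modifications are applied to truth
#'   peptides.
#' @param min_len,max_len peptide length bounds.
#' @param seed integer seed; everything is deterministic given it.
#' @param mgf_path,truth_path optional output paths (MGF and TSV).
#' @return list with \code{spectra} (list of [spectrum()]), \code{truth}
#'   (data.frame spectrum_id, peptide, base_seq).
#' @export
simulate_spectra <- function(proteins, n_spectra = 100,
                             fragment_coverage = 0.9, noise_peaks = 20,
                             mz_jitter_ppm = 5, intensity_meanlog = 0,
                             intensity_sdlog = 0.5, charges = c(2L, 3L),
                             charge_probs = c(0.6, 0.4),
                             precursor_tol_ppm = 20,
                             rule = cleavage_rule(), scheme = mod_scheme(),
                             min_len = 6L, max_len = 50L, seed = 1L,
                             mgf_path = NULL, truth_path = NULL) {
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  pool <- digest_pool(proteins, rule, scheme, min_len, max_len)
  if (length(pool) < n_spectra)
    stop("only ", length(pool), " digest peptides available for ",
         n_spectra, " spectra")
  st <- local_rng_state(); on.exit(restore_rng_state(st))
  set.seed(seed)
  picks <- sample(pool, n_spectra)
  spectra <- vector("list", n_spectra)
  for (i in seq_len(n_spectra)) {
    z <- sample(charges, 1, prob = charge_probs)
    spectra[[i]] <- gen_spectrum(picks[i], sprintf("sim_%04d", i),
                                 fragment_coverage, noise_peaks,
                                 mz_jitter_ppm, intensity_meanlog,
                                 intensity_sdlog, z, precursor_tol_ppm)
  }
  truth <- data.frame(spectrum_id = vapply(spectra, `[[`, character(1),
                                           "spectrum_id"),
                      peptide = picks, base_seq = strip_mods(picks),
                      stringsAsFactors = FALSE)
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(spectra = spectra, truth = truth)
}

#' Simulate null spectra absent from a database
#'
#' Generates spectra whose true peptides are mass-matched to database
#' candidates but, as exact sequences, verifiably absent from the digest of
#' the excluded database: each truth peptide is an interior shuffle (fixed
#' C-terminal residue) of a randomly chosen digest peptide, rejected and
#' redrawn whenever the shuffle collides with any digest peptide. No target
#' candidate can therefore be correct, making targets and decoys
#' exchangeable — the null condition under which FDR control is testable.
#'
#' @param proteins excluded database: FASTA path or [read_fasta()] frame.
#' @param n_spectra number of spectra.
#' @param seed integer seed.
#' @param ... spectrum-generation parameters as in [simulate_spectra()].
#' @inheritParams simulate_spectra
#' @return list with \code{spectra} and \code{truth} as in
#'   [simulate_spectra()].
#' @export
null_spectra <- function(proteins, n_spectra = 100, seed = 1L,
                         fragment_coverage = 0.9, noise_peaks = 20,
                         mz_jitter_ppm = 5, intensity_meanlog = 0,
                         intensity_sdlog = 0.5, charges = c(2L, 3L),
                         charge_probs = c(0.6, 0.4), precursor_tol_ppm = 20,
                         rule = cleavage_rule(), scheme = mod_scheme(),
                         min_len = 6L, max_len = 50L,
                         mgf_path = NULL, truth_path = NULL) {
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  pool <- digest_pool(proteins, rule, scheme, min_len, max_len)
  pool_base <- strip_mods(pool)
  st <- local_rng_state(); on.exit(restore_rng_state(st))
  set.seed(seed)
  picks <- character(n_spectra)
  for (i in seq_len(n_spectra)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      src <- sample(pool, 1)
      tk <- tokenize_peptide(src)
      n <- length(tk$tokens)
      if (n <= 2L) next
      perm <- c(sample(tk$tokens[seq_len(n - 1L)]), tk$tokens[n])
      cand <- paste(perm, collapse = "")
      if (!(strip_mods(cand) %in% pool_base)) { picks[i] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a null peptide absent from the digest")
  }
  spectra <- vector("list", n_spectra)
  for (i in seq_len(n_spectra)) {
    z <- sample(charges, 1, prob = charge_probs)
    spectra[[i]] <- gen_spectrum(picks[i], sprintf("null_%04d", i),
                                 fragment_coverage, noise_peaks,
                                 mz_jitter_ppm, intensity_meanlog,
                                 intensity_sdlog, z, precursor_tol_ppm)
  }
  truth <- data.frame(spectrum_id = vapply(spectra, `[[`, character(1),
                                           "spectrum_id"),
                      peptide = picks, base_seq = strip_mods(picks),
                      stringsAsFactors = FALSE)
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(spectra = spectra, truth = truth)
}
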