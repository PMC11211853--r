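#' Search configuration
#'
#' Bundles all search parameters with the defaults used throughout:
#' +/-20 ppm precursor and fragment tolerances, trypsin with proline
#' suppression and one missed cleavage, static carbamidomethyl-C with
#' variable M oxidation, N/Q deamidation and four N-terminal modifications,
#' and acceptance threshold alpha = 0.01.
#'
#' @param fasta protein database: FASTA path or [read_fasta()] data.frame.
#' @param mgf spectra: MGF path or a list of [spectrum()] objects.
#' @param out_dir optional output directory; when given, [run_search()]
#'   writes mzTab, detection report, PIN and a log there.
#' @param precursor_tol_ppm,fragment_tol_ppm match tolerances (ppm).
#' @param cleavage cleavage-rule string, e.g. \code{"[RK]|{P}"}.
#' @param max_missed maximum missed cleavages.
#' @param scheme a [mod_scheme()].
#' @param scorer scorer name for [make_scorer()].
#' @param aggregate \code{"geometric"} or \code{"arithmetic"} (sequence-model
#'   scorers only).
#' @param alpha FDR acceptance threshold, 0 < alpha < 1.
#' @param decoy_seed seed for decoy shuffling.
#' @param seed master seed for any stochastic scorer.
#' @param top_k candidates retained per spectrum.
#' @param min_len,max_len peptide length bounds.
#' @param index optional prebuilt [build_peptide_index()] (skips digestion).
#' @return object of class \code{search_config}.
#' @export
search_config <- function(fasta = NULL, mgf = NULL, out_dir = NULL,
                          precursor_tol_ppm = 20, fragment_tol_ppm = 20,
                          cleavage = "[RK]|{P}", max_missed = 1L,
                          scheme = mod_scheme(), scorer = "evidence",
                          aggregate = "geometric", alpha = 0.01,
                          decoy_seed = 1L, seed = 1L, top_k = 20L,
                          min_len = 6L, max_len = 50L, index = NULL) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            alpha > 0, alpha < 1, top_k >= 1)
  structure(list(fasta = fasta, mgf = mgf, out_dir = out_dir,
                 precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm,
                 cleavage = cleavage, max_missed = as.integer(max_missed),
                 scheme = scheme, scorer = scorer, aggregate = aggregate,
                 alpha = alpha, decoy_seed = as.integer(decoy_seed),
                 seed = as.integer(seed), top_k = as.integer(top_k),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 index = index),
            class = "search_config")
}

load_search_inputs <- function(cfg) {
  index <- cfg$index
  if (is.null(index)) {
    if (is.null(cfg$fasta)) stop("search_config needs a fasta or an index")
    index <- build_peptide_index(cfg$fasta,
                                 rule = cleavage_rule(cfg$cleavage,
                                                      cfg$max_missed),
                                 scheme = cfg$scheme, min_len = cfg$min_len,
                                 max_len = cfg$max_len,
                                 decoy_seed = cfg$decoy_seed)
  }
  spectra <- if (is.list(cfg$mgf)) cfg$mgf else read_mgf(cfg$mgf)
  list(index = index, spectra = spectra)
}

#' Run an end-to-end database search
#'
#' Digest/index the database (unless a prebuilt index is supplied), read the
#' spectra, score every mass-window candidate per spectrum with the
#' configured scorer, retain the top-k, run spectrum competition, peptide
#' collapse, pair competition and FDR estimation, and (optionally) write
#' mzTab, a detection report, a PIN file and a log.
#'
#' @param cfg a [search_config()].
#' @return object of class \code{search_result}: list with \code{scored}
#'   (per-spectrum top-k candidate scores with ranks), \code{psms} (one per
#'   spectrum), \code{detections} (a \code{detection_list}), \code{tmp},
#'   and run counts.
#' @export
run_search <- function(cfg) {
  stopifnot(inherits(cfg, "search_config"))
  inp <- load_search_inputs(cfg)
  index <- inp$index; spectra <- inp$spectra
  st <- local_rng_state(); on.exit(restore_rng_state(st))
  set.seed(cfg$seed)
  score_fn <- make_scorer(cfg$scorer, fragment_tol_ppm = cfg$fragment_tol_ppm,
                          aggregate = cfg$aggregate, scheme = cfg$scheme)
  scored <- vector("list", length(spectra))
  n_no_cand <- 0L
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    win <- precursor_window(s$precursor_mz, s$charge, cfg$precursor_tol_ppm)
    cand <- query_candidates(index, win)
    if (!nrow(cand)) { n_no_cand <- n_no_cand + 1L; next }
    cand$score <- score_fn(s, cand)
    o <- order(-cand$score, !cand$is_decoy, cand$peptide)
    cand <- cand[o[seq_len(min(cfg$top_k, nrow(cand)))], , drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
    cand$spectrum_id <- s$spectrum_id
    cand$precursor_mz <- s$precursor_mz
    cand$charge <- s$charge
    scored[[i]] <- cand
  }
  scored <- do.call(rbind, scored)
  if (is.null(scored))
    stop("no spectrum had any candidate in its precursor window")
  rownames(scored) <- NULL
  psms <- spectrum_competition(scored)
  tmp_res <- tmp(psms)
  survivors <- pair_competition(peptide_collapse(psms))
  det <- estimate_fdr(survivors, cfg$alpha)
  res <- structure(list(
    config = cfg, scored = scored, psms = psms, detections = det,
    tmp = tmp_res,
    counts = list(spectra_read = length(spectra),
                  spectra_with_candidates = length(spectra) - n_no_cand,
                  spectra_no_candidates = n_no_cand,
                  target_psms = tmp_res$T_inf, decoy_psms = tmp_res$D_inf,
                  accepted = attr(det, "n_accepted"))
  ), class = "search_result")
  if (!is.null(cfg$out_dir)) write_search_outputs(res, cfg$out_dir)
  res
}

write_search_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mztab(res$psms, file.path(out_dir, "psms.mztab"))
  write_pin(res$psms, file.path(out_dir, "psms.pin"))
  det <- as.data.frame(res$detections)
  rep <- data.frame(peptide = det$peptide,
                    score = sprintf("%.6f", det$score),
                    label = ifelse(det$is_decoy, "decoy", "target"),
                    fdr = sprintf("%.6f", det$fdr),
                    qvalue = sprintf("%.6f", det$qvalue),
                    accepted = as.integer(det$accepted))
  utils::write.table(rep, file.path(out_dir, "detections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cn <- res$counts
  writeLines(c(
    sprintf("scorer: %s (aggregate: %s)", res$config$scorer,
            res$config$aggregate),
    sprintf("seed: %d | decoy_seed: %d", res$config$seed,
            res$config$decoy_seed),
    sprintf("spectra read: %d", cn$spectra_read),
    sprintf("spectra with >=1 candidate: %d", cn$spectra_with_candidates),
    sprintf("target PSMs: %d | decoy PSMs: %d", cn$target_psms,
            cn$decoy_psms),
    sprintf("TMP: %.4f", res$tmp$tmp),
    sprintf("detections at alpha=%g: %d", res$config$alpha, cn$accepted)
  ), file.path(out_dir, "search.log"))
  invisible(out_dir)
}

#' @export
print.search_result <- function(x, ...) {
  cn <- x$counts
  cat("search_result:", cn$spectra_read, "spectra,",
      cn$spectra_with_candidates, "with candidates\n")
  cat(sprintf("  scorer %s | TMP %.4f | %d detections at alpha=%g\n",
              x$config$scorer, x$tmp$tmp, cn$accepted, x$config$alpha))
  invisible(x)
}

#' Compare scorers on identical candidate lists
#'
#' Every scorer consumes exactly the same per-spectrum candidate sets, so
#' differences in detections reflect the score function alone. Emits a
#' peptides-versus-FDR-threshold table per scorer and each scorer's TMP.
#'
#' @param cfg a [search_config()].
#' @param scorers character vector (>= 2) of scorer names.
#' @param thresholds FDR thresholds for the detection curve.
#' @return object of class \code{scorer_comparison}: data.frame with columns
#'   \code{scorer}, \code{threshold}, \code{detections}; TMP per scorer in
#'   attribute \code{tmp}.
#' @export
compare_scorers <- function(cfg, scorers,
                            thresholds = c(0.001, 0.002, 0.005, 0.01, 0.02,
                                           0.05, 0.1)) {
  stopifnot(length(scorers) >= 2)
  inp <- load_search_inputs(cfg)
  curves <- vector("list", length(scorers)); tmps <- numeric(0)
  for (si in seq_along(scorers)) {
    sc <- scorers[si]
    cfg_i <- cfg
    cfg_i$scorer <- sc
    cfg_i$index <- inp$index
    cfg_i$mgf <- inp$spectra
    cfg_i$out_dir <- NULL
    res <- run_search(cfg_i)
    survivors <- pair_competition(peptide_collapse(res$psms))
    det <- vapply(thresholds, function(a)
      attr(estimate_fdr(survivors, a), "n_accepted"), numeric(1))
    curves[[si]] <- data.frame(scorer = sc, threshold = thresholds,
                               detections = det)
    tmps[si] <- res$tmp$tmp
  }
  names(tmps) <- scorers
  structure(do.call(rbind, c(curves, make.row.names = FALSE)),
            class = c("scorer_comparison", "data.frame"), tmp = tmps)
}

#' @export
print.scorer_comparison <- function(x, ...) {
  cat("scorer_comparison (detections by FDR threshold):\n")
  print(stats::xtabs(detections ~ scorer + threshold, data = x))
  cat("\nTMP by scorer:\n")
  print(round(attr(x, "tmp"), 4))
  invisible(x)
}

#' Plot detection curves from a scorer comparison
#'
#' @param x a [compare_scorers()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scorer_comparison <- function(x, ...) {
  wide <- stats::xtabs(detections ~ threshold + scorer, data = x)
  graphics::matplot(as.numeric(rownames(wide)), wide, type = "b", pch = 1,
                    log = "x", xlab = "FDR threshold",
                    ylab = "peptides detected", ...)
  graphics::legend("topleft", colnames(wide), col = seq_len(ncol(wide)),
                   lty = seq_len(ncol(wide)), bty = "n")
  invisible(x)
}
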