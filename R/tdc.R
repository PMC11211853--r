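# Peptide-level target-decoy competition ("double competition"):
# spectrum-level competition -> per-peptide collapse -> target/decoy pair
# competition -> ranked FDR estimation with q-values.

#' Spectrum-level competition
#'
#' For every spectrum, retain the single top-scoring candidate (target or
#' decoy). Ties break toward the decoy, then toward the lexicographically
#' smaller peptide, so results are deterministic and conservative.
#'
#' @param scored data.frame of scored candidates with columns
#'   \code{spectrum_id}, \code{peptide}, \code{score}, \code{is_decoy} (and
#'   optionally \code{precursor_mz}, \code{charge}, \code{pair_id}).
#' @return one PSM row per spectrum.
#' @export
spectrum_competition <- function(scored) {
  if (!nrow(scored)) return(scored)
  o <- order(scored$spectrum_id, -scored$score, !scored$is_decoy,
             scored$peptide)
  s <- scored[o, , drop = FALSE]
  out <- s[!duplicated(s$spectrum_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse PSMs to one record per peptide
#'
#' Retains the top-scoring PSM for each distinct modified peptide sequence.
#'
#' @param psms data.frame of PSMs (one per spectrum).
#' @return best PSM per peptide.
#' @export
peptide_collapse <- function(psms) {
  if (!nrow(psms)) return(psms)
  o <- order(psms$peptide, -psms$score, psms$spectrum_id)
  s <- psms[o, , drop = FALSE]
  out <- s[!duplicated(s$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-decoy pair competition
#'
#' Each target competes against its generation-time decoy partner: the
#' higher-scoring matched side survives; an unmatched side automatically
#' loses; if neither is matched the pair contributes nothing; an exact tie
#' goes to the decoy. Pairs flagged as decoy collisions are dropped (with a
#' message giving the count).
#'
#' @param best peptide-level records from [peptide_collapse()] carrying
#'   \code{pair_id} and \code{is_decoy}; rows with collision flags are
#'   excluded.
#' @return the surviving records, one per contested pair at most.
#' @export
pair_competition <- function(best) {
  if (!nrow(best)) return(best)
  if (is.null(best$pair_id) || anyNA(best$pair_id))
    stop("pair_competition requires a pair_id for every peptide")
  if (!is.null(best$collision) && any(best$collision)) {
    message(sum(unique(best$pair_id[best$collision]) %in% best$pair_id),
            " collision pair(s) dropped")
    best <- best[!best$collision, , drop = FALSE]
  }
  o <- order(best$pair_id, -best$score, !best$is_decoy, best$peptide)
  s <- best[o, , drop = FALSE]
  out <- s[!duplicated(s$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' FDR estimation and acceptance over pair-competition survivors
#'
#' Survivors are ranked by score (best first; ties decoy-first then
#' lexicographic). At rank k with T_k targets and D_k decoys among ranks
#' 1..k, the FDR estimate is min(1, (D_k + 1) / T_k) (1 where T_k = 0).
#' q-values monotonize the FDR from the bottom of the list. The accepted set
#' comprises the targets among ranks 1..k*, where k* is the largest k with
#' (D_k + 1) / T_k < alpha.
#'
#' @param survivors data.frame from [pair_competition()].
#' @param alpha acceptance threshold on the estimated FDR (0 < alpha < 1).
#' @return object of class \code{detection_list}: the ranked data.frame with
#'   \code{T_k}, \code{D_k}, \code{fdr}, \code{qvalue}, \code{accepted}
#'   columns, plus attributes \code{alpha} and \code{n_accepted}.
#' @export
estimate_fdr <- function(survivors, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  d <- survivors
  if (nrow(d)) {
    o <- order(-d$score, !d$is_decoy, d$peptide)
    d <- d[o, , drop = FALSE]
    d$T_k <- cumsum(!d$is_decoy)
    d$D_k <- cumsum(d$is_decoy)
    raw <- ifelse(d$T_k > 0, (d$D_k + 1) / d$T_k, Inf)
    d$fdr <- pmin(1, raw)
    d$qvalue <- rev(cummin(rev(d$fdr)))
    pass <- which(raw < alpha)
    k_star <- if (length(pass)) max(pass) else 0L
    d$accepted <- !d$is_decoy & seq_len(nrow(d)) <= k_star
    rownames(d) <- NULL
  } else {
    d$T_k <- d$D_k <- d$fdr <- d$qvalue <- numeric(0)
    d$accepted <- logical(0)
  }
  structure(d, class = c("detection_list", "data.frame"),
            alpha = alpha, n_accepted = sum(d$accepted))
}

#' @export
print.detection_list <- function(x, ...) {
  cat("detection_list:", nrow(x), "peptides,",
      attr(x, "n_accepted"), "targets accepted at alpha =",
      attr(x, "alpha"), "\n")
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x)[
      c("peptide", "score", "is_decoy", "fdr", "qvalue", "accepted")], 10))
    if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  }
  invisible(x)
}

#' Target match percentage
#'
#' The proportion of spectra whose assigned (competition-winning) peptide is
#' a target rather than a decoy. A calibration-free measure of per-spectrum
#' ranking quality.
#'
#' @param psms one PSM per spectrum, as from [spectrum_competition()].
#' @return list with \code{T_inf}, \code{D_inf} and \code{tmp}.
#' @export
tmp <- function(psms) {
  if (!nrow(psms)) stop("TMP undefined: no PSMs")
  T_inf <- sum(!psms$is_decoy)
  D_inf <- sum(psms$is_decoy)
  list(T_inf = T_inf, D_inf = D_inf, tmp = T_inf / (T_inf + D_inf))
}

#' Stratify PSMs by precursor m/z quartile
#'
#' Returns the PSMs whose precursor m/z lies in the empirical bottom
#' (<= Q1) or top (>= Q3) quartile of the input's precursor m/z
#' distribution, enabling separate competition on low- and high-mass strata.
#'
#' @param psms data.frame of PSMs with \code{precursor_mz}.
#' @param quartile \code{"lower"} or \code{"upper"}.
#' @return the filtered PSM data.frame.
#' @export
stratify_by_precursor <- function(psms, quartile = c("lower", "upper")) {
  quartile <- match.arg(quartile)
  stopifnot(nrow(psms) >= 4)
  qs <- stats::quantile(psms$precursor_mz, c(0.25, 0.75), names = FALSE)
  keep <- if (quartile == "lower") psms$precursor_mz <= qs[1] else
    psms$precursor_mz >= qs[2]
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
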