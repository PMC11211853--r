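#' Cross-correlation score between binned spectra
#'
#' XCorr is the dot product of the observed and theoretical binned spectra
#' minus the mean dot product over the 150 nonzero bin offsets r in
#' -75..75: \deqn{XCorr(u,v) = <u,v> - (1/150) \sum_{r \ne 0} \sum_i v_i
#' u_{i-r}.} Out-of-range indices are treated as zero.
#'
#' @param u observed [bin_spectrum()] result.
#' @param v theoretical \code{binned_spectrum} of the same length and width.
#' @return the XCorr score.
#' @export
xcorr <- function(u, v) {
  uu <- if (inherits(u, "binned_spectrum")) u$u else u
  vv <- if (inherits(v, "binned_spectrum")) v$u else v
  if (length(uu) != length(vv)) stop("binned spectra differ in length")
  n <- length(uu)
  # window sums W_i = sum_{j=i-75}^{i+75} u_j via padded cumsum
  cs <- cumsum(c(0, uu))
  hi <- pmin(seq_len(n) + 75L, n)
  lo <- pmax(seq_len(n) - 75L, 1L)
  W <- cs[hi + 1L] - cs[lo]
  sum(uu * vv) - sum(vv * (W - uu)) / 150
}

#' Binned theoretical spectrum for XCorr
#'
#' Constant-intensity peaks: 50 at b/y ion bins, 10 at a-ion and neutral-loss
#' bins.
#'
#' @param peptide modified peptide string.
#' @param bin_width,offset,n_bins binning grid (match the observed spectrum).
#' @param max_charge maximum fragment charge.
#' @return a \code{binned_spectrum}.
#' @export
xcorr_theoretical <- function(peptide, bin_width = 1.0005079, offset = 0,
                              n_bins, max_charge = 1L) {
  fr <- theoretical_fragments(peptide, ions = c("b", "y", "a"),
                              max_charge = max_charge, losses = TRUE)
  v <- numeric(n_bins)
  b <- floor((fr$mz - offset) / bin_width) + 1L
  height <- ifelse(fr$series %in% c("b", "y"), 50, 10)
  ok <- b >= 1L & b <= n_bins
  for (i in which(ok)) v[b[i]] <- max(v[b[i]], height[i])
  structure(list(u = v, bin_width = bin_width, offset = offset),
            class = "binned_spectrum")
}

#' XCorr score of a peptide against an observed spectrum
#'
#' @param s a [spectrum()].
#' @param peptide modified peptide string.
#' @param bin_width,region_count binning parameters for [bin_spectrum()].
#' @return the XCorr score.
#' @export
xcorr_score <- function(s, peptide, bin_width = 1.0005079, region_count = 10) {
  fr_max <- max(theoretical_fragments(peptide, c("b", "y", "a"),
                                      losses = TRUE)$mz)
  n_bins <- ceiling(max(fr_max, if (length(s$mz)) max(s$mz) else 0) /
                      bin_width) + 76L
  u <- bin_spectrum(s, bin_width, region_count, offset = 0, n_bins = n_bins)
  v <- xcorr_theoretical(peptide, bin_width, 0, n_bins)
  xcorr(u, v)
}

#' Hyperscore from ion match counts
#'
#' \deqn{Hyperscore = \log(n_b! \, n_y! \, \Sigma I_b \, \Sigma I_y)} with
#' natural log, computed via log-gamma; 0 when either ion count or intensity
#' sum is zero.
#'
#' @param n_b,n_y matched b-/y-ion counts.
#' @param sum_Ib,sum_Iy sums of unit-normalized matched intensities.
#' @return the Hyperscore.
#' @export
hyperscore <- function(n_b, n_y, sum_Ib, sum_Iy) {
  if (n_b == 0 || n_y == 0 || sum_Ib <= 0 || sum_Iy <= 0) return(0)
  lgamma(n_b + 1) + lgamma(n_y + 1) + log(sum_Ib) + log(sum_Iy)
}

#' Hyperscore of a peptide against an observed spectrum
#'
#' Matches singly charged b/y fragments at the given tolerance and evaluates
#' [hyperscore()].
#'
#' @param s a [spectrum()].
#' @param peptide modified peptide string.
#' @param tol_ppm fragment tolerance in ppm.
#' @return the Hyperscore.
#' @export
hyperscore_score <- function(s, peptide, tol_ppm = 20) {
  fr <- theoretical_fragments(peptide, ions = c("b", "y"))
  m <- match_peaks(s, fr, tol_ppm)
  hyperscore(m$n_b, m$n_y, sum(m$I_b), sum(m$I_y))
}

#' Andromeda score of a peptide against an observed spectrum
#'
#' For each q in 1..q_max the spectrum is reduced to its q most intense peaks
#' per 100 m/z, the number k of matched theoretical peaks (same fragment set
#' as XCorr: b, y, a plus ammonia/water losses) is counted, and the match is
#' scored as \eqn{-10 \log_{10}} of the binomial tail
#' \eqn{P(X \ge k), X \sim Binom(n, q/100)}; the score is the maximum over q
#' (ties to the smaller q). \code{type = "pmf"} instead returns the maximal
#' bare binomial point probability \eqn{C(n,k) (q/100)^k (1-q/100)^{n-k}}.
#'
#' @param s a [spectrum()].
#' @param peptide modified peptide string (or a data.frame of fragments).
#' @param tol_ppm fragment tolerance in ppm.
#' @param q_max maximum peaks-per-window depth to try.
#' @param type \code{"tail"} (default) or \code{"pmf"}.
#' @return the Andromeda score.
#' @export
andromeda_score <- function(s, peptide, tol_ppm = 20, q_max = 10,
                            type = c("tail", "pmf")) {
  type <- match.arg(type)
  stopifnot(q_max >= 1)
  fr <- if (is.data.frame(peptide)) peptide else
    theoretical_fragments(peptide, ions = c("b", "y", "a"), losses = TRUE)
  n <- nrow(fr)
  best <- -Inf
  for (q in seq_len(q_max)) {
    sq <- top_q_filter(s, q)
    k <- match_peaks(sq, fr, tol_ppm)$k
    p <- q / 100
    val <- if (type == "tail") {
      if (k == 0) 0 else -10 * log10(stats::pbinom(k - 1, n, p, lower.tail = FALSE))
    } else {
      stats::dbinom(k, n, p)
    }
    if (val > best) best <- val
  }
  best
}
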