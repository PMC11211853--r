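#' Theoretical fragment ions for a peptide
#'
#' Generates singly to \code{max_charge}-charged b- and y-series m/z values,
#' optionally a-ions (b - CO) and ammonia/water neutral losses of each b and y
#' ion. An N-terminal modification delta is carried by every prefix (b-side)
#' fragment.
#'
#' @param peptide modified peptide string.
#' @param ions subset of \code{c("b", "y", "a")}.
#' @param max_charge maximum fragment charge.
#' @param losses if TRUE, add NH3 and H2O neutral-loss series for b and y.
#' @return data.frame with columns \code{series}, \code{index} (fragment
#'   number within the series), \code{charge}, \code{mz}.
#' @export
theoretical_fragments <- function(peptide, ions = c("b", "y"),
                                  max_charge = 1L, losses = FALSE) {
  tk <- tokenize_peptide(peptide)
  has_nt <- grepl("^\\[", tk$tokens[1])
  ntd <- if (has_nt) tk$masses[1] else 0
  rm_ <- if (has_nt) tk$masses[-1] else tk$masses
  n <- length(rm_)
  if (n < 2L) stop("peptide must have length >= 2")
  prefix <- cumsum(rm_)[seq_len(n - 1L)] + ntd
  suffix <- cumsum(rev(rm_))[seq_len(n - 1L)]     # suffix_i = last i residues
  b1 <- prefix + MASS_PROTON
  y1 <- suffix + MASS_WATER + MASS_PROTON
  base <- list()
  if ("b" %in% ions) base$b <- b1
  if ("y" %in% ions) base$y <- y1
  if ("a" %in% ions) base$a <- b1 - MASS_CO
  if (losses) {
    if ("b" %in% ions) {
      base$`b-NH3` <- b1 - MASS_NH3
      base$`b-H2O` <- b1 - MASS_H2O
    }
    if ("y" %in% ions) {
      base$`y-NH3` <- y1 - MASS_NH3
      base$`y-H2O` <- y1 - MASS_H2O
    }
  }
  out <- do.call(rbind, lapply(names(base), function(ser) {
    do.call(rbind, lapply(seq_len(max_charge), function(z) {
      data.frame(series = ser, index = seq_len(n - 1L), charge = z,
                 mz = (base[[ser]] + (z - 1) * MASS_PROTON) / z,
                 stringsAsFactors = FALSE)
    }))
  }))
  out[out$mz > 0, , drop = FALSE]
}

#' Match observed peaks to theoretical fragments
#'
#' A theoretical fragment at m/z m matches an observed peak within
#' m * tol * 1e-6; within each ion series every observed peak may support at
#' most one fragment, with the closest-m/z pairing winning. Matched
#' intensities are unit-normalized by the spectrum's maximum intensity.
#'
#' @param s a [spectrum()].
#' @param fragments data.frame from [theoretical_fragments()].
#' @param tol_ppm fragment tolerance in ppm (> 0).
#' @return list with \code{n_b}, \code{n_y}, \code{I_b}, \code{I_y}
#'   (b/y-series counts and unit-normalized matched intensities) and
#'   \code{n}, \code{k} (total theoretical and matched peak counts over all
#'   series in \code{fragments}).
#' @export
match_peaks <- function(s, fragments, tol_ppm) {
  stopifnot(tol_ppm > 0)
  max_int <- if (length(s$intensity)) max(s$intensity) else 0
  res <- lapply(split(fragments, fragments$series), function(fr) {
    nf <- nrow(fr)
    if (!length(s$mz) || nf == 0L)
      return(list(k = 0L, I = numeric(0)))
    # all (fragment, peak) pairs within tolerance, closest-distance greedy
    cand <- do.call(rbind, lapply(seq_len(nf), function(i) {
      tol <- fr$mz[i] * tol_ppm * 1e-6
      jj <- which(s$mz >= fr$mz[i] - tol & s$mz <= fr$mz[i] + tol)
      if (!length(jj)) return(NULL)
      data.frame(f = i, p = jj, d = abs(s$mz[jj] - fr$mz[i]))
    }))
    if (is.null(cand)) return(list(k = 0L, I = numeric(0)))
    cand <- cand[order(cand$d), , drop = FALSE]
    used_f <- logical(nf); used_p <- logical(length(s$mz))
    I <- numeric(0)
    for (r in seq_len(nrow(cand))) {
      f <- cand$f[r]; p <- cand$p[r]
      if (!used_f[f] && !used_p[p]) {
        used_f[f] <- TRUE; used_p[p] <- TRUE
        I <- c(I, s$intensity[p] / max_int)
      }
    }
    list(k = sum(used_f), I = I)
  })
  kb <- res[["b"]]; ky <- res[["y"]]
  list(
    n_b = if (is.null(kb)) 0L else kb$k,
    n_y = if (is.null(ky)) 0L else ky$k,
    I_b = if (is.null(kb)) numeric(0) else kb$I,
    I_y = if (is.null(ky)) numeric(0) else ky$I,
    n = nrow(fragments),
    k = sum(vapply(res, `[[`, integer(1), "k"))
  )
}
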