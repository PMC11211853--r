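#' Construct a spectrum object
#'
#' @param spectrum_id character identifier.
#' @param precursor_mz observed precursor m/z.
#' @param charge precursor charge (>= 1).
#' @param mz,intensity fragment peak vectors; peaks are stored sorted by m/z.
#' @return object of class \code{spectrum}.
#' @export
spectrum <- function(spectrum_id, precursor_mz, charge, mz, intensity) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0), charge >= 1)
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum %s: precursor %.4f m/z (%d+), %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$charge, length(x$mz)))
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS and CHARGE lines.
#' Charge lines like \code{"2+"} are parsed to integer 2; blocks with no
#' CHARGE line are skipped (with a message giving the count) rather than
#' guessed.
#'
#' @param path path to an MGF file.
#' @return a list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  spectra <- list()
  n_skipped <- 0L
  i <- 1L; block_i <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      block_i <- block_i + 1L
      title <- paste0("index=", block_i)
      pepmass <- NA_real_; charge <- NA_integer_
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (ln == "") { i <- i + 1L; next }
        if (grepl("^TITLE=", ln)) {
          title <- sub("^TITLE=", "", ln)
        } else if (grepl("^PEPMASS=", ln)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (grepl("^CHARGE=", ln)) {
          charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        } else if (grepl("^[A-Z]+=", ln)) {
          # other headers ignored
        } else {
          f <- strsplit(ln, "\\s+")[[1]]
          v <- suppressWarnings(as.numeric(f[1:2]))
          if (length(f) < 2L || anyNA(v)) {
            stop("unparseable peak line ", i, " in ", path, ": '", ln, "'")
          }
          mz <- c(mz, v[1]); int <- c(int, v[2])
        }
        i <- i + 1L
      }
      if (is.na(charge)) {
        n_skipped <- n_skipped + 1L
      } else {
        spectra[[length(spectra) + 1L]] <-
          spectrum(title, pepmass, charge, mz, int)
      }
    }
    i <- i + 1L
  }
  if (n_skipped > 0L) message(n_skipped, " spectra without charge skipped")
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$charge),
                 sprintf("%.6f %.6f", s$mz, s$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Keep the q most intense peaks per m/z window
#'
#' Within each half-open window \code{[k w, (k+1) w)} the \code{q} highest
#' intensity peaks are retained; intensity ties break toward lower m/z.
#' Idempotent: filtering twice equals filtering once.
#'
#' @param s a [spectrum()].
#' @param q peaks to keep per window (>= 1).
#' @param window window width in Da (default 100).
#' @return the filtered [spectrum()].
#' @export
top_q_filter <- function(s, q, window = 100) {
  stopifnot(q >= 1)
  if (!length(s$mz)) return(s)
  win <- floor(s$mz / window)
  keep <- unlist(lapply(split(seq_along(s$mz), win), function(ii) {
    o <- ii[order(-s$intensity[ii], s$mz[ii])]
    o[seq_len(min(q, length(o)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  spectrum(s$spectrum_id, s$precursor_mz, s$charge,
           s$mz[keep], s$intensity[keep])
}

#' Bin and normalize a spectrum for cross-correlation scoring
#'
#' Peak intensities are accumulated into bins of width \code{bin_width}
#' starting at \code{offset}, square-root transformed, and the bin range is
#' divided into \code{region_count} equal regions, each scaled so that its
#' maximum is 50 (empty regions stay zero). The bin width default
#' 1.0005079 Da is the classic cross-correlation setting.
#'
#' @param s a [spectrum()].
#' @param bin_width bin width in Da.
#' @param region_count number of normalization regions.
#' @param offset m/z of the left edge of bin 1.
#' @param n_bins vector length; defaults to covering the largest peak.
#' @return object of class \code{binned_spectrum}: list with \code{u}
#'   (intensity vector), \code{bin_width}, \code{offset}.
#' @export
bin_spectrum <- function(s, bin_width = 1.0005079, region_count = 10,
                         offset = 0, n_bins = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(n_bins)) {
    n_bins <- if (length(s$mz)) ceiling((max(s$mz) - offset) / bin_width) + 1L else 1L
  }
  u <- numeric(n_bins)
  if (length(s$mz)) {
    b <- floor((s$mz - offset) / bin_width) + 1L
    ok <- b >= 1L & b <= n_bins
    for (i in which(ok)) u[b[i]] <- u[b[i]] + s$intensity[i]
    u <- sqrt(u)
    reg <- ceiling(seq_len(n_bins) / (n_bins / region_count))
    reg[reg > region_count] <- region_count
    for (r in unique(reg)) {
      ii <- which(reg == r)
      mx <- max(u[ii])
      if (mx > 0) u[ii] <- u[ii] * 50 / mx
    }
  }
  structure(list(u = u, bin_width = bin_width, offset = offset),
            class = "binned_spectrum")
}
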