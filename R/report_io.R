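#' Write top-ranked PSMs to an mzTab file
#'
#' Emits a minimal-compliance mzTab: an MTD metadata section and a PSM
#' section whose rows carry the plain sequence, spectrum reference, charge,
#' precursor m/z, score (6 decimal places) and a target/decoy flag plus the
#' full modified sequence as optional columns.
#'
#' @param psms data.frame with one row per spectrum: \code{spectrum_id},
#'   \code{peptide}, \code{score}, \code{is_decoy}, \code{precursor_mz},
#'   \code{charge}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mztab <- function(psms, path) {
  if (anyDuplicated(psms$spectrum_id))
    stop("write_mztab expects at most one PSM per spectrum")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "MTD\tmzTab-version\t1.0.0",
    "MTD\tmzTab-mode\tSummary",
    "MTD\tmzTab-type\tIdentification",
    "MTD\tdescription\tmsdbsearch PSM report",
    "MTD\tpsm_search_engine_score[1]\t[MS, MS:1001143, search engine specific score for PSMs, ]"
  ), con)
  hdr <- c("PSH", "sequence", "PSM_ID", "accession", "unique", "database",
           "database_version", "search_engine", "search_engine_score[1]",
           "modifications", "retention_time", "charge", "exp_mass_to_charge",
           "calc_mass_to_charge", "spectra_ref", "pre", "post", "start",
           "end", "opt_global_is_decoy", "opt_global_modified_sequence")
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(psms)) {
    calc <- (peptide_mass(psms$peptide) + psms$charge * MASS_PROTON) /
      psms$charge
    rows <- paste("PSM", strip_mods(psms$peptide), seq_len(nrow(psms)),
                  "null", "null", "null", "null", "msdbsearch",
                  sprintf("%.6f", psms$score), "null", "null", psms$charge,
                  sprintf("%.6f", psms$precursor_mz), sprintf("%.6f", calc),
                  psms$spectrum_id, "null", "null", "null", "null",
                  as.integer(psms$is_decoy), psms$peptide, sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read back an mzTab PSM section
#'
#' Line-oriented reader for files produced by [write_mztab()].
#'
#' @param path path to an mzTab file.
#' @return data.frame with \code{spectrum_id}, \code{peptide},
#'   \code{score}, \code{is_decoy}, \code{precursor_mz}, \code{charge}.
#' @export
read_mztab <- function(path) {
  lines <- readLines(path)
  psh <- strsplit(lines[grepl("^PSH\t", lines)][1], "\t")[[1]]
  rows <- lines[grepl("^PSM\t", lines)]
  if (!length(rows)) {
    return(data.frame(spectrum_id = character(0), peptide = character(0),
                      score = numeric(0), is_decoy = logical(0),
                      precursor_mz = numeric(0), charge = integer(0)))
  }
  f <- do.call(rbind, strsplit(rows, "\t"))
  col <- function(nm) f[, match(nm, psh)]
  data.frame(
    spectrum_id = col("spectra_ref"),
    peptide = col("opt_global_modified_sequence"),
    score = as.numeric(col("search_engine_score[1]")),
    is_decoy = col("opt_global_is_decoy") == "1",
    precursor_mz = as.numeric(col("exp_mass_to_charge")),
    charge = as.integer(col("charge")),
    stringsAsFactors = FALSE
  )
}

#' Write a Percolator input (PIN) feature file
#'
#' Tab-separated with the minimal feature set: score, precursor m/z, and
#' one-hot charge. ScanNr falls back to the ordinal of the PSM when the
#' spectrum id carries no scan number.
#'
#' @param psms data.frame with \code{spectrum_id}, \code{peptide},
#'   \code{score}, \code{is_decoy}, \code{precursor_mz}, \code{charge}.
#' @param path output path.
#' @param max_charge highest one-hot charge column.
#' @return \code{path}, invisibly.
#' @export
write_pin <- function(psms, path, max_charge = 5L) {
  con <- file(path, "w"); on.exit(close(con))
  ch_cols <- paste0("charge", seq_len(max_charge))
  writeLines(paste(c("PSMId", "Label", "ScanNr", "score", "precursor_mz",
                     ch_cols, "Peptide", "Proteins"), collapse = "\t"), con)
  if (nrow(psms)) {
    scan <- suppressWarnings(as.integer(sub("^.*scan=([0-9]+).*$", "\\1",
                                            psms$spectrum_id)))
    scan[is.na(scan)] <- seq_len(nrow(psms))[is.na(scan)]
    onehot <- vapply(seq_len(max_charge), function(z)
      as.integer(pmin(psms$charge, max_charge) == z), integer(nrow(psms)))
    if (nrow(psms) == 1L) onehot <- matrix(onehot, nrow = 1L)
    rows <- paste(psms$spectrum_id,
                  ifelse(psms$is_decoy, -1L, 1L), scan,
                  sprintf("%.6f", psms$score),
                  sprintf("%.6f", psms$precursor_mz),
                  apply(onehot, 1, paste, collapse = "\t"),
                  paste0("-.", psms$peptide, ".-"), "protein1",
                  sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Validate a PIN file's column structure
#'
#' Checks that every row has the header's field count, that Label is +/-1,
#' and that ScanNr and the feature columns are numeric.
#'
#' @param path path to a PIN file.
#' @return TRUE (invisibly) if valid; otherwise an error describing the
#'   first violation.
#' @export
validate_pin <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty PIN file")
  hdr <- strsplit(lines[1], "\t")[[1]]
  nf <- length(hdr)
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) != nf)
      stop("row ", i, " has ", length(f), " fields, expected ", nf)
    if (!f[2] %in% c("1", "-1")) stop("row ", i, ": Label must be 1 or -1")
    num <- suppressWarnings(as.numeric(f[3:(nf - 2)]))
    if (anyNA(num)) stop("row ", i, ": non-numeric feature field")
  }
  invisible(TRUE)
}
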