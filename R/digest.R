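#' Read a protein FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that uppercases lowercase
#' residues (with a warning) and preserves the description line.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns \code{id} (first word of the header),
#'   \code{description} (full header line) and \code{sequence}, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  seqs <- as.character(aas)
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    warning("lowercase residues found; uppercasing")
  }
  seqs <- toupper(seqs)
  desc <- names(aas)
  if (is.null(desc)) desc <- rep("", length(seqs))
  data.frame(
    id = sub("\\s.*$", "", desc),
    description = desc,
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' Parse a cleavage-rule string
#'
#' Rules use the compact enzyme notation \code{"[RK]|{P}"}: cut after any
#' residue inside \code{[...]} unless the next residue is inside \code{{...}}.
#'
#' @param rule rule string, e.g. \code{"[RK]|{P}"} for trypsin with proline
#'   suppression.
#' @param max_missed maximum number of missed (internal) cleavage sites.
#' @return an object of class \code{cleavage_rule}.
#' @export
cleavage_rule <- function(rule = "[RK]|{P}", max_missed = 1L) {
  stopifnot(max_missed >= 0)
  m <- regexec("^\\[([A-Z]+)\\]\\|(\\{([A-Z]*)\\})?$", rule)
  g <- regmatches(rule, m)[[1]]
  if (!length(g)) stop("cannot parse cleavage rule: ", rule)
  cut_after <- strsplit(g[2], "")[[1]]
  suppress_before <- if (nchar(g[4])) strsplit(g[4], "")[[1]] else character(0)
  bad <- setdiff(c(cut_after, suppress_before), names(AA_MASS))
  if (length(bad)) stop("non-standard residues in cleavage rule: ",
                        paste(bad, collapse = ","))
  structure(list(cut_after = cut_after, suppress_before = suppress_before,
                 max_missed = as.integer(max_missed)),
            class = "cleavage_rule")
}

#' Digest a protein sequence
#'
#' Cleavage sites fall after any residue in \code{cut_after} whose following
#' residue is not in \code{suppress_before}; protein termini always count as
#' boundaries. Every substring between boundaries spanning at most
#' \code{max_missed} internal sites is returned.
#'
#' @param protein protein sequence (uppercase string).
#' @param rule a [cleavage_rule()].
#' @return data.frame with columns \code{sequence} and \code{missed}.
#' @export
digest <- function(protein, rule = cleavage_rule()) {
  stopifnot(inherits(rule, "cleavage_rule"))
  n <- nchar(protein)
  if (n == 0L) return(data.frame(sequence = character(0), missed = integer(0)))
  res <- strsplit(protein, "")[[1]]
  # site i means a cut between residues i and i+1 (1-based)
  is_site <- res[-n] %in% rule$cut_after & !(res[-1] %in% rule$suppress_before)
  bounds <- c(0L, which(is_site), n)        # cut positions incl. termini
  bounds <- unique(bounds)
  k <- length(bounds)
  out_seq <- character(0); out_miss <- integer(0)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):min(k, i + 1L + rule$max_missed)) {
      out_seq  <- c(out_seq, substring(protein, bounds[i] + 1L, bounds[j]))
      out_miss <- c(out_miss, j - i - 1L)
    }
  }
  data.frame(sequence = out_seq, missed = out_miss, stringsAsFactors = FALSE)
}

#' Define a modification scheme
#'
#' @param static named numeric vector of static mass deltas by residue,
#'   applied unconditionally to every occurrence.
#' @param variable named numeric vector of variable deltas by residue.
#' @param nterm numeric vector of N-terminal deltas; at most one per peptide
#'   form, counted toward \code{max_variable}.
#' @param max_variable maximum number of variable modifications per peptide.
#' @return an object of class \code{mod_scheme}.
#' @export
mod_scheme <- function(static = c(C = 57.02146),
                       variable = c(M = 15.994915, N = 0.984016, Q = 0.984016),
                       nterm = c(42.010565, 43.005814, -17.026549, 25.980265),
                       max_variable = 3L) {
  stopifnot(max_variable >= 0)
  structure(list(static = static, variable = variable, nterm = nterm,
                 max_variable = as.integer(max_variable)),
            class = "mod_scheme")
}

fmt_delta <- function(d) sprintf("%+.6f", d)

#' Enumerate modified forms of a peptide
#'
#' Static modifications are applied to all matching residues in every form.
#' Every assignment of at most \code{max_variable} variable-modification
#' sites is emitted, crossed with no-N-terminal-mod plus each N-terminal
#' choice; an applied N-terminal modification counts toward the limit.
#'
#' @param sequence plain peptide sequence.
#' @param scheme a [mod_scheme()].
#' @return character vector of modified peptide strings.
#' @export
enumerate_modified_forms <- function(sequence, scheme = mod_scheme()) {
  res <- strsplit(sequence, "")[[1]]
  var_sites <- which(res %in% names(scheme$variable))
  max_v <- scheme$max_variable
  site_sets <- list(integer(0))
  if (length(var_sites) && max_v > 0) {
    for (k in seq_len(min(max_v, length(var_sites)))) {
      cmb <- if (length(var_sites) == 1L) list(var_sites) else
        utils::combn(var_sites, k, simplify = FALSE)
      site_sets <- c(site_sets, cmb)
    }
  }
  forms <- character(0)
  for (sites in site_sets) {
    toks <- vapply(seq_along(res), function(i) {
      d <- 0
      if (res[i] %in% names(scheme$static)) d <- d + scheme$static[[res[i]]]
      if (i %in% sites) d <- d + scheme$variable[[res[i]]]
      if (d != 0) paste0(res[i], "[", fmt_delta(d), "]") else res[i]
    }, character(1))
    core <- paste(toks, collapse = "")
    forms <- c(forms, core)
    if (length(sites) < max_v) {
      for (nt in scheme$nterm) {
        forms <- c(forms, paste0("[", fmt_delta(nt), "]-", core))
      }
    }
  }
  unique(forms)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Generate a shuffled decoy peptide
#'
#' The decoy is a permutation of the target's residue tokens that fixes the
#' C-terminal residue (preserving tryptic character); per-residue
#' modifications travel with their residues and an N-terminal modification
#' token stays at the N-terminus, so the decoy's mass equals the target's.
#' Up to 20 seeded retries avoid emitting the target itself; if that fails
#' (homopolymers, length <= 2 interiors) the decoy equals the target and is
#' flagged as a collision so downstream competition can drop the pair.
#'
#' @param target modified peptide string of the target.
#' @param seed integer seed; the shuffle is deterministic given it.
#' @return list with \code{peptide} (decoy string), \code{collision}
#'   (logical), and \code{source_target}.
#' @export
make_decoy <- function(target, seed = 1L) {
  tk <- tokenize_peptide(target)
  has_nt <- grepl("^\\[", tk$tokens[1])
  nt <- if (has_nt) tk$tokens[1] else ""
  resid <- if (has_nt) tk$tokens[-1] else tk$tokens
  n <- length(resid)
  decoy <- target; collision <- TRUE
  if (n > 2L) {
    interior <- resid[seq_len(n - 1L)]
    st <- local_rng_state()
    on.exit(restore_rng_state(st), add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
    for (try in seq_len(20L)) {
      perm <- sample(interior)
      cand <- paste0(nt, paste(c(perm, resid[n]), collapse = ""))
      if (cand != target) { decoy <- cand; collision <- FALSE; break }
    }
  }
  list(peptide = decoy, collision = collision, source_target = target)
}

local_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(st) {
  if (is.null(st)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", st, envir = globalenv())
}

#' Build a mass-indexed candidate store from a FASTA database
#'
#' Digests every protein, applies length bounds, drops peptides containing
#' ambiguous residues (B, Z, X, U, O) with a logged count, enumerates modified
#' forms, generates one shuffled decoy per unique target form, and sorts all
#' candidates by neutral mass for interval queries.
#'
#' @param fasta path to the protein FASTA, or a data.frame as returned by
#'   [read_fasta()].
#' @param rule a [cleavage_rule()].
#' @param scheme a [mod_scheme()].
#' @param min_len,max_len peptide length bounds (residues).
#' @param decoy_seed integer seed for decoy shuffling.
#' @param verbose print a digest summary.
#' @return an object of class \code{candidate_index}: a list with
#'   \code{peptides} (data.frame sorted by mass with columns \code{peptide},
#'   \code{base_seq}, \code{mass}, \code{is_decoy}, \code{pair_id},
#'   \code{collision}) and counts.
#' @export
build_peptide_index <- function(fasta, rule = cleavage_rule(),
                                scheme = mod_scheme(),
                                min_len = 6L, max_len = 50L,
                                decoy_seed = 1L, verbose = FALSE) {
  prot <- if (is.character(fasta)) read_fasta(fasta) else fasta
  pieces <- lapply(prot$sequence, digest, rule = rule)
  seqs <- unique(unlist(lapply(pieces, `[[`, "sequence")))
  len <- nchar(seqs)
  seqs <- seqs[len >= min_len & len <= max_len]
  amb <- grepl(paste0("[", paste(AMBIGUOUS_RESIDUES, collapse = ""), "]"), seqs)
  n_ambiguous <- sum(amb)
  seqs <- seqs[!amb]
  forms <- unlist(lapply(seqs, enumerate_modified_forms, scheme = scheme))
  forms <- unique(forms)
  n_targets <- length(forms)
  decoys <- vector("list", n_targets)
  for (i in seq_along(forms)) {
    decoys[[i]] <- make_decoy(forms[i], seed = decoy_seed + i)
  }
  d_pep <- vapply(decoys, `[[`, character(1), "peptide")
  d_col <- vapply(decoys, `[[`, logical(1), "collision")
  pep <- data.frame(
    peptide  = c(forms, d_pep),
    is_decoy = rep(c(FALSE, TRUE), each = n_targets),
    pair_id  = rep(seq_len(n_targets), 2L),
    collision = rep(d_col, 2L),
    stringsAsFactors = FALSE
  )
  pep$base_seq <- strip_mods(pep$peptide)
  pep$mass <- peptide_mass(pep$peptide)
  pep <- pep[order(pep$mass, pep$peptide), , drop = FALSE]
  rownames(pep) <- NULL
  idx <- structure(list(peptides = pep,
                        n_targets = n_targets,
                        n_ambiguous_dropped = n_ambiguous,
                        n_collisions = sum(d_col)),
                   class = "candidate_index")
  if (verbose) print(idx)
  idx
}

#' @export
print.candidate_index <- function(x, ...) {
  cat("candidate_index:", x$n_targets, "target forms,",
      sum(x$peptides$is_decoy), "decoys\n")
  cat("  mass range:", sprintf("%.3f-%.3f Da", min(x$peptides$mass),
                               max(x$peptides$mass)), "\n")
  cat("  decoy collisions:", x$n_collisions,
      "| ambiguous-residue peptides dropped:", x$n_ambiguous_dropped, "\n")
  invisible(x)
}

#' Query candidates by neutral-mass interval
#'
#' @param index a [build_peptide_index()] result.
#' @param interval numeric \code{c(lo, hi)} in Da (closed interval).
#' @return the candidate rows with mass in the interval, ascending by mass.
#' @export
query_candidates <- function(index, interval) {
  stopifnot(inherits(index, "candidate_index"), length(interval) == 2L)
  m <- index$peptides$mass
  lo <- findInterval(interval[1], m, left.open = TRUE) + 1L
  hi <- findInterval(interval[2], m)
  if (hi < lo) return(index$peptides[0, , drop = FALSE])
  index$peptides[lo:hi, , drop = FALSE]
}
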