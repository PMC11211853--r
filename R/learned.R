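# Teacher-forced autoregressive PSM scoring: a sequence model assigns each
# residue of a known peptide its conditional probability given the spectrum
# and the preceding residues; the PSM score is the mean log probability
# (log of the geometric mean).

PROB_FLOOR <- 1e-12
STOP_TOKEN <- "$"

model_registry <- new.env(parent = emptyenv())

#' Register a pluggable sequence model constructor
#'
#' Allows an externally trained autoregressive model to be used as the PSM
#' scorer: the constructor must return an object accepted by
#' [teacher_force()] (fields \code{alphabet} and \code{condprob}).
#'
#' @param name registry key; selected in configs as \code{"plugin:<name>"}.
#' @param constructor function(params) returning a \code{sequence_model}.
#' @export
register_sequence_model <- function(name, constructor) {
  stopifnot(is.function(constructor))
  assign(name, constructor, envir = model_registry)
  invisible(name)
}

#' Alphabet of residue tokens implied by a modification scheme
#'
#' Static modifications are folded into their residue's token; each variable
#' modification and each N-terminal modification is a distinct token, plus a
#' stop token.
#'
#' @param scheme a [mod_scheme()].
#' @return data.frame with columns \code{token}, \code{mass}, \code{is_stop},
#'   \code{is_nterm}.
#' @export
model_alphabet <- function(scheme = mod_scheme()) {
  tok <- character(0); mass <- numeric(0); ntm <- logical(0)
  for (r in names(AA_MASS)) {
    if (r %in% AMBIGUOUS_RESIDUES) next
    d <- if (r %in% names(scheme$static)) scheme$static[[r]] else 0
    t0 <- if (d != 0) paste0(r, "[", fmt_delta(d), "]") else r
    tok <- c(tok, t0); mass <- c(mass, unname(AA_MASS[r]) + d); ntm <- c(ntm, FALSE)
    if (r %in% names(scheme$variable)) {
      dv <- d + scheme$variable[[r]]
      tok <- c(tok, paste0(r, "[", fmt_delta(dv), "]"))
      mass <- c(mass, unname(AA_MASS[r]) + dv); ntm <- c(ntm, FALSE)
    }
  }
  for (nt in scheme$nterm) {
    tok <- c(tok, paste0("[", fmt_delta(nt), "]-"))
    mass <- c(mass, nt); ntm <- c(ntm, TRUE)
  }
  data.frame(token = c(tok, STOP_TOKEN), mass = c(mass, 0),
             is_stop = c(rep(FALSE, length(tok)), TRUE),
             is_nterm = c(ntm, FALSE), stringsAsFactors = FALSE)
}

#' Fragment-evidence sequence model
#'
#' A deterministic autoregressive model over peptide tokens that scores the
#' next token by the fragment-ion evidence it would explain: for candidate
#' token a with mass m_a, the b-ion of prefix+a and the complementary y-ion
#' (precursor neutral mass - prefix mass - m_a + proton) are looked up in the
#' observed spectrum, and the token's evidence is the summed max-normalized
#' intensity of peaks within \code{fragment_tol_ppm} of either ion. The stop
#' token receives \code{stop_bonus} when the prefix accounts for the
#' precursor mass (within \code{precursor_tol_ppm}) and is otherwise
#' impossible. The conditional distribution is softmax(beta * evidence).
#'
#' @param fragment_tol_ppm fragment-ion match tolerance (ppm).
#' @param beta softmax sharpness (> 0); larger values concentrate probability
#'   on the best-supported token.
#' @param stop_bonus evidence credited to a mass-consistent stop.
#' @param precursor_tol_ppm tolerance for declaring the prefix complete.
#' @param scheme [mod_scheme()] defining the token alphabet.
#' @return an object of class \code{sequence_model}.
#' @export
evidence_model <- function(fragment_tol_ppm = 20, beta = 5, stop_bonus = 1,
                           precursor_tol_ppm = 20, scheme = mod_scheme()) {
  stopifnot(beta > 0, fragment_tol_ppm > 0)
  alpha <- model_alphabet(scheme)
  res_i <- which(!alpha$is_stop)
  stop_i <- which(alpha$is_stop)
  masses <- alpha$mass
  tolf <- fragment_tol_ppm * 1e-6
  tolp <- precursor_tol_ppm * 1e-6

  condprob <- function(s, prefix_tokens) {
    mz <- s$mz
    cumint <- attr(s, ".cumint")
    if (is.null(cumint)) {
      ni <- if (length(s$intensity) && max(s$intensity) > 0)
        s$intensity / max(s$intensity) else s$intensity
      cumint <- c(0, cumsum(ni))
    }
    M <- s$charge * (s$precursor_mz - MASS_PROTON)
    pm <- if (length(prefix_tokens))
      sum(masses[match(prefix_tokens, alpha$token)]) else 0
    e <- numeric(nrow(alpha))
    if (length(mz)) {
      bmz <- pm + masses[res_i] + MASS_PROTON
      ymz <- M - pm - masses[res_i] + MASS_PROTON
      sum_win <- function(center) {
        lo <- center * (1 - tolf); hi <- center * (1 + tolf)
        ihi <- findInterval(hi, mz)
        ilo <- findInterval(lo, mz, left.open = TRUE)
        out <- cumint[ihi + 1L] - cumint[ilo + 1L]
        out[center <= 0] <- 0
        out
      }
      e[res_i] <- sum_win(bmz) + sum_win(ymz)
    }
    complete <- abs((pm + MASS_WATER) - M) <= M * tolp
    e[stop_i] <- if (complete) stop_bonus else -Inf
    z <- beta * e
    z <- z - max(z)
    p <- exp(z)
    p / sum(p)
  }

  structure(list(alphabet = alpha, condprob = condprob,
                 params = list(fragment_tol_ppm = fragment_tol_ppm,
                               beta = beta, stop_bonus = stop_bonus,
                               precursor_tol_ppm = precursor_tol_ppm)),
            class = "sequence_model")
}

prepare_spectrum <- function(s) {
  if (!is.null(attr(s, ".cumint"))) return(s)
  ni <- if (length(s$intensity) && max(s$intensity) > 0)
    s$intensity / max(s$intensity) else s$intensity
  attr(s, ".cumint") <- c(0, cumsum(ni))
  s
}

#' Teacher-force a peptide through a sequence model
#'
#' Instead of letting the model decode, the true token sequence is fed in and
#' the probability the model assigns to each true token, conditional on the
#' spectrum and the preceding tokens, is recorded. No search or decoding
#' occurs. Probabilities are floored at 1e-12 so downstream logs stay finite.
#'
#' @param model a \code{sequence_model}.
#' @param s a [spectrum()].
#' @param peptide modified peptide string.
#' @return numeric vector x_1..x_n of per-token probabilities in (0, 1].
#' @export
teacher_force <- function(model, s, peptide) {
  tk <- tokenize_peptide(peptide)
  miss <- setdiff(tk$tokens, model$alphabet$token)
  if (length(miss)) stop("token(s) outside model alphabet: ",
                         paste(miss, collapse = ", "))
  s <- prepare_spectrum(s)
  n <- length(tk$tokens)
  x <- numeric(n)
  for (i in seq_len(n)) {
    p <- model$condprob(s, tk$tokens[seq_len(i - 1L)])
    x[i] <- max(p[match(tk$tokens[i], model$alphabet$token)], PROB_FLOOR)
  }
  x
}

#' Aggregate per-token probabilities by geometric mean (log scale)
#'
#' \deqn{score = (1/n) \sum_i \log x_i,} the log of the geometric mean of
#' the x_i. Low-confidence positions are punished much more severely than by
#' the arithmetic mean, which is what makes this aggregate well suited to
#' ranking candidates that include poor matches.
#'
#' @param x per-token probabilities in (0, 1].
#' @return a score <= 0.
#' @export
aggregate_geometric <- function(x) {
  if (!length(x)) stop("empty score vector")
  stopifnot(all(x > 0), all(x <= 1))
  mean(log(x))
}

#' Aggregate per-token probabilities by arithmetic mean
#'
#' Provided for the ablation comparison against [aggregate_geometric()].
#'
#' @param x per-token probabilities in (0, 1].
#' @return the mean of x.
#' @export
aggregate_arithmetic <- function(x) {
  if (!length(x)) stop("empty score vector")
  mean(x)
}

#' Score candidate peptides for one spectrum
#'
#' Each candidate is teacher-forced through the model and aggregated; the
#' result is sorted by descending score with deterministic tie-breaking
#' (decoy first, then lexicographically smaller sequence).
#'
#' @param model a \code{sequence_model}.
#' @param s a [spectrum()].
#' @param candidates data.frame with at least \code{peptide}; an
#'   \code{is_decoy} column participates in tie-breaking.
#' @param aggregate \code{"geometric"} (default) or \code{"arithmetic"}.
#' @return the candidates data.frame with a \code{score} column, sorted.
#' @export
score_candidates <- function(model, s, candidates,
                             aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "geometric") aggregate_geometric else aggregate_arithmetic
  if (!nrow(candidates)) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  s <- prepare_spectrum(s)
  candidates$score <- vapply(candidates$peptide, function(p)
    agg(teacher_force(model, s, p)), numeric(1), USE.NAMES = FALSE)
  dec <- if ("is_decoy" %in% names(candidates)) candidates$is_decoy else
    rep(FALSE, nrow(candidates))
  o <- order(-candidates$score, !dec, candidates$peptide)
  out <- candidates[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a PSM scorer by name
#'
#' Returns a function \code{f(spectrum, candidates)} giving one score per
#' candidate row. Available scorers: \code{"evidence"} (teacher-forced
#' fragment-evidence model, geometric aggregate unless overridden),
#' \code{"xcorr"}, \code{"hyperscore"}, \code{"andromeda"}, \code{"random"}
#' (uniform scores; a calibration baseline), or \code{"plugin:<name>"} for a
#' registered model.
#'
#' @param name scorer name.
#' @param fragment_tol_ppm fragment tolerance for matching scorers.
#' @param aggregate aggregate for sequence-model scorers.
#' @param scheme [mod_scheme()] (alphabet for sequence-model scorers).
#' @param ... passed to the underlying model constructor.
#' @return a scoring function.
#' @export
make_scorer <- function(name, fragment_tol_ppm = 20,
                        aggregate = c("geometric", "arithmetic"),
                        scheme = mod_scheme(), ...) {
  aggregate <- match.arg(aggregate)
  if (grepl("^plugin:", name)) {
    key <- sub("^plugin:", "", name)
    if (!exists(key, envir = model_registry))
      stop("no registered sequence model named '", key, "'")
    model <- get(key, envir = model_registry)(list(...))
    agg <- if (aggregate == "geometric") aggregate_geometric else aggregate_arithmetic
    return(function(s, candidates) {
      s <- prepare_spectrum(s)
      vapply(candidates$peptide,
             function(p) agg(teacher_force(model, s, p)),
             numeric(1), USE.NAMES = FALSE)
    })
  }
  switch(name,
    evidence = {
      model <- evidence_model(fragment_tol_ppm = fragment_tol_ppm,
                              scheme = scheme, ...)
      agg <- if (aggregate == "geometric") aggregate_geometric else aggregate_arithmetic
      function(s, candidates) {
        s <- prepare_spectrum(s)
        vapply(candidates$peptide,
               function(p) agg(teacher_force(model, s, p)),
               numeric(1), USE.NAMES = FALSE)
      }
    },
    xcorr = function(s, candidates)
      vapply(candidates$peptide, function(p) xcorr_score(s, p),
             numeric(1), USE.NAMES = FALSE),
    hyperscore = function(s, candidates)
      vapply(candidates$peptide,
             function(p) hyperscore_score(s, p, fragment_tol_ppm),
             numeric(1), USE.NAMES = FALSE),
    andromeda = function(s, candidates)
      vapply(candidates$peptide,
             function(p) andromeda_score(s, p, fragment_tol_ppm),
             numeric(1), USE.NAMES = FALSE),
    random = function(s, candidates) stats::runif(nrow(candidates)),
    stop("unknown scorer: ", name)
  )
}
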