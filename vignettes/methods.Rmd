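---
title: "Scoring peptide-spectrum matches with a teacher-forced sequence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring peptide-spectrum matches with a teacher-forced sequence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Tandem mass spectrometry database search assigns to each observed MS2
spectrum the database peptide most likely to have generated it. A search
engine digests a protein database to candidate peptides, selects for each
spectrum the candidates whose neutral mass lies within a ppm window of the
precursor-derived mass, scores every peptide-spectrum match (PSM) with a
score function, and controls the false discovery rate (FDR) of the reported
peptide detections by competition against shuffled decoy peptides.

`msdbsearch` implements that whole loop at desk scale with a pluggable score
function. Its centerpiece is a *learned-score interface*: any autoregressive
sequence model that returns a conditional distribution over the next peptide
token given the spectrum and a sequence prefix can be used as the PSM score
function via teacher forcing. The three classic hand-designed scores —
XCorr, Hyperscore and Andromeda — are implemented alongside for comparison
on identical candidate lists.

## Teacher-forced scoring and the geometric mean

An autoregressive peptide sequencer defines
$p(s_i \mid \text{spectrum}, s_1,\dots,s_{i-1})$ over a token alphabet
(residues, modified residues, and a stop symbol). To score a *given*
peptide rather than decode a new one, the true tokens are fed in at each
step (teacher forcing) and the probability $x_i$ the model assigns to the
true token $s_i$ is recorded. The PSM score is the mean log probability

$$\mathrm{score}(s) = \frac{1}{n}\sum_{i=1}^{n} \log x_i,$$

the log of the geometric mean of the $x_i$. Relative to the arithmetic mean
of the $x_i$, the geometric mean punishes positions where the model is
uncertain much more severely: a single near-zero $x_i$ sinks the whole
score. That is the desired behavior when ranking candidates that include
outright wrong peptides, where calibration across good and bad matches
matters more than picking the best continuation. Both aggregates are
exposed (`aggregate_geometric()`, `aggregate_arithmetic()`) so the ablation
can be reproduced.

Decisions taken where the formulation is open:

* probabilities are floored at $10^{-12}$ before the log, keeping scores
  finite for tokens a model rules out entirely;
* the stop token's probability is **not** included among $x_1..x_n$ — the
  sum runs over the $n$ sequence tokens only;
* modified residues are distinct alphabet tokens (e.g. oxidized methionine),
  and an N-terminal modification is its own prefix token, mirroring the
  vocabularies of trained sequence models.

## The fragment-evidence reference model

Shipping a pretrained transformer is out of scope, so the package provides
a deterministic reference model, `evidence_model()`, that exercises the
same contract. For candidate next token $a$ with mass $m_a$ after a prefix
of mass $m_p$, the model computes the b-ion m/z of prefix$+a$ and the
complementary y-ion m/z (precursor neutral mass $-\,m_p - m_a$ + proton),
sums the max-normalized intensities of observed peaks within the fragment
tolerance of either ion, and passes the per-token evidence vector through a
softmax with sharpness $\beta$. The stop token receives a fixed evidence
bonus when the prefix mass accounts for the precursor mass within the
precursor tolerance and is impossible otherwise.

Defaults: $\beta = 5$ and stop bonus $1$, chosen once so that noiseless
spectra are scored confidently while jitter and noise degrade the
distribution gracefully; the fragment tolerance is shared with the search
configuration (20 ppm). The model is deliberately simple — it knows only
b/y evidence and mass bookkeeping — but it is a genuine conditional
distribution (non-negative, sums to one, deterministic), so every property
of the teacher-forcing machinery and the downstream FDR pipeline is
exercised exactly as it would be with learned weights. A trained model can
be plugged in through `register_sequence_model()`.

## Classic score functions

* **XCorr**: the observed spectrum is binned at 1.0005079 Da, square-root
  transformed, and normalized in 10 regions to a maximum of 50; the
  theoretical spectrum holds constant-intensity peaks (50 for b/y, 10 for
  a-ions and ammonia/water losses). The score is
  $\langle u,v\rangle - \tfrac{1}{150}\sum_{r=-75,\,r\neq 0}^{75}\sum_i v_i u_{i-r}$.
  The background sum excludes the zero offset: the normalizer 150 equals
  the number of *nonzero* offsets in $-75..75$, and with $r=0$ included the
  score of a spectrum against itself would no longer reduce to the plain
  dot product. The binning constants are not part of the score's printed
  definition anywhere; they follow the score's established lineage.
* **Hyperscore**: $\log(n_b!\,n_y!\,\Sigma I_b\,\Sigma I_y)$ over matched
  b/y counts and unit-normalized matched intensities, with natural log
  (the conventional reading of the bare "log") computed via log-gamma, and
  a score of 0 when either series has no matches.
* **Andromeda**: for each $q \le 10$ the spectrum is reduced to its $q$
  most intense peaks per 100 m/z and the number $k$ of matched theoretical
  peaks out of $n$ is scored as $-10\log_{10} P(X\ge k)$,
  $X\sim\mathrm{Binom}(n, q/100)$, maximized over $q$ (ties to smaller
  $q$). The original score is a binomial *tail* survival probability on a
  decibel scale; a formulation sometimes written as the bare point
  probability $\binom{n}{k}(q/100)^k(1-q/100)^{n-k}$ is available as
  `type = "pmf"` for fidelity testing, but the tail form is the default
  because the point mass is not monotone in match quality.

Peak matching is closest-wins within each ion series, each observed peak
supporting at most one fragment per series, at a relative tolerance (ppm of
the theoretical m/z).

## Digestion, modifications, decoys

Digestion follows a cleavage rule in `"[RK]|{P}"` notation (cut after R/K
unless followed by P) with up to one missed cleavage by default. The
default modification scheme is static carbamidomethyl-C (+57.02146 Da),
variable oxidation of M (+15.994915), deamidation of N and Q (+0.984016),
and four N-terminal modifications (+42.010565, +43.005814, −17.026549,
+25.980265), at most 3 variable modifications per peptide with an applied
N-terminal modification counting toward the limit. Peptide length bounds
default to 6–50 residues and the variable-modification cap to 3 — common
search-engine defaults adopted as this package's defaults. I and L are kept
distinct; peptide identity everywhere (uniqueness, collapse, pairing) is
the *modified sequence string*.

Each unique target form gets one decoy: a seeded shuffle of the residue
tokens that fixes the C-terminal residue, preserving tryptic character, the
residue multiset and hence the mass; per-residue modifications travel with
their residues. Up to 20 retries avoid emitting the target itself; when
that is impossible (homopolymers, length ≤ 2) the pair is flagged and
excluded from pair competition with a logged count. Monoisotopic residue
masses are the standard 20-residue table with water 18.0105646863 Da and
proton 1.00727646688 Da.

## FDR by peptide-level target-decoy competition

The pipeline is the double-competition procedure: (1) per spectrum, keep
the single best-scoring candidate (first competition); (2) per peptide,
keep its best PSM; (3) per target/decoy pair, keep the better-scoring
matched side — an unmatched side loses automatically; (4) rank survivors by
score and estimate FDR at rank $k$ as $\min(1, (D_k+1)/T_k)$, accepting
targets up to the largest $k$ with $(D_k+1)/T_k < \alpha$ (default
$\alpha = 0.01$, strict inequality). q-values are the running minimum of
the FDR from the bottom of the list, added for reporting; the acceptance
rule itself uses the raw estimate. All competition ties break toward the
decoy — the conservative choice — and then lexicographically, so runs are
deterministic. The target match percentage, TMP
$= T_\infty/(T_\infty + D_\infty)$, is reported as a calibration-free
companion measure, and `stratify_by_precursor()` supports separate
competition on the empirical bottom and top precursor-m/z quartiles.

## The synthetic-data generator

`simulate_proteome()` draws proteins uniformly over the 20 residues;
`simulate_spectra()` samples distinct digest peptides and emits singly
charged b/y fragments, each retained with probability $f$ (fragment
coverage), log-normal(0, 0.5) intensities, Gaussian m/z jitter in ppm, and
uniform noise peaks with intensities uniform on (0, median signal);
precursor m/z is back-computed from the peptide mass and a sampled charge
(2 or 3, probabilities 0.6/0.4) with jitter within half the precursor
tolerance. The reference conditions used by the package's own checks are a
50-protein × 300-residue database and, for signal runs, 200 spectra at
$f = 0.9$, 5 ppm jitter and 20 noise peaks; null runs use 500 spectra per
seed. These sizes keep every check a desk-scale computation while leaving
binomial standard errors small relative to the margins being tested.

`null_spectra()` generates spectra whose true peptides are *absent* from
the searched database, the condition under which accepted targets are false
by construction and FDR control is measurable. Null peptides are interior
shuffles of database peptides (C-terminus fixed), redrawn if the shuffle
collides with any digest peptide: this keeps every null spectrum
mass-matched to real candidates — a pure-random peptide would almost never
fall inside any ±20 ppm window, making the test vacuous — while
guaranteeing no target candidate is correct and targets and decoys are
exchangeable (TMP ≈ 0.5).

What the simulator does **not** emulate: realistic fragmentation intensity
patterns, isotope envelopes, multiply charged fragments, co-isolated
(chimeric) spectra, and retention time. Passing tests therefore demonstrate
the correctness of the scoring and FDR machinery and the qualitative
behavior of the score functions under coverage, jitter and noise — not
performance on instrument data, which depends on fragmentation chemistry
the evidence model does not attempt to capture.

## Numerical and degenerate-input choices

* Mass-interval candidate lookup is a binary search over mass-sorted
  peptides; interval endpoints are closed.
* Binomial tails use `pbinom` on the log-safe survival side; factorials use
  `lgamma`.
* Empty spectra are legal everywhere: binning yields zeros, matching yields
  zero counts, and the evidence model falls back to a uniform distribution
  over non-stop tokens.
* Spectra lacking a charge assignment are skipped on MGF read, not guessed.
* Ambiguous residues (B, Z, X, U, O) exclude the containing peptide from
  the index, with a count kept.
* All randomness (proteome, spectra, decoys, the random-baseline scorer)
  flows through explicit integer seeds; RNG state is saved and restored so
  package calls do not perturb a session's generator.

## Limitations

The evidence model is a stand-in realization of the sequence-model
contract, not a learned scorer; absolute detection counts on its synthetic
conditions say nothing about trained-model performance on real data.
Protein-level inference, semi-enzymatic digestion, isotope-error precursor
windows, Percolator's semi-supervised re-scoring (only its PIN input file
is exported) and raw/mzML reading are out of scope.
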