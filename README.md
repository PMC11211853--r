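# msdbsearch

A desk-scale tandem mass spectrometry database search engine for R, built
around a pluggable peptide-spectrum-match (PSM) score function. It is aimed
at method developers who want to study *score functions* — in particular,
scores derived from autoregressive peptide sequence models — and FDR
machinery under fully controlled, ground-truthed conditions, without the
weight of a production search engine.

The package implements:

* **In-silico digestion and indexing** — cleavage rules in `"[RK]|{P}"`
  notation with missed cleavages, static / variable / N-terminal
  modifications, mass-preserving shuffled decoys (C-terminal residue
  fixed), and binary-search candidate lookup by precursor mass window
  (±20 ppm defaults).
* **A teacher-forced learned score**. Any model exposing
  $p(s_i \mid \text{spectrum}, s_1..s_{i-1})$ over peptide tokens can score
  a PSM: the true sequence is fed in token by token and the per-position
  probabilities $x_1..x_n$ are aggregated as
  $\mathrm{score} = \frac{1}{n}\sum_i \log x_i$ — the log of the geometric
  mean, which punishes low-confidence positions far more severely than the
  arithmetic mean and therefore ranks poor candidates low. A deterministic
  fragment-evidence reference model (`evidence_model()`) exercises the
  contract; trained models plug in via `register_sequence_model()`.
* **Classic comparison scores** — XCorr (binned cross-correlation with
  background subtraction over ±75 bin offsets), the Hyperscore
  ($\log(n_b!\,n_y!\,\Sigma I_b\,\Sigma I_y)$), and the Andromeda score
  ($-10\log_{10}$ binomial tail of matched peak counts, maximized over the
  peaks-per-window depth $q$).
* **Peptide-level target-decoy competition FDR** — spectrum competition,
  per-peptide collapse, target/decoy pair competition, FDR estimated at
  rank $k$ as $\min(1,(D_k+1)/T_k)$ with acceptance at
  $(D_k+1)/T_k < \alpha$, q-values, target match percentage (TMP), and
  precursor-m/z quartile stratification.
* **Standard formats** — FASTA and MGF in; mzTab, Percolator PIN and a TSV
  detection report out.
* **A seeded spectrum simulator** — ground-truthed proteomes and MGF
  spectra with controllable fragment coverage, m/z jitter, noise peaks and
  intensity distributions, plus a null-spectrum generator (true peptides
  verifiably absent from the searched database) for FDR-control
  experiments.

See `vignettes/methods.Rmd` for the model, its assumptions, parameter
choices and limitations.

## Worked example

```r
library(msdbsearch)

sch  <- mod_scheme(variable = numeric(0), nterm = numeric(0))  # static C only
prot <- simulate_proteome(n_proteins = 50, protein_length = 300, seed = 101)
idx  <- build_peptide_index(prot, scheme = sch, decoy_seed = 101)
idx
#> candidate_index: 2138 target forms, 2138 decoys
#>   mass range: 571.333-6353.698 Da
#>   decoy collisions: 0 | ambiguous-residue peptides dropped: 0

sim <- simulate_spectra(prot, n_spectra = 200, fragment_coverage = 0.9,
                        mz_jitter_ppm = 5, noise_peaks = 20, seed = 102,
                        scheme = sch)
res <- run_search(search_config(mgf = sim$spectra, index = idx,
                                scorer = "evidence", scheme = sch, seed = 103))
res
#> search_result: 200 spectra, 200 with candidates
#>   scorer evidence | TMP 1.0000 | 200 detections at alpha=0.01
```

The index holds 2138 modified target peptides and one shuffled decoy each.
Searching 200 simulated spectra (90% fragment coverage, 5 ppm jitter, 20
noise peaks) with the teacher-forced evidence scorer assigns every spectrum
a target peptide (TMP = 1.0), and all 200 generating peptides are accepted
at 1% FDR. An uninformative baseline on the same candidates shows what
calibration failure looks like:

```r
res_r <- run_search(search_config(mgf = sim$spectra, index = idx,
                                  scorer = "random", scheme = sch, seed = 103))
res_r
#> search_result: 200 spectra, 200 with candidates
#>   scorer random | TMP 0.4850 | 0 detections at alpha=0.01
```

With random scores, targets and decoys win spectra at chance (TMP ≈ 0.5)
and the decoy-based FDR estimate correctly admits nothing.

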