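# apeg

**A**ffinity **P**rediction with **E**pi**G**enomic marks: a thermodynamic
model of transcription-factor (TF) occupancy in which local epigenomic marks
modulate site affinities, plus tools to fit, test, and simulate that model.

## Scientific problem

A TF's sequence preference, summarised as a position-specific weight matrix
(PSWM), explains only part of where the factor actually binds in vivo: two
genomic regions with identical motif matches can show very different ChIP
enrichment. One candidate explanation is the local chromatin state —
histone-modification and accessibility marks that make a site more or less
available. `apeg` formalises that idea in an equilibrium statistical-mechanics
framework, asks whether measured mark intensities significantly improve
occupancy predictions beyond sequence alone, and quantifies the magnitude and
sign of each mark's influence.

## The model

A regulatory region carries candidate sites \(i = 1, \dots, n\) for the TF.
Each configuration \(c \subseteq \{1,\dots,n\}\) of simultaneously bound,
non-overlapping sites has Boltzmann weight

\[ W(c) \;=\; \prod_{i \in c} q_i \;\times\; \prod_{\substack{i<j \text{ adjacent in } c}} \tilde\omega(i,j), \]

with the empty configuration given weight 1. The statistical weight of a
site is

\[ q_i \;=\; \beta_A \cdot a(S_i) \cdot \prod_k \gamma_k^{\,I_{k,i}\,[I_{k,i} > \sigma]}, \]

where

* \(\beta_A = [A]\,K(S_{\mathrm{con}})\) bundles the (unknown) nuclear TF
  concentration and the association constant of the consensus site — the two
  are not separately identifiable from occupancy data;
* \(a(S_i) = \exp(\mathrm{score}(S_i) - \mathrm{score}(S_{\mathrm{con}}))\)
  is the PSWM-derived affinity of the site relative to the consensus;
* \(I_{k,i}\) is the intensity of mark \(k\) at site \(i\) — the natural log
  of the enrichment ratio of the overlapping track window (an intensity of
  1.32 corresponds to a 3.74-fold enrichment);
* \(\gamma_k\) is the per-mark modulation factor (\(\gamma > 1\) activating,
  \(\gamma < 1\) repressive, \(\gamma = 1\) neutral), applied only where the
  intensity exceeds the threshold \(\sigma\) (default 0);
* \(\tilde\omega(i,j)\) equals the cooperativity factor \(\omega\) when two
  consecutively bound sites lie within `coop_distance` (default 100 bp) of
  each other and 1 otherwise.

The partition function \(Z = \sum_c W(c)\) and the marginal probability that
any site for TF \(A\) is bound,
\(P_A = (Z - Z_{\setminus A}) / Z\), are computed exactly by a linear-chain
dynamic program over sites sorted by position (log-domain, Rcpp kernel),
which handles steric exclusion of overlapping sites and nearest-neighbour
cooperativity. A brute-force enumerator over all \(2^n\) configurations is
included as an oracle and used throughout the test suite.

Model parameters (\(\ln\beta\), \(\ln\gamma_k\), optionally \(\ln\omega\))
are fit by maximising the Pearson correlation between predicted \(P_A\) and
observed region-level binding intensities, with multi-start quasi-Newton
optimisation. Significance of each mark is assessed by a permutation test:
track window intensities are shuffled, the model refit, and a two-sided
add-one p-value computed for \(|\ln\hat\gamma|\), with Holm correction
across marks.

## Worked example

Generate a synthetic cohort with a planted activating mark
(\(\ln\gamma = 1\)) and a decoy mark, fit the model, and scan both marks:

```r
library(apeg)

ds <- synth_dataset(synth_config(n_regions = 400, seed = 42))
ds$rs
#> region_set: 400 regions, 800 sites (TF1), 2 marks, observed intensities

f <- fit(ds$rs, "TF1", "mark_act", n_restarts = 10, seed = 1)
f
#> fit_result [TF1]: pearson r = 0.9798 (marks: mark_act; 10 restarts)
#> model_params
#>   beta: TF1=5.16
#>   gamma:
#>             TF1
#> mark_act 2.7448
#>   omega: 1, sigma: 0, coop_distance: 100 bp

sm <- scan_marks(ds$rs, "TF1", n_permutations = 50, seed = 1,
                 n_restarts = 6, null_restarts = 2)
print(sm, digits = 3)
#>    tf       mark gamma r_seq r_epi improvement  p_raw  p_adj
#> 1 TF1   mark_act 2.745 0.928 0.980    5.64e-02 0.0196 0.0392
#> 2 TF1 mark_decoy 0.994 0.928 0.928    1.33e-06 0.9804 0.9804
```

The causal mark is recovered near its planted value
(\(\hat\gamma = 2.74 \approx e\)) and flagged as significant; the decoy is
not. Closed-form sanity checks are equally direct — a single site with
association constant \(K\) reaches half-maximal occupancy at concentration
\(1/K\):

```r
half_max_concentration(sim_scenario(K_con = 1e-4, gamma = 1))
#> [1] 10000
half_max_concentration(sim_scenario(K_con = 1/3e5, gamma = 1))
#> [1] 3e+05
```

## Command-line interface

A thin CLI wraps the main workflows:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "apeg.R", package = "apeg"))')" \
  synth --seed 7 --n-regions 200 --out data/
```

Subcommands: `synth` (write a synthetic dataset as FASTA + bedGraph + BED),
`fit`, `scan-marks`, `predict`, `simulate` (concentration/noise and
cooperativity scenarios), and `variation` (site-strength and paired-allele
analyses). Exit code 2 signals a configuration error, 1 a runtime failure.

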