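---
title: "Partitioning a promoter by conservation and composition, and measuring expression robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning a promoter by conservation and composition, and measuring expression robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisrobust)
```

## The problem

A *C. elegans* promoter such as that of *unc-47* (a GABAergic marker
expressed in the 19 D-type motor neurons of the ventral nerve cord and in
the postanal neuron DVB) splits into two functionally distinct parts. The
proximal ~250 bp carry essentially all of the cross-species sequence
conservation and suffice to drive a spatially correct expression pattern.
The remaining ~1 kb of distal promoter shows no conserved blocks at all,
yet it is required for *robust* expression: without it, the fraction of
D-type neurons expressing a GFP reporter drops and varies between
individuals, and the ratio of DVB to D-neuron intensity disperses, most
dramatically under temperature stress. The distal sequence behaves as a
bulk-composition element — AT-rich, AA/TT-dinucleotide-enriched,
GC/CG-depleted, with a trinucleotide signature of nucleosome depletion —
and unrelated sequences of similar composition can substitute for it.

`cisrobust` implements the complete desk-side analysis around these
observations: conservation profiling that finds the proximal boundary,
composition scoring that predicts robustness-conferring fragments, genome
windowing that nominates candidates, and the nonparametric statistics that
quantify robustness of reporter expression. Because the original
microscopy measurements and promoter sequences are not deposited, the
package carries synthetic-data generators that emulate both kinds of
input; every claim the test suite makes is made against that stated world.

## Conservation profiling and the proximal boundary

`sliding_identity()` computes a Vista-style percent-identity profile over
windows of reference positions (defaults: window 20 bp, step 1 bp).
Windows are anchored on non-gap positions of the chosen reference row so
profile coordinates map directly onto the reference promoter; a gap or an
`N` in any row counts as a mismatch, and alignment columns where the
reference itself is gapped (insertions in other species) are skipped.

`call_blocks()` (threshold 0.70) merges maximal runs of qualifying
windows into conserved blocks; overlapping runs are merged so the output
intervals are disjoint, and raising the threshold can only shrink
coverage. `upstream_coords()` flips block coordinates into bp upstream of
the translation start (the reporter fusions place the ATG immediately 3'
of the promoter, so position 0 is the first base 5' of the ATG).

`call_boundary()` then grows a proximal cluster from the
start-codon-proximal block, absorbing blocks separated by at most
`max_gap` (default 50 bp — the scale at which the nearest conserved
motifs sit beyond the main conserved core); the boundary is the distal
edge of that cluster. How the ~250 bp boundary was originally read off a
Vista plot is not documented anywhere, so this clustering rule is a
declared convention of this package, not a reconstruction; on alignments
whose conservation is confined to the proximal 250 bp it recovers a
boundary within a window-width of 250 bp (`analysis/02`, and the
acceptance test asserts [230, 270]).

## Composition scores

All k-mer counting (`count_kmers()`) uses overlapping windows at step 1 —
the standard convention for composition statistics; windows containing
`N` are dropped from both numerator and total rather than imputed.
`collapse_classes()` merges each k-mer with its reverse complement, giving
the 10 canonical dinucleotide classes (AA/TT, AT, TA, AC/GT, CA/TG,
AG/CT, GA/TC, CC/GG, GC, CG); all 10 are always reported. Collapsing
makes every downstream score strand-invariant.

`enrichment()` reports `log2(f_target / f_baseline)` per class, the
display convention for composition bias relative to the reporter-vector
backbone. Log base 2 is a package choice (only "log scale" is documented
upstream). When any involved class count is zero, a pseudocount (default
0.5) is added to every class count of *both* profiles before frequencies
are recomputed — this keeps all bars finite and preserves the exact
antisymmetry `E(a,b) = -E(b,a)`, which a frequency-floor formulation
would break.

`at_enrichment_score()` returns the AA/TT class frequency as the primary
score — AA/TT enrichment is the feature named for robustness-conferring
fragments — with the loose mononucleotide A+T fraction alongside.

`nucleosome_depletion_score()` computes the weighted fold-enrichment

$$\mathrm{fold} = \frac{\sum_t w(t)\, f_{\mathrm{seq}}(t)}
                       {\sum_t w(t)\, f_{\mathrm{bg}}(t)},$$

over the 64 trinucleotides; 1.0 means no enrichment. The membership /
weights of nucleosome-depletion-preferring trinucleotides derive from
external nucleosome-positioning data that are not reprinted here, so the
table is a user-supplied input (`read_trinuc_table()`). The shipped
`trinuc_weights_synthetic_example.tsv` is a *synthetic* example — an
indicator of the eight A/T-only trinucleotides over a uniform background —
adequate for demonstrating and testing the score's mechanics, not a
reconstruction of any published table. Against it, a 1 kb fragment at the
distal-promoter composition scores ~2.9-fold (cf. the two-fold enrichment
reported for real robustness-conferring sequences), the backbone ~1.1 and
an AT-poor fragment ~0.26.

## Genome scanning

`segment_genome()` tiles contigs into non-overlapping 1 kb windows
(matching the size of the experimentally tested distal fragments);
trailing partial windows are dropped because scores on unequal lengths
are not comparable, and an optional `step` enables sliding scans.
`score_windows()` attaches `at_score`, the combined GC+CG class frequency
and optionally the nucleosome score; windows more than half `N` are
excluded with a warning. `select_candidates()` implements "enriched to a
similar extent": windows within a relative tolerance (default 10% — no
tolerance is documented upstream, this is the package convention) of a
reference score, ranked by closeness, ties broken by (contig, start) so
selection is deterministic; `mode = "depleted"` ranks ascending instead.
Annotation-aware filtering (genic vs intergenic) is deliberately out of
scope.

## Robustness statistics

Groups are keyed by (strain, temperature). Animals with no GFP anywhere
are treated as transgene losses (`drop_no_gfp()`) before count analyses;
DVB-negative or zero/missing-intensity animals are excluded from ratio
and scatter analyses only.

* `count_distribution()` — percentage histogram of the number of
  GFP-positive D-type neurons (0–19) per individual.
* `compare_counts()` — two-sided Wilcoxon rank-sum; exact when
  `n1 + n2 <= 20` without ties, otherwise normal approximation with tie
  and continuity correction. Whether the original analyses used the exact
  or approximate form is undocumented; both are provided and switched
  deterministically.
* `ratio_distribution()` — per-animal DVB/D intensity ratio and its
  log10.
* `compare_dispersion()` — Ansari-Bradley scale test on median-centred
  log ratios (raw-vs-log is undocumented upstream; log with median
  alignment is the default here so only scale is compared). Exact for
  pooled n ≤ 50 without ties; otherwise a normal approximation computed
  from the conditional moments of the midrank scores, which — unlike the
  un-tie-corrected mean in `stats::ansari.test`'s asymptotic branch —
  keeps the two-sided p exactly symmetric under sample swap.
* `scatter_distances()` — each animal is a point
  (log intensity_D, log intensity_DVB); the statistic is the Euclidean
  distance to the group centroid. Log base 10 by default; distances scale
  by `ln 10 / ln b` under a base change, and the downstream KS statistic
  is exactly base-invariant, so the choice is cosmetic.
* `compare_scatter()` — two-sample two-sided Kolmogorov-Smirnov on the
  distance distributions.

Raw p-values are reported throughout (matching how such test families are
reported for this assay); `adjust_bh()` exists behind an explicit call
and is never applied implicitly.

## The synthetic world

`gen_sequence()` draws from a first-order Markov chain with
`P(b|a) = f(ab) / sum_c f(ac)` and the stationary initial distribution. A
subtlety worth recording: an arbitrary nonnegative vector over the 16
dinucleotides is *not* necessarily achievable by any stationary sequence —
achievability requires consistent base marginals (each base equally often
as left and right member). `gen_sequence()` warns when the realized
stationary class frequencies (`realized_dinuc_freqs()`) depart from the
target by more than 0.01; `random_dinuc_freqs()` draws random *achievable*
compositions (stationary dinucleotide distributions of random transition
matrices) and is what the fidelity tests use. The three shipped
composition presets (`dinuc_preset()`) are exactly marginal-consistent by
construction: `distal_promoter` (AA/TT class 0.30, ~70% AT — typical of
*C. elegans* AT-rich intergenic/distal promoter sequence),
`vector_backbone` (~48% AT, plasmid-like) and `at_poor` (GC-rich,
coding-like).

`gen_expression()` draws, per animal,
`d_count ~ BetaBinomial(19, p, rho)` — beta-binomial because fragile
promoters show count histograms wider than binomial at matched mean, and
`rho` gives a single overdispersion knob (`rho = 0` is exactly binomial);
`dvb_expressed ~ Bernoulli(q_dvb)`; `log10 I_D ~ N(mu_d, sigma_d m(T))`
and `log10 I_DVB = log10 I_D + N(delta, sigma_r m(T))` when DVB is
expressed. Temperature enters only through the variance multiplier
`m(T)`; for the fragile preset `m(20) = 1, m(26) = 1.3, m(15) = 2`
because cold is the more destabilizing stress, while the robust preset is
nearly flat. Effect sizes for the presets are calibrated only to
reproduce the qualitative robustness ordering (robust full-length,
intermediate chimera, fragile proximal; cohort n = 200; `mu_d = 3.0`
(~1000 AU), `delta = 0` for the robust preset — a mean DVB/D ratio of
one — and `delta = -0.15` with reduced `q_dvb = 0.85` for the fragile
one); no quantitative histograms exist to calibrate against, and the
presets were fixed before the acceptance checks were run.

`recover_params()` closes the loop with method-of-moments estimates
(`p_hat = mean/19`, `rho_hat` from `Var = 19p(1-p)(1+18 rho)`,
`sigma_r_hat` = SD of the log ratio); at n = 200 over 20 seeds the mean
absolute errors stay within 0.02 (p) and 0.03 (sigma_r).

What a green suite establishes — and does not. The generators produce
clean bivariate log-normal intensities and exchangeable animals; real
microscopy data carry segmentation error, array-mosaicism, inter-strain
variance and detection floors that are *not* modelled (single-copy
integration effects are explicitly out of scope). Green tests therefore
certify the machinery — scores, profiles, tests, selection rules — and
the internal consistency of the stated world, not the biological effect
sizes.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere; BED output is standard
  BED6 with strand `"."`.
* Identical samples or all-tied data yield p = 1 with a degeneracy
  warning rather than an error; empty groups, all-`N` sequences and
  weight tables with zero background mass are errors.
* Candidate selection and block calling are fully deterministic,
  including tie-breaks.
* Generator seeds are explicit arguments; the caller's RNG state is
  saved and restored.

## Reproducing the analyses

The numbered drivers under `analysis/` run the four stages end to end on
synthetic inputs and write their tables under `results/`;
`scripts/acceptance.R --seed <int> --out <path>` replays the whole
pipeline headlessly. See the README for a worked example.
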