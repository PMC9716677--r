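---
title: "Models and methods for asymmetric double-knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for asymmetric double-knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkoscreen)
```

## The screen this package models

A pooled double-knockout (DKO) CRISPR screen asks which *pairs* of gene
losses change a phenotype beyond what each single loss explains. The design
implemented here is asymmetric: library slot 1 carries guides against
candidate immunotherapy-resistance genes, slot 2 carries guides against
recurrently mutated tumor suppressors, and the two slots are crossed
combinatorially. Each lentiviral construct encodes one guide per slot, so a
construct is the unit of counting. Alongside the DKO cross, every targeting
guide is also paired with non-targeting controls (NTCs) in the opposite slot
(single knockouts, SKO), and NTC x NTC pairs (DNTC) anchor the null.

Selection is immunological: a Cas9-expressing, antigen-presenting tumor line
carrying the library is co-cultured with cytotoxic T cells at increasing
effector-to-target (E:T) ratios, and surviving cells are sequenced. Guides
that disable antigen presentation or interferon signaling (the Jak1/Jak2
axis is the canonical example) dominate the surviving pool.

## The generative model

`simulate_screen()` draws from an explicit chain whose ground truth is known,
so every downstream statistic can be validated:

1. **Plasmid pool.** Construct abundances are log-normal
   (`plasmid_sigma`, default 0.5 on the natural-log scale), normalized to 1.
2. **Transduction bottleneck.** Integrations per cell are Poisson with mean
   `moi` (default 0.1; the low-MOI regime). Multiply infected cells are
   discarded, so the usable pool is the single-integration fraction
   `moi * exp(-moi) / (1 - exp(-moi))` of transduced cells, allocated
   multinomially by abundance. The number of transduced cells defaults to
   `coverage * n_constructs` with `coverage = 500` (a 500X screen).
3. **Selection.** A cell carrying genes (A, B) survives co-culture at ratio
   ET with probability
   `min(1, (1 - baseline_kill(ET)) * 2^(s(ET) * (beta1[A] + beta2[B] + gamma[A,B])))`.
   Fitness composes additively on the log2 scale, which makes
   "observed = expected under additivity" exactly the null the interaction
   module tests; `gamma` is the interaction term the screen exists to find.
   `s(ET) = ET / (1 + ET)` is non-decreasing and saturating, and
   `baseline_kill` rises from 0.1 at E:T 0.1 to 0.9 at E:T 5 (linear in
   log E:T), mirroring titrations in which only high ratios kill most
   neutral cells. Probabilities above 1 are clipped and the clip count
   reported: strong resistance effects make this regime reachable, and it is
   one reason interaction signals on top of very strong single-gene effects
   are attenuated in real screens.
4. **Sequencing.** Reads are gamma-multinomial: per-construct gamma
   multipliers with shape `1/nb_dispersion` (default dispersion 0.05)
   perturb the relative abundances, then a multinomial draw of `depth` reads.
   Marginally this is negative binomial (variance `mu + 0.05 mu^2`) while
   column sums stay exactly at the depth.

One plasmid sample and one pre-selection sample are emitted per run;
selection is drawn independently per (screen, E:T ratio) and each selected
pool is sequenced `replicates` times (technical replicates). Every operation
is a pure function of its inputs and a seed.

**What the simulator does not capture:** per-guide efficacy variation,
cell-intrinsic clonal heterogeneity, T cell dynamics (exhaustion, antigen
loss), PCR chimeras between cassettes, and index hopping. Passing recovery
tests on simulated screens therefore demonstrates that the statistics do
what they claim under the stated noise model, not that any particular real
dataset will behave as cleanly — real screens add guide-level dispersion
that would lower sensitivity at equal depth.

## Paired-guide counting

Reads are matched by fixed-offset extraction: the slot-1 spacer is read from
R1 at the 5' flank length, the slot-2 spacer from R2 at a configurable
offset (reverse-complemented first if the layout says so). Each spacer is
resolved exactly, then (optionally) against a Hamming-distance-1
neighborhood; a variant reachable from two guides is *ambiguous* and the
read is dropped rather than assigned. One substitution per spacer, and no
indels, is the standard operating point for pooled-screen readout. Pairs
whose two guides are both known but never cloned together are counted as
recombinants (lentiviral template switching) and excluded from the count
matrix. The indexed matcher is property-tested against a brute-force
minimum-Hamming-distance oracle, and `mapped + recombinant + unmapped =
total` holds by construction.

## Normalization and QC

Counts are normalized to counts-per-million and log2-transformed with a
pseudocount of 1 (configurable). The paper-style QC set is: sample PCA on
per-construct-centered log2 CPM; average-linkage clustering on
`1 - Pearson correlation`, which at k = 2 separates post-co-culture samples
from plasmid/pre-selection when selection is strong; per-E:T multiple
t tests on titration survival fractions (pooled variance by default, Welch
behind a flag) with two-stage step-up FDR across ratios; and Tukey box
statistics (type-7 interpolated quartiles, 1.5 x IQR whiskers — quartile
conventions differ across software, so ours is fixed and documented).

## Enrichment and the control-based empirical FDR

A construct's score is its mean log2 fold change over all selected
post-co-culture samples versus the pre-selection reference. The q value
compares, at every candidate threshold t, the rate of DNTCs at or above t
(with a +1 pseudocount) to the rate of all constructs at or above t, takes
the minimum over thresholds at or below the construct's score, and clips to
[0, 1]. The estimator is deliberately conservative, and its *resolution is
set by the control count*: the smallest attainable q is roughly
`N / ((#DNTC + 1) * k)` for k calls out of N constructs. This is why the
package defaults to 10 NTC guides per slot (about 5% of a realistic
position's guides, in line with pooled-screen practice) rather than a
minimal 2: with only a handful of DNTC combinations the +1-corrected
estimator can never certify a small FDR, and per-gene SKO summaries would
rest on a few constructs. Enrichment is one-sided (resistance = positive
fold change); depletion scoring is out of scope.

## Interaction calling

Gene-level summaries are medians across member constructs (robust to one
bad guide combination; mean behind a flag). For each gene pair the additive
expectation is `SKO(A) + SKO(B)` on the log2 scale. Observed DKO summaries
are regressed on the expectation by OLS — the fitted slope and intercept
absorb global attenuation such as guide-efficiency dilution and the common
normalization offset — and each pair's *externally* studentized residual is
computed by the closed form
`t_i = e_i / (s_(i) * sqrt(1 - h_ii))`, with
`s_(i)^2 = (SSE - e_i^2 / (1 - h_ii)) / (n - p - 1)`,
the construction behind the classical single-outlier test. Two-sided t tail
probabilities (df `n - p - 1`) are Bonferroni-adjusted by the number of
tested pairs (pairs with undefined residuals still count toward the family
— conservative). A pair is *additive* when its residual is positive and
adjusted p <= alpha (default 0.001), *subtractive* when negative and
significant, otherwise unclassified. Analysis is at gene-pair level on
scores pooled across screens, E:T ratios and replicates.

## Numerical choices and degenerate inputs

* Exact fits (SSE numerically zero relative to the fitted values) return
  all-zero studentized residuals instead of 0/0 noise.
* Exact leverage points (`h_ii` ~ 1) yield `NA` residuals with a warning;
  the Bonferroni family size is unchanged.
* Survival probabilities above 1 are clipped and counted, never silently.
* `sequence_counts()` at dispersion 0 is a plain multinomial; zero-abundance
  constructs always receive zero reads.
* All-zero sample columns, constant samples (undefined correlation),
  constant regression designs and empty selections are hard errors naming
  the offender.
* Ties in enrichment scores are handled by evaluating the FDR estimator at
  unique thresholds with "at or above" counting on the full tie block.

## Simulation study sizes

The bundled studies use: a 61 x 19 gene cross with 3 guides/gene and 10
NTCs/slot (12,931 constructs) at 500X coverage and 5e6 reads/sample with 2
E:T ratios x 3 replicates for interaction recovery (8 planted interactions
of |gamma| = 1.5 on neutral slot-1 genes, plus two beta = 3 resistance
genes — planting interactions away from the saturating strong genes avoids
the survival-probability clip confounding the additivity test, the same
reason real interaction signals on top of strong Jak1/2 effects are
modest); a control-rich 4 x 3 library (625 DNTCs of 1,023 constructs) for
validating the empirical-FDR estimator, whose resolution needs controls;
and an 8 x 4 library for QC and null checks. These sizes give each study
stable behavior at interactive run times.

## Known limitations

* The empirical FDR needs many DNTCs to certify small q values; libraries
  with few controls will see q values clip to 1 even for real hits.
* The additive null is on log2 survival; screens whose biology composes
  differently (e.g. epistasis through shared pathways) will register
  systematic, not pairwise, departures that OLS absorbs into the slope.
* Fixed-offset spacer extraction assumes a constant cassette layout; stagger
  bases or adapter drift require configuring offsets, not scanning.
* Counting tolerates substitutions only; indel-bearing reads are dropped.
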