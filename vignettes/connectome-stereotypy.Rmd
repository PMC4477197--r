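---
title: "Quantifying inter-individual connectome stereotypy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-individual connectome stereotypy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstereo)
```

## The question

Serial-section EM reconstructions give the synaptic wiring diagram of one
individual. Whether that diagram generalises — whether a second animal of
the same stage is wired the same way — is the stereotypy question.
`connstereo` operationalises it for cell-type-resolved circuits such as the
visual eye circuit of the nectochaete annelid larva: photoreceptors (PRC)
feeding primary interneurons (IN1), relay interneurons (INton, INint, INsn),
motoneurons (MN), and ciliated-band and muscle effectors.

Single cells cannot generally be matched one-to-one across individuals, but
cell types and body sides can. The package therefore compares individuals at
the level of the **grouped connectivity matrix**: cells are pooled into
`(cell_type, side)` groups, and the single-cell synapse-count matrix is
aggregated over the grouping.

## The grouped matrix and its aggregation rules

For presynaptic group $G$ and postsynaptic group $H$ with inter-group
synapse total $S_{GH} = \sum_{i \in G, j \in H} s_{ij}$:

* **neuronal targets** use the *averaged* synapse number. The default
  `pair_mean` divides by the number of cell pairs, $S_{GH}/(|G||H|)$; it is
  symmetric in the two group sizes, bounded by the per-pair counts, and
  exactly invertible (multiplying back by $|G||H|$ recovers $S_{GH}$, which
  the conservation tests exploit). The alternative `per_pre_mean`
  ($S_{GH}/|G|$) reads as "synapses contributed per presynaptic cell". The
  averaging denominator is genuinely underdetermined in the source
  convention, so both are exposed; both produce the same qualitative
  pattern on synthetic data, and `pair_mean` is the default for its
  symmetry.
* **effector targets** (ciliary bands, muscles) use the *total* synapse
  number: effectors integrate total drive, and their per-cell counts are
  not the quantity of interest.

Unpaired midline cells form their own `unpaired` side stratum. Fragments —
neurite pieces with no identifiable soma — are excluded from grouping;
they are accounted for separately by length binning (below). Autapses are
rejected by default since none occur in this circuit; a flag permits them
for other data.

## Comparing two individuals

`align_matrices()` restricts both grouped matrices to the shared group
keys; cell types found in only one individual are reported as dropped and
never correlated. The global statistic is the Spearman rank correlation
$\rho_s$ of the flattened **off-diagonal** cells (self-group cells are
structurally depressed in autapse-free data and are excluded). Ties get
average ranks, the universal Spearman convention.

Significance comes from a permutation test: the cells of one matrix are
permuted $B$ times and

$$p = \frac{1 + \#\{|\rho_s^\ast| \ge |\rho_s|\}}{B + 1}.$$

The add-one correction keeps $p$ positive and makes the smallest
reportable value at the default $B = 10^4$ about $10^{-4}$ — a floor, not
an asymptotic tail probability. Every stochastic result carries its seed
and $B$.

Two **zero policies** are offered because grouped matrices are sparse: the
default `all_cells` correlates every aligned off-diagonal cell (a literal
matrix correlation; concordant double zeros count as agreement), while
`union_support` keeps only cells with at least one synapse in either
individual. Double-zero inflation is a known artifact of the first policy
and the published convention is unstated, so neither is asserted as "the"
statistic; the acceptance script reports both.

Further comparison layers:

* the **combined matrix**, the cell-wise geometric mean
  $\sqrt{a_{GH} b_{GH}}$, whose support is exactly the intersection of the
  two supports — a connection survives only if seen in both animals;
* **per-type profiles**: each group's outgoing (presynaptic) and incoming
  (postsynaptic) grouped vectors over shared partner groups, correlated
  between individuals with the same machinery. Profiles constant in either
  individual yield `NA` rather than an error. Groups with fewer than
  `weak_floor = 5` total synapses in either individual are flagged
  `weakly_connected` — with so few synapses a rank correlation is
  uninformative, and these are exactly the groups expected to fail; the
  floor is a flagging threshold, not a filter;
* **reciprocal strength** between single cells,
  $\sqrt{s_{AB} s_{BA}}$ — zero unless both directions carry synapses;
* the **asymmetry score** of a neuron against its bilateral homolog: one
  minus the cosine similarity between the neuron's partner-group output
  vector and the homolog's side-mirrored vector. Mirror-symmetric pairs
  score 0; output onto entirely non-mirrored partners scores 1.

## Dataset accounting

Reconstruction bookkeeping lives in the same package because stereotypy
claims depend on it: `section_loss_rate()` (lost layers as a percentage of
the series, one decimal), `classify_fragments()` (lengths binned as
$[0,4)$, $[4,40]$, $(40,\infty)$ µm — values exactly at a threshold fall
in the closed middle bin, the most literal reading of the "4–40 µm"
notation), and `instantiate_ciliary_band()` (bilateral pairs plus unpaired
midline cells; 11 pairs + 1 gives the 23-cell prototroch).
`reclassify_motoneurons()` applies the effector-output rule: a motoneuron
candidate with no synapse onto any effector is relabeled a projection
interneuron candidate.

## Photoreceptor maturation

Developmental state is indexed by rhabdom volume (µm³). Three ordinary
least-squares regressions relate it to axon cable length (µm), outgoing
synapse count, and the **connectivity-maturation index** — implemented,
pluggably, as the fraction of a photoreceptor's outgoing synapses onto
designated mature target types (IN1 by default), with 0 for synapse-less
cells. The published index definition lives in earlier work and is not
restated in the text this package follows, so the fraction-onto-mature-
targets form is the package's own default and is swappable. Fits report
the slope, intercept, Pearson r, its two-sided p-value, and the 95%
pointwise confidence band for the mean response; no multiple-testing
correction is applied across the three panels, matching per-panel
reporting. Per-panel statistics are deliberately plain `lm()` machinery;
the tests verify them against explicit normal equations.

## The synthetic generator

Because the real reconstructions cannot ship with the package, every
stage is exercised against a generator that samples whole individuals
from a ground-truth **wiring template**. `make_default_template()` fixes
the study conditions: a feed-forward eye circuit with

* four photoreceptor eye groups whose dominant drive is the *crosswise*
  IN1, plus a weak ipsilateral branch from the posterior eyes only;
* a strong reciprocal IN1–IN1 motif;
* INsn cells driving each motoneuron group from both sides;
* motoneurons innervating contralateral ciliary bands and muscles;
* one right-side motoneuron (`MNr3`) that mirrors a left motoneuron's
  effector output but additionally synapses onto contralateral
  motoneurons — the left-right-asymmetric motif;
* a weakly wired `INpro → INvnc` trunk circuit (total synapses below the
  weak-connection floor, so those groups exercise the flagging path).

Mean weights are per cell pair and were fixed once from the circuit's
described connection strengths (strong sensory and muscle drive ~6–8,
relay connections ~3–4, the "several synapses" asymmetric motif 6 onto
three contralateral cells, trunk circuit 1).

`noise_model()` controls the deviation of a sampled individual from the
template:

| parameter | default | meaning |
|---|---|---|
| `dispersion` | 0.5 | gamma-mixed (NB2) count overdispersion, var $= m + d m^2$ |
| `dropout_p` | 0.05 | probability a true connection goes unobserved |
| `truncate_p` | 0.05 | probability a neuron is truncated |
| `truncate_frac` | 0.5 | fraction of outgoing links a truncated neuron loses |
| `fragment_rate` | 164 | expected untraceable fragments per individual |
| `deterministic` | FALSE | rounded means instead of sampled counts |

The defaults are the moderate-noise conditions used for the pipeline's
regression baseline (paired individuals correlate with mean $\rho_s >
0.8$); `dispersion = 0` gives plain Poisson counts, and `noise_free()`
gives the deterministic limit in which paired individuals are identical
and $\rho_s = 1$ exactly. Fragment cable lengths are log-normal
(meanlog 0.71, sdlog 2.42), matched to the observed fragment-length bin
proportions 100:46:18. All sampling is reproducible from a single seed,
which is recorded in the output.

`random_template()` keeps the cell groups but rewires connections
uniformly at random, deliberately ignoring every biological constraint —
including "effectors have no output" — so that two random templates share
no structure at all. Retaining shared structural zeros was measured to
bias the null correlation upward by ~0.09; the unconstrained rewiring
brings the 100-replicate null mean to ~0.000, which is what the null
calibration tests assert.

### What the generator does and does not emulate

It emulates count noise, missed connections, truncation and fragment
load — the main technical noise sources of serial-section reconstruction.
It does **not** emulate spatial structure (no geometry, no section-loss
correlation between nearby synapses), polyadic synapse expansion,
annotation errors that *merge* cells, or developmental left-right
covariance. Passing tests therefore show that the statistics behave
correctly under independent per-connection noise; they cannot show
robustness to spatially correlated artifacts.

## Numerical and design choices

* Spearman $\rho_s$ is computed as the Pearson correlation of midrank
  vectors; permutations reuse the precomputed ranks, so a permutation
  replicate costs one correlation. The comparison `|rho*| >= |rho|` is
  applied with a $10^{-12}$ slack so exactly-tied statistics count as
  extreme (conservative).
* Correlations of identical vectors can return $1 - \epsilon$ in floating
  point; exactness claims in the tests use $10^{-12}$ tolerances.
* Degenerate inputs fail loudly with classed conditions
  (`connstereo_degenerate_error` etc.): constant matrices, empty section
  counts, all-zero asymmetry vectors, sub-3-point regressions.
* Ties in `max_synapses_per_mn()` break lexicographically; an innervation
  of all zeros reports the lexicographically first motoneuron with 0.
* The per-type profile excludes the group's own-group cell, mirroring the
  global statistic's diagonal exclusion.

## Problem sizes in the test suite

The suite calibrates against simulation at sizes chosen to keep Monte-
Carlo error well below the asserted tolerances: 1,000 random tied vectors
for the Spearman oracle; 200 random matrix pairs each for support,
symmetry and conservation properties; 100 unrelated-template pairs for
the null mean; 500 replicates at 199 permutations for the uniformity of
the permutation p (compared with the Kolmogorov bound at α = 0.01 plus
the half-step of the achievable p grid); a 10-point dispersion grid with
12 pairs per point for monotonicity (one Monte-Carlo inversion
tolerated); and 50 replicates for template-mean recovery, asserted as an
ensemble z-statistic within 2 Monte-Carlo standard errors — at 50
replicates a per-entry 5% band is below Monte-Carlo resolution for the
weakest template edges, so the 5% check is applied to the matrix-level
total deviation.

## Known limitations

* **Asymmetry detection at full noise.** Under the default moderate-noise
  conditions the asymmetric motoneuron's score exceeds its
  mirror-symmetric peers' in only about 85% of replicates, not 95%: the
  motif's cosine offset (~0.2) is comparable to the spread of the
  mirror-pair noise floor once overdispersion and dropout act on a
  three-cell motif. In the Poisson-count limit the ranking holds in every
  replicate the suite checks. The corresponding strict assertion is kept
  at its stated threshold and documents this gap rather than loosening
  it.
* The comparison handles exactly two individuals; no multi-animal or
  spectral extensions.
* Group correspondence across individuals is by exact
  `(cell_type, side)` key equality; no fuzzy type matching.
* The maturation index default is one of several reasonable definitions;
  conclusions about "maturation" depend on it and it should be stated
  with any result.
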