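---
title: "Mapping heavy-ion-bombardment deletions from SNP-array cluster shifts"
author: "hibdel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping heavy-ion-bombardment deletions from SNP-array cluster shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hibdel)
```

## The problem

Heavy-ion bombardment (HIB) of bread wheat produces large chromosomal
deletions. Locating them is awkward in an allohexaploid: most loci exist in
three homoeologous copies (subgenomes A, B, D), and a 50-mer genotyping
probe usually hybridises to all of them. Losing one homoeolocus therefore
does not silence a probe — it shifts the probe's two-channel intensity
cluster, because the summed allele dosage across its hybridisation sites
changes. `hibdel` implements the full chain from exported cluster
coordinates to annotated deletion intervals, for a design consisting of a
euploid parent cultivar, HIB mutant lines, parent × mutant backcross F1s,
and a panel of unrelated HIB lines used as a second reference. It also
implements the downstream phenotype statistics: stem water-soluble
carbohydrate (WSC) remobilisation during grain filling, the trait the
deletions of the three fructan 1-exohydrolase (*1-FEH*) isoform genes were
created to dissect.

## The signal model

Infinium-style arrays report each probe × sample observation as polar
cluster coordinates: `NormTheta` (allelic ratio, 0 = pure A channel, 1 =
pure B channel) and `NormR` (total intensity). The generator models the
channel sums as linear in allele dosage over the probe's hybridisation
sites:

$$X = \sum_{i \in A\text{-sites}} g_i d_i + \epsilon_X, \qquad
  Y = \sum_{i \in B\text{-sites}} g_i d_i + \epsilon_Y,$$

with per-site gain $g_i$ (default 1 per allele copy), dosage $d_i \in
\{0, 1, 2\}$, independent Gaussian channel noise clamped at zero, and

$$\theta = \tfrac{2}{\pi}\,\mathrm{atan2}(Y, X), \qquad R = X + Y.$$

When both channels are zero the probe has no fluorescence: $\theta$ is
undefined (`NA`) and $R = 0$ — a *null allele*. The array vendor's actual
normalisation pipeline is not modelled; this is the standard polar
convention, and it reproduces the two behaviours the analysis relies on:
a deletion shifts $\theta$ and/or drops $R$ at multi-site probes, and
silences single-site probes.

Within one subgenome a locus carries 2 copies (euploid), 0 (homozygous
deletion) or 1 (heterozygous deletion in a backcross F1). The arctangent
makes $\theta$ non-linear in dosage, which matters for heterozygous
confirmation (below).

## Calling deletion markers

For each mutant, per-marker *cluster shifts* are computed as signed
reference-minus-sample differences on both axes, against two references:
the euploid parent, and the arithmetic mean cluster of the unrelated-HIB
panel. A marker is **flagged** when

$$|\Delta\theta| \ge 0.1 \quad\text{or}\quad |\Delta R| \ge 0.5$$

against the parent, and (by default) the same disjunction also holds
against the panel average. Values exactly at a threshold are flagged. Both
thresholds are configurable (`caller_config()`); the two reference
requirement (`require_panel_concordance`) can be relaxed, since the panel
is a corroborating tool rather than a hard filter. Markers whose *parent*
observation is itself a null are uninformative and never flagged.

Further evidence channels:

* **Null alleles** — `norm_r < null_floor` (default 0.2 in units where the
  per-allele gain is 1, i.e. a tenth of a euploid single-site probe's
  $R = 2$). Nulls at single-site probes are decisive: they place the
  deletion on that site's subgenome, which is how a candidate region is
  attributed to 6A vs 6B vs 6D (`assign_subgenome()`). Conflicting nulls
  leave a region `"unassigned"` with the votes reported.
* **HET confirmation** — in a backcross F1 a deleted locus is heterozygous,
  so its cluster should sit between the mutant and the euploid parent,
  near the midpoint. `confirm_het()` requires strict betweenness of
  $\theta_{F1}$ plus $|\theta_{F1} - (\theta_P + \theta_M)/2| \le$
  `het_tolerance`. Because $\theta$ is an arctangent of dosage, "halfway"
  is not exact: for a 3-site probe with one A site deleted the noise-free
  midpoint offset is 0.0084, and for a 2-site mixed-allele probe it is
  0.0452. The default tolerance of 0.05 covers the model's largest
  noise-free offset; for the 2-site class it leaves little noise headroom,
  which is a property of the geometry, not of the implementation. HET
  status is reported as indeterminate (`NA`) for unflagged markers, for
  single-site probes (their $\theta$ does not respond to dosage — their
  evidence channel is the $R$ drop), and wherever an observation is a null
  (a null's $\theta$ is a ratio of residual noise).
* **Biotype exclusion** — seed stocks of the same cultivar can differ at
  scattered markers ("biotypes"). When observations for both parent stocks
  (the stock the mutants derive from, and the stock used for backcrossing)
  are available, markers on which the stocks disagree by ≥ the theta
  threshold are removed from deletion evidence and listed in a report.
  Without this, stock heterogeneity masquerades as deletion signal in the
  F1 comparisons.

## From flagged markers to intervals

Flagged markers are segmented into *runs* per chromosome. Following array
marker-table convention, a multi-site probe is placed on **every**
chromosome it hybridises to, at that chromosome's site position (the same
SNP index legitimately appears under 6A, 6B and 6D at three different
positions). On the deleted chromosome the run is anchored at the deleted
sites themselves; on the other homoeologues the same probes form diffuse
*shadow runs*. Shadow runs contain no single-site nulls, so they come out
`"unassigned"` — the subgenome attribution is what separates the true
location from its homoeologous reflections, exactly as visual inspection
of single-site probes does in practice.

Within a chromosome, consecutive flagged markers belong to one run while
their gap is at most `gap_max`; runs need `min_markers` members (default
3). Unflagged markers inside a run's span are recorded as discordant
support but do not split the run (a probe can fail to shift when a
paralogous site masks the dosage change). `gap_max` defaults to 20× the
chromosome's median inter-marker spacing: under near-uniform marker
placement inter-marker gaps are approximately exponential, so the
probability of spuriously splitting a contiguous deletion at one gap is
about $e^{-20\ln 2} \approx 10^{-6}$, while regions tens of median
spacings apart still separate. A smaller multiplier (5×, say) splits a
40-marker run with appreciable probability ($1 - (1-e^{-5\ln 2})^{39}
\approx 0.7$), which is why the default is deliberately generous.

An interval's coordinates follow the flanking-marker convention: `start` is
the `span_start` of the first flanking marker, `end` the `span_end` of the
last (the member with the largest start), and `size = end − start` — the
plain difference, not `end − start + 1`, which is the convention under
which the published flanking coordinates reproduce the published sizes
exactly. Two consequences are worth stating plainly: the interval is
*nested inside* the true deletion (flanking markers sit inside it), so each
boundary underestimates the truth by up to the local marker spacing; and an
interval end can overhang a breakpoint by up to the probe span width (the
probe's anchored end is inside, its span extends past), which
`recover_truth(span_slack = )` accounts for.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: three 60 Mb model
subgenomes; 900 markers (≈ 1 per 200 kb, the density of a 90K array on a
17 Gb genome); 70% of probes multi-site; a 96-line unrelated panel;
per-channel noise SD 0.05 (euploid clusters are tight relative to the 0.1
theta threshold); biotype discordance at 2% of markers in the backcross
stock; and, as default ground truth, the three mapped deletion intervals on
6A (28.2 Mb), 6B (4.9 Mb) and 6D (1.6 Mb), each yielding a homozygous
mutant and a heterozygous backcross F1.

Among multi-site probes, 95% bind all three homoeoloci and 5% bind two.
The weighting reflects probe biology — homoeologue divergence across a
50-mer is within hybridisation tolerance, so a probe that cross-hybridises
at all almost always binds all three subgenomes, with two-site probes the
minority class of diverged or absent homoeoloci (e.g. tetraploid-derived
loci with no D copy). The mixture matters for HET confirmation: 2-site
probes carry the 0.0452 midpoint offset described above and pass the 0.05
tolerance only ~2/3 of the time under noise, so a panel dominated by
2-site probes would dilute the aggregate HET confirmation rate.

Homoeologous site positions are jittered ±2 Mb around the primary
position. Biotype discordance is an allele swap at the probe's primary
site in the backcross stock only.

Not emulated: raw two-colour intensities and the vendor normalisation
(GenTrain/GenCall), probe thermodynamics, base substitutions and
rearrangements (only deletions are simulated), linkage between markers,
and real 90K ascertainment structure. Passing tests on this generator
therefore demonstrate that the evidence chain is internally consistent and
recovers known truth under the stated signal model — not that the
thresholds are optimal for any particular real array export.

## WSC remobilisation statistics

Stem WSC concentration (% dry weight) peaks early under post-anthesis
water deficit and then declines as fructans are hydrolysed and remobilised
to the grain. The module reports, per line and treatment:

* `find_peak()` — the DAA (days after anthesis) of maximum stem WSC, ties
  broken to the earliest time point;
* `wsc_remobilisation()` — over a window (default 12→22 DAA, peak to
  permanent wilting point under deficit): `decline` $=$ WSC(12) − WSC(22)
  in %dw, and `rate` $=$ decline / 10 in %dw·day⁻¹. Both are exposed
  because the 10-day decline and the daily rate are one order of magnitude
  apart and easy to conflate;
* `relative_slowdown()` — (parent decline − line decline) / parent decline
  × 100;
* `wsc_correlate()` — Pearson's r with the two-sided t-based p-value
  (delegated to `stats::cor.test`).

The decline depends on the two window endpoints alone; it is deliberately
not a regression slope. Where published endpoint concentrations are
rounded, the recomputed decline can differ from a printed value in the
last decimal (e.g. endpoints 31 and 5.7 give 25.3); the module reports the
computed value and does not adjust it.

The bundled phenotype table (`wsc_phenotype_synthetic.csv`) is a synthetic
stand-in anchored at the published endpoint values (peak timings, peak
concentrations, 22-DAA concentrations, final grain weights), with
interpolated values at the remaining sampling stages; the raw trial data
are not public.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:

* the signal model against closed-form arctangent evaluations;
* noise-free end-to-end flagging against a brute-force loop over sites and
  dosages (300-marker panels, 100 seeds — exact set equality);
* noisy recovery of a 3 Mb deletion on a 900-marker panel (100 seeds,
  noise SD 0.05): interval present, nested, median boundary error below
  the median inter-marker spacing;
* HET confirmation in simulated F1s: strict betweenness at every
  informative marker (flagged, multi-site, defined thetas,
  $|\Delta\theta| \ge 0.1$) and ≥95% within the midpoint tolerance;
* specificity: zero intervals over 100 no-deletion simulations;
* biotype hygiene: excluded markers never reach a flanking set;
* interval gene queries against a brute-force overlap scan (1,000 random
  intervals over a 10-gene annotation);
* the correlation estimator against its sampling distribution (1,000
  bivariate simulations at ρ = 0.78, n = 24).

These sizes were chosen so the whole suite runs in a few minutes on one
CPU while keeping every stochastic assertion several standard errors away
from its pass boundary.

## Known limitations

* Breakpoints are resolved only to the flanking-marker grid; there is no
  sub-marker refinement and no joint multi-sample segmentation (no
  HMM/CBS-style CNV machinery).
* Subgenome attribution needs at least one single-site probe inside the
  deletion; short deletions in marker-sparse regions can stay
  `"unassigned"` even when correctly located.
* The keyword-based functional classifier is a convenience for triage; it
  is no substitute for curated annotation.
* The expression-negligibility screen is a max-over-samples ratio test
  with a configurable cut-off (default 0.1), reported alongside results —
  not a differential-expression model.
* Group-level inference on the phenotype (ANOVA/post-hoc structure) is out
  of scope; the module reports the defined statistics and descriptive
  summaries only.
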