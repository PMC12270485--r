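---
title: "Models and methods behind meiophos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiophos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

meiophos analyzes multiplexed (TMT) phosphoproteomic time courses of oocyte
meiotic maturation: nine biological timepoints (0, 2, 3, ..., 9 h after
progesterone stimulation) quantified in one isobaric plex together with two
phosphatase-treated "anchor" channels, in three biological replicates. This
vignette is the package's account of the statistical models it implements,
the knobs that matter, and the choices made where the design was open.

## The plex design and the forward model

A `plex_design` maps each channel to a timepoint and a loading (amount of
material, in oocyte-equivalents). The default (`default_design()`) has nine
regular channels (100 oocytes each), channel 10 an anchor of 100 oocytes
from the latest timepoint, and channel 11 an anchor mixing 50 oocytes of the
first and 50 of the last timepoint. Anchors are phosphatase treated, so any
peptide they contain is in its unmodified form.

For one phosphosite with occupancy $f_t \in [0,1]$ at timepoint $t$, on a
protein at relative level $r_t$, the expected (unnormalized) reporter
intensity in channel $c$ is

* regular channel at $t$: $L_c\, r_t\, f_t$ for the phospho form and
  $L_c\, r_t\, (1-f_t)$ for the unmodified form;
* anchor channel $d$ with mixture weights $w_{dt}$:
  $L_d \sum_t w_{dt} r_t$ for the unmodified form (the phosphatase converts
  everything) and only a leakage fraction $\varepsilon$ of that for the
  phospho form. Default $\varepsilon = 10^{-3}$: dephosphorylation is
  near-complete but not perfect.

Because reporter measurements are only *relative* (each form's signal is a
composition over channels), the anchors are what pins the absolute scale of
the unmodified form and makes occupancy identifiable.

## Peptide aggregation (`aggregate_counts`)

Reporter signal-to-noise is treated as an ion count (conversion factor
`kappa`, default 1). All peptide rows measuring the same protein or site
group are pooled by a conjugate Dirichlet–multinomial model:
posterior $\mathrm{Dir}(\alpha_0 + \sum_i x_i/\phi)$ with a flat prior
$\alpha_0 = 1$ per channel, where $\phi \ge 1$ is a method-of-moments
overdispersion (Pearson chi-square of the rows about the pooled share over
its degrees of freedom, floored at 1). Concordant peptides therefore tighten
the credible intervals while discordant peptides widen them — the role a full
hierarchical reporter-ion model plays in comparable pipelines — and
the closed form is testable against an independent grid-integration oracle,
which the test suite does for every 2-channel problem with totals up to 50.

Equal-tailed credible intervals come from the marginal Beta distributions.
Replicates are pooled as additional rows rather than averaged afterwards:
the counting model already weighs each row by its depth, so a deep replicate
counts for more than a shallow one, as it should.

One numerical note: the flat prior shifts posterior means by $O(1/N)$.
For noise-free synthetic data, where exact recovery is the property under
test, `prior_alpha = 0` and unrounded counts are used; with real (noisy)
counts the default prior is immaterial at realistic depths.

## Occupancy estimation (`estimate_occupancy`)

Each site's two forms give two observed share vectors (phospho $p$,
unmodified $u$). Writing the forward model's predicted shares as functions
of the occupancy vector $f$ (the normalizing constants are determined by
$f$ itself), the estimator minimizes

$$\sum_c w^p_c\,(p_c - \hat p_c(f))^2 + \sum_c w^u_c\,(u_c - \hat u_c(f))^2,
\qquad f \in [0,1]^T,$$

with weights the inverse squared credible-interval half-widths of each
channel. The minimization is a box-constrained quasi-Newton (L-BFGS-B) with
an analytic gradient, started from a closed-form anchor back-substitution
($D_u = A_d/u_d$, $1-f_t = u_c D_u / (L_c r_t)$), which is already exact on
noise-free data. An earlier fixed-point scheme that alternated per-timepoint
closed forms with normalizer updates was abandoned: its stationary point is
not the least-squares minimum and depends on the start, which both biased
estimates and collapsed bootstrap dispersion.

Credible intervals are obtained by refitting on draws from the Dirichlet
posteriors of all three input trends (phospho, unmodified, protein; default
500 draws) and taking 2.5/97.5 percentiles; each refit re-derives its own
starting point so that scale uncertainty propagates. The protein trend
defaults to uniform (flagged `protein-uniform`) when the protein was not
quantified. A site is excluded, not errored, when no unmodified partner
peptide was measured — in real datasets only a minority of sites qualify —
or when every candidate partner also spans a *different*
measured phosphosite: such a peptide's abundance tracks that other site's
occupancy too, and using it would bias the fit. With two anchors, their
implied scales are compared and a `anchor-inconsistent` flag is raised when
they disagree by more than 10%.

## Dynamics classes and protein trends

Stages are PRO = 0 h, MI = mean of 3 and 4 h, MII = mean of 7, 8 and 9 h
(read literally from the stage definitions). Phospho trends are divided by
the protein trend and rescaled to PRO = 1 before staging. Classes use
strict ±1 thresholds on $\log_2$FC(MI/PRO) ($x$) and $\log_2$FC(MII/MI)
($y$): I iff $x < -1$; II iff $x > 1$ and $|y| < 1$; III iff $x > 1$,
$y < -1$; IV iff $x > 1$, $y > 1$; V iff $|x| < 1$, $y > 1$; anything else,
including values exactly on a threshold, is unclassified — the class
definitions use strict inequalities, so ties go to no class. Values are
floored at $10^{-4}$ before ratios so the fold changes stay finite; floored
summaries are flagged. Protein trends use fold-change thresholds 1.5
(accumulating) and 0.75 (decreasing) on FC(MII/PRO).

Class percentages can be reported against two denominators — all quantified
phosphopeptides, or only the classifiable ones — and reported percentages in
the literature often mix the two; the census output exposes both counts
rather than choosing silently.

## Clustering and enrichment

`kmeans_cosine` is spherical k-means: rows unit-normalized, distance
$1 - \cos$, centroids normalized cluster means, best of `n_restarts`
seeded initializations, empty clusters re-seeded with the worst-fit points.
Clusters are relabeled by cardinality, most populated first (cluster 1 is
the largest — 1-based, as is idiomatic in R). The reference cluster counts
for full-size data are 60 (proteins) and 90 (phosphopeptides); the demo
pipeline caps k at half the number of trajectories so that toy runs remain
meaningful. Hand-rolling the clustering (rather than `stats::kmeans`) is
deliberate: the Euclidean objective of the standard implementation is not
the cosine objective, and the brute-force enumeration oracle in the tests
checks the spherical objective specifically.

Enrichment is the upper-tail hypergeometric test per annotation term with
Benjamini–Hochberg FDR across terms (`stats::phyper`, `stats::p.adjust`).

## Absolute quantification

Total soluble protein mass per oocyte (default 30 µg) is prorated over
proteins by their share of total precursor ion current; molarity follows
from the average molecular mass and the oocyte volume (sphere of diameter
1.2 mm ⇒ 0.905 µL). No peptide-detectability correction is applied — proration is by raw
summed ion current only, and alternative estimators are out of scope; this
is a documented limitation. Per-channel concentrations are the
reference concentration scaled by per-loading reporter shares.

## Motifs and cross-species matching

Degron and kinase-consensus scanning uses a mini-pattern syntax (literal
residues, `x` wildcard, `[..]` classes). The default degron set (D-box
`RxxL`, KEN-box `KEN`, SCF/βTrCP `DSGxxS`) is literature-standard
configuration, not a canonical definition — degron
annotations differ between curations — so any census output should name the
motif set used. PSSM scoring sums log2-odds over non-center
flank positions, with positions beyond the protein termini contributing 0
(neutral, not missing). Percentiles use strict rank (ties excluded), with a
midrank option; prediction applies a percentile threshold, default 90.

Cross-species site matching aligns protein pairs globally with free end
gaps under BLOSUM90 (shipped as a plain-text copy of the standard NCBI
matrix, since the installed alignment library does not bundle it) and
affine gaps 11/1, computes Karlin–Altschul E-values
($E = Kmn\,e^{-\lambda S}$, parameters configurable; defaults are the
common gapped-search values, and a raw-score threshold mode is provided as
a deterministic alternative), and keeps site pairs only when the alignment
passes $E$ strictly below $10^{-20}$, the positions align without a gap,
and both residues are identical phosphoacceptors. Requiring identity (not
merely both-S/T/Y) follows the phrase "matched ... phosphorylated
residues"; it is switchable. Since only one dataset is synthesized, the
demo pipeline exercises this module by treating the L and S homeologs of
the allotetraploid genome as two "species".

## The synthetic-data generator

`gen_proteome` draws uniform-composition sequences (this ignores real
amino-acid frequencies; nothing downstream depends on composition), with a
configurable fraction of L/S allo-allele pairs at 5% substitution
divergence. `simulate_trajectories` places sites on S/T/Y residues with the
residue mix typical of vertebrate phosphoproteomes (80% S / 19.9% T /
0.1% Y) and assigns
archetypal occupancy trajectories per class, each clearing its thresholds
with a margin of at least 0.25 log2 units; the default class mix (2/39/5/9/5%
and the rest unclassified) and protein trend mix (5% accumulating, 7%
decreasing) reflect the relative class sizes seen in oocyte maturation
phosphoproteomes. Protein archetypes reach 2× (or
0.5×) at 7 h and plateau, so the MII stage average is exactly the nominal
fold change.

`simulate_tables` draws a per-row depth from a log-normal (median `depth`,
`sigma_log` = 1 — reporter intensity spans orders of magnitude in real TMT
data), then multinomial reporter counts over channels from the forward
model. A fraction $1 - \texttt{phospho\_purity}$ (default 20%, matching
the ~80% enrichment purity the protocol attains) of phospho-table rows are
unmodified contaminants; these are allocated to cover phosphosites first,
because this flow-through contamination is precisely what provides
unmodified partner peptides in the same experimental conditions — without
it no occupancy would be computable. The unmodified form of a peptide
covering several sites gets the product of $(1-f)$ over all of them (the
abundance of the species unphosphorylated everywhere). Isolation
specificity is drawn uniformly on [0.5, 1]; the 0.75 post-search filter
then removes about half the rows, as a filter should have something to do.
`noise = FALSE` emits exact expectations with specificity 1, for
recovery-style tests.

What the generator does **not** emulate: co-isolation interference (the
specificity value is drawn independently of the signal), missing peptides,
chromatographic fractionation, variable ionization efficiency between
peptides, and composite multi-phospho species (sites are simulated
independently, so composite site-set handling is exercised by hand-built
fixtures instead). Passing recovery tests therefore shows the estimators
invert the stated forward model at realistic depths — not that they are
robust to every pathology of real spectra.

## Problem sizes and runtime choices

The shipped checks run at sizes chosen to finish in minutes on one core:
140 proteins / ~430 sites for occupancy recovery and CI calibration
(500 posterior draws per site at median depth $10^4$), 2-channel oracle
problems up to total count 50, and 120 trajectories for cluster recovery.
The demo pipeline (`run_pipeline(default_config())`) uses 60 proteins at
depth 2000 and completes in well under a minute, writing every stage's TSV
plus an md5 manifest; runs are byte-identical given the config seed.

## Known limitations

* The Dirichlet–multinomial aggregation is a deliberate, documented
  simplification of the original hierarchical Bayesian model; it preserves
  signal-weighted pooling and calibrated intervals but not that model's
  exact prior structure, and `kappa`/`prior_alpha` are exposed rather than
  guessed.
* Occupancy for composite site sets treats the set as one unit; per-member
  occupancies within a set are not resolved.
* Dataset-scale results from real experiments — total phosphopeptide
  counts, the specific list of occupancy-computable sites, per-protein
  concentrations, cross-species correlations — depend on the deposited raw
  data of a given study and are not reproduction targets for synthetic
  runs.
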