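# meiophos

Quantitative analysis of multiplexed (TMT) phosphoproteomic time courses of
oocyte meiotic maturation. The package is aimed at proteomics analysts who
have peptide-level reporter-ion tables from an isobaric time-course plex
that includes phosphatase-treated **anchor channels**, and who want
absolute phosphosite occupancy (stoichiometry), dynamics classification,
clustering, and the surrounding census machinery — plus a synthetic-data
generator that makes the whole pipeline testable end to end without any
raw data.

## What it computes

**Peptide aggregation.** All peptide measurements of one protein or
phosphosite group are pooled by a conjugate Dirichlet–multinomial model:
posterior Dir(α₀ + Σᵢ xᵢ/φ), with reporter S/N treated as ion counts and
φ ≥ 1 a method-of-moments overdispersion that discounts discordant
peptides. Shares are posterior means; credible intervals come from the
marginal Beta distributions.

**Phospho-occupancy.** For a site with occupancy f_t at timepoint t on a
protein at relative level r_t, the expected reporter signal in a regular
channel is L·r_t·f_t (phospho form) and L·r_t·(1−f_t) (unmodified form),
while a phosphatase-treated anchor channel carries the full dephosphorylated
signal. The occupancy trajectory is the weighted-least-squares fit of the
two observed share vectors to this forward model, f constrained to [0,1],
with credible intervals from refitting on posterior draws. The anchors make
f identifiable in absolute terms from purely relative measurements.

**Dynamics.** Stage summaries (PRO = 0 h, MI = mean of 3–4 h, MII = mean of
7–9 h) on protein-normalized trends; the five phosphosite classes from
strict ±1 thresholds on log₂FC(MI/PRO) and log₂FC(MII/MI); protein
accumulation classes at 1.5×/0.75×; spherical (cosine) k-means with
clusters ordered by cardinality; hypergeometric enrichment with BH FDR.

**Census tools.** Absolute protein concentrations from precursor ion
current prorated over isobaric fractions (30 µg soluble protein in a
1.2 mm oocyte); degron and kinase-consensus motif scanning; PSSM percentile
scoring of site flanks; cross-species phosphosite matching via BLOSUM90
alignment with Karlin–Altschul E-value filtering and Pearson correlation of
matched dynamics.

## Worked example

Simulate a small study with the default design (9 timepoints, 2 anchor
channels, 3 replicates), apply the isolation-specificity filter, estimate
occupancy, and classify a site:

```r
library(meiophos)
design <- default_design()
truth <- gen_proteome(n_proteins = 40, allo_allele_fraction = 0.3, seed = 1)
truth <- simulate_trajectories(truth, design = design, seed = 2)
tabs  <- simulate_tables(truth, depth = 5000, seed = 3)

phos <- filter_isolation_specificity(tabs$phospho)   # keep > 0.75 spectra
prot <- filter_isolation_specificity(tabs$proteome)
occ  <- occupancy_batch(phos, design, proteome_table = prot,
                        n_boot = 300, seed = 4)
occ$trajectories[[2]]
```

```
Occupancy trajectory (SP0001.L:T115)
             0h    2h    3h    4h    5h    6h    7h    8h    9h
occupancy 0.110 0.098 0.316 0.330 0.470 0.633 0.943 0.945 0.938
ci_low    0.101 0.089 0.303 0.314 0.455 0.615 0.935 0.937 0.930
ci_high   0.118 0.106 0.332 0.346 0.486 0.651 0.951 0.953 0.948
```

The planted truth for this site is (0.105, 0.105, 0.314, 0.314, 0.471,
0.627, 0.941, 0.941, 0.941): occupancy ~10% in prophase rising to ~94% by
the MII arrest, recovered within the intervals at every timepoint. Staging
its protein-normalized phospho trend,

```r
s  <- stage_summary(normalize_by_protein(ph, pr))  # see vignette for ph, pr
assign_class(s)
```

```
log2FC(MI/PRO) = 1.57, log2FC(MII/MI) = 1.56 -> Class IV
```

a progressive riser peaking at MII — the class that was planted. Sites
whose unmodified form was never measured are excluded with a reason
(`occ$exclusions`), mirroring the fact that occupancy is only computable
for the minority of sites with a measured unmodified partner.

The full demo pipeline (simulation → filter → aggregation → occupancy →
classes → clustering → enrichment → concentrations → degrons →
cross-species matching on L/S homeolog pairs) runs with

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "demo_run")
```

and writes one TSV per stage plus an md5 manifest; two runs with the same
seed are byte-identical.

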