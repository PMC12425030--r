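# mwfomics

Multi-omics validation of myelin water fraction (MWF) imaging biomarkers in
R.

MWF is the fraction of MRI-visible water attributed to water trapped between
the layers of the myelin sheath — a per-subject, per-region scalar in (0, 1)
that is widely used as an *in vivo* proxy for myelin content, but whose
biological specificity cannot be checked against histology in living
subjects. `mwfomics` implements the cross-modal validation strategy of
confronting an MWF measure with two independent molecular readouts:

1. **Plasma proteomics.** For every aptamer *j* on a SomaScan-style panel,
   an ordinary least squares fit

   *MWF_i = β₀ + β_j · log₂(abundance_ij) + γ₁·age_i + γ₂·age_i² +
   γ₃·sex_i + γ₄·eGFR_i + ε_ij*

   yields the protein–MWF association β_j with its t-based two-sided
   p-value. Genes with any aptamer at unadjusted p < α (default 0.05) form
   the positive and negative hit lists (volcano-plot surface).
2. **Cell-type specificity.** Each hit gene's nTPM profile across cell
   types is standardized with geometric-mean z-scores,
   *z_c = (ln x_c − mean ln x) / sd(ln x)*; brain-related cell types with
   z ≥ 2 define the gene's enrichment call (`none`, `single`,
   `oligoMultiCell`, `multiCell`), highlighting oligodendrocyte-lineage
   involvement.
3. **Pathway enrichment.** The positive and negative lists are tested
   against GMT gene-set libraries with the one-sided Fisher exact
   (hypergeometric) test over the assay-panel background,
   *p = Σ_{i≥k} C(K,i)·C(N−K,n−i)/C(N,n)*, reporting per library the top 5
   most significant pathways or all with p < 0.05, whichever is fewer.
4. **Spatial transcriptomics.** From a multi-donor expression atlas, one
   probe per gene is selected by differential stability (mean pairwise
   Spearman correlation of regional profiles across donor pairs), donor
   samples are assigned to atlas regions when within 2 mm of a labeled
   voxel center in MNI space, expression is aggregated donor-first, and
   regional mean MWF is regressed on regional mean expression, reporting
   the Pearson r and its p-value.

Because the cohort, proteomic, nTPM, and atlas resources such analyses use
are access-restricted, the package ships a first-class synthetic-data
generator (`simulate_study()`) with planted ground truth — true protein
effects, true enriched cell types, true over-represented pathways, a stable
probe, and a true regional myelin gradient — so every stage is testable by
parameter recovery.

## Worked example

```r
library(mwfomics)
cfg <- run_config("demo_run", seed = 1)
summary <- run_pipeline(cfg)
print(summary)
#> Pipeline run (mwfomics 0.1.0): ok
#>   simulate  ok
#>   associate ok
#>   annotate  ok
#>   enrich    ok
#>   spatial   ok
#>   counts:
#>     n_hits_positive = 35
#>     n_hits_negative = 39
#>     n_cell_specific = 15
#>     n_oligo_involved = 2
#>     n_reported_positive = 1
#>     n_reported_negative = 2
#>     n_regions = 12
#>     spatial_r = 0.9978
#>     spatial_p = 3.855e-13
#>     selected_probe = MBP_p1
```

Reading the counts: of 500 simulated aptamers (50 with planted effects), 35
genes were significantly positively and 39 negatively associated with
global MWF at p < 0.05 — the planted 25 + 25 plus the expected handful of
false positives at the unadjusted threshold. Fifteen hit genes had
cell-type-specific expression, 2 involving the oligodendrocyte lineage. One
pathway was reported as enriched among the positive hits and two among the
negative hits (the planted `myelination` and `acute_inflammatory_response`
sets rank first on their respective sides). In the spatial stage the
planted stable probe `MBP_p1` was selected by differential stability, and
mean regional MBP-like expression correlated with mean regional MWF at
r = 0.998 across the 12 synthetic white-matter and deep-gray regions —
white-matter regions carry both higher MWF and higher expression, as a
myelin-specific marker should.

All stage outputs land in `demo_run/` as plain TSV/JSON (association table,
volcano table, hit lists, specificity calls, enrichment tables, assignment
table, differential-stability table, region scatter, run summary), with the
generated inputs under `demo_run/inputs/`.

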