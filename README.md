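# ladscape

Quantify remodeling of lamina-associated domains (LADs) between two
conditions, from binned enrichment tracks (e.g. lamin B1 CUT&Tag) to an
enrichment test linking LAD gain to gene downregulation.

LADs are broad heterochromatic regions in contact with the nuclear
lamina; genes inside them are typically repressed. When a structural
regulator is knocked out, the LAD landscape shifts: whole domains appear
or disappear and the edges of persisting domains move. `ladscape` is for
genomicists who have per-replicate domain calls or log-enrichment tracks
for two conditions (plus gene models and a differential-expression table)
and want the remodeling quantified, annotated and statistically tested —
with every step validated against synthetic data with planted ground
truth. The same machinery applies to other broad-domain classes called
from histone marks (e.g. H3K9me2 "KDD" or H3K4me1 "KMD" domains).

## The model

Given a reference domain set *R* and an altered set *A*, every base of
*R ∪ A* gets exactly one of five labels:

| label | definition |
|---|---|
| cLAD | *R ∩ A* (common) |
| Gained LAD | run of *A \ R* whose enclosing domain of *A* does not touch *R* |
| Gained Edge | run of *A \ R* whose enclosing domain does touch *R* |
| Lost LAD / Lost Edge | symmetric, for *R \ A* |

Genome outside *R ∪ A* is inter-LAD. The whole-vs-edge call is
containment-based and parameter-free, and two identities hold exactly:
cLAD + Lost LAD + Lost Edge = |*R*| and
cLAD + Gained LAD + Gained Edge = |*A*|.

Around that core the package provides: a two-state domain caller
(Gaussian-HMM default, classic threshold/gap/min-run variant included),
replicate merging and constitutive intersections, three-set Venn
coverage, scaled-body ±flank signal metaprofiles, midpoint-precedence
gene-feature annotation with signed TSS-distance distributions, the
down-vs-ns × gained-vs-not Fisher's exact test with cross-product odds
ratios (Haldane–Anscombe corrected on zero cells), in-vs-out-of-LAD
expression comparison (Wilcoxon rank-sum), and an SVD ordination of
domain sets by binned genome coverage.

## Worked example

The bundled pipeline simulates a scenario (2 × 10 Mb genome, ~1/3 LAD
coverage, median 0.5 Mb domains; 3 whole gains, 2 whole losses, 6 edge
edits; two replicate tracks per condition at signal-to-noise 2; 200
genes, half of the LAD-gaining genes downregulated), calls domains,
classifies the change and runs the enrichment:

```r
library(ladscape)
rep <- run_pipeline(list(seed = 1, effect = list(p_effect = 0.5)))
print(rep)
#> ladscape pipeline report (v0.1.0, seed 1)
#>   WT 5.85 Mb planted / 5.87 Mb called; KO 5.07 / 5.02 Mb
#>   truth-recovery accuracy 0.9955
#> Category totals (% of union, 6.6 Mb); net change -0.8 Mb
#>    category      bp   mb   percent
#>        cLAD 4270000 4.27 64.501511
#>     LostLAD 1190000 1.19 17.975831
#>    LostEdge  410000 0.41  6.193353
#>   GainedLAD  410000 0.41  6.193353
#>  GainedEdge  340000 0.34  5.135952
#>   enrichment: OR 95, p = 5.876e-09

print(rep$enrichment)
#> LAD-gain enrichment (down vs ns), Fisher's exact test
#>      gained not_gained
#> down     10          1
#> ns       18        171
#> odds ratio 95.000, two-sided p = 5.876e-09  [enriched at 0.05]
```

Reading the output: the caller recovered the planted architecture to
99.6% of genome bases (`truth-recovery accuracy`); the category table
gives each change class in bp/Mb and as a share of the WT∪KO coverage;
the Fisher table shows that 10 of 11 downregulated genes gained lamina
association versus 18 of 189 non-differentially-expressed genes — odds
ratio 95, p ≈ 6·10⁻⁹, i.e. the planted gain→downregulation coupling is
detected.

Real data enter through the same surfaces the pipeline uses internally:
`load_assembly()` (chrom.sizes), `load_domains()` (BED),
`load_track()` (bedGraph), `load_genes()` (GTF or gene TSV),
`load_expression()` (TSV), then `call_domains_hmm()` /
`merge_replicates()` → `classify_changes()` → `category_totals()`,
`build_metaprofile()`, `annotate_intervals()`,
`gain_enrichment_test()`, `domain_overlap_pca()`.

See `vignettes/lad-remodeling-methods.Rmd` for the model, parameter
defaults and their rationale, numerical policies, and what the synthetic
validation does and does not establish.

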