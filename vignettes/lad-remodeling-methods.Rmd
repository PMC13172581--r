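---
title: "Methods: quantifying lamina-associated domain remodeling"
author: "ladscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lamina-associated domain remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladscape)
```

## The problem

Lamina-associated domains (LADs) are broad (typically 0.1–10 Mb)
heterochromatic regions that contact the nuclear lamina; genes inside them
are usually repressed, while inter-LAD (i-LAD) regions are more open and
active. When a structural regulator is perturbed (for example, a knockout
of a LINC-complex or lamin component), the LAD landscape is remodeled:
whole domains appear or disappear, and the boundaries of persisting
domains advance or retreat. `ladscape` quantifies that remodeling from
binned enrichment tracks (lamin B1 CUT&Tag, or H3K9me2/H3K4me1 for the
analogous KDD/KMD domain classes) and links it to gene expression changes.

The same machinery applies to any two-condition comparison of broad
domain calls; nothing in the package is specific to one antibody.

## The five-category change model

Given a reference domain set $R$ and an altered set $A$ on one genome,
every base in $R \cup A$ receives exactly one label:

* **cLAD** — in both ($R \cap A$);
* **Gained LAD** — a maximal run of $A \setminus R$ whose containing
  domain of $A$ has *no* overlap with $R$ (a domain that appeared whole);
* **Gained Edge** — a run of $A \setminus R$ whose containing domain does
  overlap $R$ (boundary extension);
* **Lost LAD / Lost Edge** — symmetrically for $R \setminus A$;
* everything outside $R \cup A$ is i-LAD and left implicit.

The whole-versus-edge decision is *containment-based* and parameter-free:
no adjacency window is involved. Two consequences of this definition are
deliberate interpretations:

* a gained run that bridges two retained domains is edge-type (the
  enclosing altered domain touches the reference);
* an internal hole punched into a persisting domain is edge-type change.
  `classify_changes(..., verbose = TRUE)` additionally labels each edge
  piece `left`, `right` or `internal`, so the two flavours can be
  reported separately.

Two invariants hold *exactly*, not approximately, and are enforced by the
test suite: the five categories are pairwise disjoint, and
$|cLAD| + |Lost\,LAD| + |Lost\,Edge| = |R|$,
$|cLAD| + |Gained\,LAD| + |Gained\,Edge| = |A|$.
An independent brute-force classifier
(`classify_changes_bruteforce`) labels every genome position on its own
and must agree with the interval implementation base-for-base on random
instances.

Coverage percentages are reported against $|R \cup A|$ by default; the
"proportion of change" denominator is genuinely ambiguous in the field,
so it is configurable (`denominator = "genome"`) and always echoed in the
output.

## Domain calling

Domain callers for broad marks are two-state segmenters at heart. The
package ships two:

* `call_domains()` — the classic threshold caller: bins at or above a
  threshold (absolute, or a genome-wide quantile, default $q = 0.75$)
  form runs; runs separated by at most `gap_bins` (default 1) sub-threshold
  bins are joined; runs shorter than `min_bins` (default 3) are dropped.
  Missing bins count as sub-threshold for run-breaking but never enter
  the quantile — absence of evidence splits domains conservatively, and
  uncovered is never treated as depleted.
* `call_domains_hmm()` — the pipeline default: a two-state Gaussian
  hidden Markov model. Emission parameters are estimated by EM on the
  genome-wide value distribution (a two-component mixture, deterministic
  quantile initialization); states are decoded per chromosome by Viterbi.
  The self-transition probability (default 0.98) encodes the expected
  domain scale: at 10 kb bins it corresponds to mean state runs of
  ~0.5 Mb, the typical mammalian LAD size.

The HMM is the default because a fixed genome-wide quantile presumes that
domains cover exactly $1 - q$ of the genome, which is wrong whenever the
true coverage differs — it either truncates domains or floods the
background. The mixture/HMM formulation estimates the two signal levels
from the data and lets run-length evidence place the boundaries. On
synthetic two-level tracks with a signal-to-noise ratio of 2 the HMM
recovers the planted six-way base labelling with ~0.98 accuracy, whereas
the quantile caller at its defaults reaches ~0.89.

Replicates are combined in two places, mirroring common practice:

* **signal level** (pipeline default): `average_tracks()` takes the
  bin-wise mean of the replicate tracks before calling — the analogue of
  merging replicate alignments before running a domain caller;
* **call level**: `merge_replicates()` forms the base-level union of two
  replicate domain sets ("merged domains between replicates");
  `mode = "intersection"` is available for sensitivity analysis.

`consensus_intersection()` computes constitutive domains (base-level
intersection across conditions) and `venn_coverage()` the seven-region
coverage partition of any three sets.

## Signal metaprofiles

`build_metaprofile()` rescales each region body to a fixed number of bins
(default 100) by length-weighted averaging of the overlapping track bins —
unbiased for domains much longer than a track bin, unlike nearest-bin
sampling — and adds fixed-width flanks (default 3,000 bp in 60 bins of
50 bp). For gene sets the profile is oriented 5′→3′. Three numerical
policies matter:

* missing track bins are excluded from the weighted means, never imputed;
* regions shorter than one track bin are skipped and counted
  (`n_skipped`) because body rescaling is undefined for them;
* a profile bin whose value draws on track bins that cross the body/flank
  boundary is *flagged* (`straddle_n`) rather than silently averaged;
  `summarize_profile()` excludes flagged bins by default, so on noiseless
  step tracks the body/flank contrast equals the planted level difference
  to machine precision.

The profile operator is linear (profiling $a x + b$ gives
$a \cdot \text{profile} + b$ exactly) and translation-invariant; both are
property-tested.

## Feature annotation and TSS distances

`annotate_intervals()` assigns each interval by its midpoint
($\lfloor (start + end)/2 \rfloor$) with the precedence
Promoter > 5′UTR > 3′UTR > Exon > Intron > Downstream > Distal intergenic.
The promoter window (default ±3,000 bp around the TSS, in the gene's
5′→3′ frame) and the downstream window (3,000 bp past the 3′ end) are
configurable — the category names are standard but their windows are
conventions, not facts. UTRs require CDS coordinates; genes without a CDS
contribute exons and introns only. Signed TSS distances (negative =
upstream in the gene's frame) use the nearest TSS, with equidistant ties
broken to the lexicographically smaller gene id for determinism, and are
binned 0–1/1–3/3–5/5–10/10–100/>100 kb per side, with distance 0 in the
first downstream bin.

One convention note: with the floor-midpoint rule, mirror symmetry of the
genome is exact for odd-length intervals; for even lengths the midpoint
sits half a base left of centre, so a mirrored even-length interval can
shift its assignment point by 1 bp. The mirror-invariance tests therefore
use odd-length intervals.

For comparisons in the style of "binding sites", broad domain sets can be
cut into fixed windows first (`tile_domains()`), which keeps the
midpoint-based annotation meaningful.

## Expression linkage

`classify_de()` applies the rule FDR < 0.05 and fold change ≥ 1.2,
interpreted as $|\log_2 FC| \ge \log_2 1.2$ on the table's values as
given (no re-shrinkage — the package consumes a DE table, it does not
refit one). `assign_gene_domain_status()` marks a gene *gained* when its
body overlaps Gained LAD ∪ Gained Edge by at least 1 bp (threshold and a
promoter-window mode are configurable, since the gene-to-domain
assignment rule is a modelling choice).

`gain_enrichment_test()` builds the 2×2 table down-regulated vs
non-differentially-expressed × gained vs not (up-regulated genes are
excluded from the contrast by default; `include_up = TRUE` pools them)
and computes the exact two-sided Fisher p-value under the "sum of table
probabilities ≤ the observed table's" convention — conventions differ, so
this one is stated. The reported odds ratio is the cross-product
$ad/bc$; when a cell is zero a Haldane–Anscombe +0.5 correction is
applied to all cells and flagged. Degenerate margins (for example, no
down-regulated genes at all) return $p = 1$ with a warning rather than an
error, so a null pipeline run completes.

`expression_by_lad()` compares expression inside vs outside a domain set
with a two-sided Wilcoxon rank-sum test: exact enumeration of rank
assignments (tie-aware) when the smaller group has ≤ 8 genes *and* the
enumeration stays below 2·10⁵ assignments, otherwise the tie-corrected
normal approximation — an exact test of 8 genes against thousands is not
enumerable, hence the cap.

`domain_overlap_pca()` ordinates domain sets by their binned coverage
profiles: rows are sets, columns are genome bins (default 100 kb),
entries the covered fraction; columns are centred and the matrix
decomposed by SVD. With a handful of sets and many bins this is the
$p \gg n$ regime, so at most $n - 1$ components carry variance;
identical sets land on identical coordinates, and an all-identical input
is returned as a flagged zero-variance result rather than an error.

## The synthetic-data generator

Every downstream stage is validated against scenarios with planted ground
truth (`simulate_scenario`). Defaults emulate a mammalian LAD landscape
at toy scale, chosen once from the field's reported magnitudes:

* genome: 2 chromosomes × 10 Mb;
* WT domains: log-normal, median 0.5 Mb (dispersion 0.45 on the log
  scale), gaps median 1 Mb — about a third of the genome covered, the
  order observed for mammalian LAD coverage;
* KO edits: 3 whole gains, 2 whole losses, 3 extensions, 3 retractions,
  edit sizes log-normal with median 120 kb — remodeled regions are
  smaller than stable domains, as observed for unstable lamina contacts;
  whole losses preferentially hit smaller domains for the same reason;
* all coordinates are quantized to the 10 kb analysis grid (`round_to`),
  because domain callers operate at bin resolution anyway; set
  `round_to = 1` for bp-resolution scenarios;
* edits are kept ≥ 20 kb (two bins) apart from every other interval, so
  each planted edit has an unambiguous category; consequently the truth
  map is *exactly* recoverable from the clean WT/KO sets, and
  `classify_changes` is required to do so on every seed.

Signal tracks (`simulate_signal_tracks`) draw each 10 kb bin from
$N(\mu_{in}, \sigma)$ or $N(\mu_{out}, \sigma)$ by bin-midpoint
membership; defaults $\mu_{in} = 1$, $\mu_{out} = 0$, $\sigma = 0.5$
give a signal-to-noise ratio of 2, the regime the recovery guarantees are
stated for. Replicates use independent streams derived from one root seed
by fixed offsets; all generator functions are deterministic given their
seed.

Gene models (`simulate_genes`) get random strand, 2–8 exons and UTRs
flanking a CDS. Placement is stratified: a requested fraction of genes is
anchored to overlap gained regions (the realized fraction is exact by
construction, which makes enrichment power testable), the rest avoid
gained regions, optionally by a minimum distance — that switch builds the
"gains planted far from any TSS" scenarios used to probe the annotation
comparisons.

Expression tables (`simulate_expression`) give each gained-overlap gene,
with probability `p_effect`, a planted downregulation
($\log_2 FC = -|N(\delta, sd)|$, FDR drawn below 0.05) while all other
genes draw null values. Two FDR-bound regimes matter:

* the default draws unaffected genes' FDR from $[0.05, 1]$ — no false
  DE calls, so saturated cases are clean (with `p_effect = 1`, every
  gained gene and only gained genes are classified down);
* the *null-calibration* configuration (`fdr_null = c(0, 1)`,
  `null_sd = 1`) lets chance DE arise independently of gain status,
  which is the correct null for checking the Fisher test's Type-I rate.
  Under it, rejection at the 0.05 level occurs in 3–7% of 1,000
  simulated tables (Fisher's exact test is conservative at finite
  counts, so the rate sits below the nominal 5%).

Baseline expression (`base_mean`) is log-normal, reduced by 2 log2 units
for genes inside WT domains — the planted form of "genes within LADs are
lowly expressed" — so the in/out-of-LAD comparison has signal to find.

What the generator does *not* emulate: read-level noise, fragment-length
or tagmentation bias, replicate batch effects, copy-number variation, or
any correlation structure between neighbouring bins beyond the domain
step itself. Passing the recovery tests therefore shows the interval
logic and the statistics are correct under the declared noise model, not
that any particular antibody or protocol reaches SNR 2.

## The pipeline and problem sizes

`run_pipeline()` composes simulate → segmentation (replicate-averaged
HMM calls by default) → classification → metaprofiles → tile-based
annotation → enrichment → ordination from one validated configuration
(`validate_config`, YAML/JSON or an R list), with every stage's output
persisted as plain text when `outdir` is set and all randomness derived
from the single config seed. The demo scale (2 × 10 Mb, two replicates,
200 genes) runs in well under a minute on one CPU; the statistical
studies in the test suite use 400 genes × 1,000 simulated tables for
calibration and 100 seeds for power, sizes chosen so the whole validation
suite completes in a few minutes while keeping the binomial uncertainty
on the checked rates small. The command-line surface is the R API itself
plus `scripts/acceptance.R`, which re-runs the full validation from a
seed and writes the headline numbers as JSON.

## Known limitations

* The caller is a declared simplified stand-in for dedicated broad-domain
  callers (EDD-class tools); no attempt is made to reproduce any specific
  tool's boundaries, score model or IgG-control arithmetic — tracks are
  assumed to be pre-normalized log-ratios.
* Annotation is gene-level, not isoform-aware, and has no
  enhancer/CpG-island classes.
* The brute-force classifier and the per-base oracles are quadratic and
  meant for ≤ ~1 Mb validation genomes only.
* Fisher's exact test is conservative for small tables; with very few
  DE or gained genes the enrichment test loses power before it loses
  validity.
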