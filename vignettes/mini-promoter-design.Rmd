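---
title: "Designing tumor-specific mini-promoters: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tumor-specific mini-promoters: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterforge)
```

## The design problem

A tumor-specific synthetic mini-promoter is a short DNA element built by
concatenating binding sites (TFBS) of transcription factors that are
active in tumors but quiet in normal tissue. Driving a therapeutic
transgene from such a promoter confines expression to the tumor. The
design question is therefore: *which* transcription factors, and the
answer comes from expression data — TFs consistently overexpressed in
tumor versus normal samples across many cancer types are good
candidates, because their activity (and hence the promoter's output)
tracks the malignant state.

`promoterforge` implements that workflow end to end at desk scale:

1. **Screen** a TF catalog against multi-cancer tumor/normal expression
   cohorts: quantile normalization, per-dataset log2 fold changes,
   GO-membership filtering (cell growth, GO:0016049; angiogenesis,
   GO:0001525), hypergeometric gene-set enrichment, and ranking by
   literature evidence.
2. **Assemble** a multi-copy TFBS construct for the top-ranked TFs and
   build cloning primers with restriction-site tails, checking the
   construct is free of the cloning enzymes' recognition sites.
3. **Quantify** the construct's behaviour with the standard readout
   formulas: a ratiometric fluorescence expression index,
   intensity-by-area section scores, caliper tumor volumes, and
   two-group comparisons.

Because the original screen rests on ~90 public microarray series that
cannot ship with a package, a seeded synthetic-cohort generator
reproduces the *statistical structure* of such cohorts, so every stage
is exercised by tests without downloads.

## The synthetic cohort model

`generate_cohort()` draws a log2 expression value for gene $g$ in
sample $s$ of dataset $d$ as

$$y_{gs} = \mu_g + \beta_d + \Delta\, Z_{gs}\,
  \mathbf{1}[s \in \text{tumor},\, g \in \text{planted}]
  + \varepsilon_{gs},$$

with per-gene baselines $\mu_g \sim N(\mu_0, \sigma_b^2)$, per-dataset
offsets $\beta_d \sim N(0, \sigma_d^2)$ emulating between-series batch
effects, independent Gaussian noise
$\varepsilon_{gs} \sim N(0, \sigma^2)$, and a Bernoulli carrier
indicator $Z_{gs}$ with success probability equal to the
*penetrance* — the share of tumor samples in which a planted gene
actually carries the shift. Defaults (all log2 units): $\mu_0 = 7$,
$\sigma_b = 1.5$, $\sigma = 0.5$, $\sigma_d = 0.25$, effect
$\Delta = 2$, penetrance $0.8$, with 8 cancer types, 3 datasets per
type and 20 tumor / 20 normal samples per dataset. The effect size
mirrors the 2-fold ($\log_2 \geq 1$) selection scale of the screen;
penetrance below 1 reproduces the partial per-patient overexpression
percentages such screens report.

Modelling choices worth making explicit:

* **Gaussian noise on the log2 scale** matches RMA-style microarray
  output; heavier-tailed noise is deliberately deferred.
* **Penetrance as an independent Bernoulli per tumor sample and
  planted gene** is the simplest mechanism that produces partial
  overexpression fractions; it also makes co-expression fractions of
  planted genes approximately products of the marginal fractions.
  Correlated carrier status (one indicator per patient) would raise
  co-expression; real tumors likely sit between the two.
* **Dataset offsets cancel in fold changes** because both arms of a
  dataset share $\beta_d$; they exist to exercise the multi-dataset
  aggregation logic, not to bias it.
* Gene symbols are synthetic (`G00001`, ...) except the planted TFs,
  which default to `NFKB1`, `CREB1`, `HIF1A` for readability.

What the generator does *not* emulate: probe-level effects,
correlation between genes (beyond shared batch offsets), non-Gaussian
tails, platform differences between series, and tumor purity
gradients. Passing recovery tests on these cohorts therefore shows the
pipeline's logic is correct under its own assumptions, not that the
screen is robust to every pathology of real microarray archives.

## The selection funnel

`select_tfs()` applies three nested filters — TF catalog membership,
GO annotation (growth **or** angiogenesis), and aggregated fold change
at or above the threshold in at least one cancer type — and records
every intermediate flag plus the funnel counts. Two conventions are
configurable because the field uses both:

* **Threshold comparison.** The fold-change filter defaults to
  $\geq$ (2-fold exactly passes); `strict = TRUE` switches to $>$.
* **Multi-dataset aggregation.** Per-cancer-type fold change is the
  median of per-dataset fold changes by default (robust to one
  discordant series); `mean` and `any-dataset` (pass in at least one
  series) are available. How multi-series screens combine their ~90
  datasets is rarely stated, so the rule is explicit configuration,
  not an assumption.

The funnel reports GO associations both ways: counted with
multiplicity (a TF annotated to both sets counts twice — the
convention under which 43 growth + 68 angiogenesis with 8 shared genes
gives 111) and as unique genes (103). Both numbers are exposed because
published funnel counts can follow either convention, and the
reconciliation ($43 + 68 - 8 = 103$) is the inclusion–exclusion
identity.

Per-patient overexpression (the basis of the reported overexpression
and co-expression percentages) is defined relative to the *same
dataset's* normal arm: a tumor sample overexpresses a gene when its
log2 value is at least the dataset's normal mean plus a margin
(default 1, i.e. 2-fold), consistent with the gene-level criterion.
The margin is exposed because the per-patient rule behind such
percentages is typically unstated.

Enrichment is the hypergeometric upper tail
$P(X \geq k)$ with Benjamini–Hochberg adjustment across sets — the
same test DAVID-style tools apply — computed in-repo so no web service
is involved. Literature ranking sums the four evidence-table count
columns (articles mentioning both functions, either, growth alone,
angiogenesis alone) and breaks ties alphabetically; summing makes the
ranking invariant to how the four columns would be weighted, and the
tie rule makes ranks deterministic.

The shipped `inst/extdata/evidence_table1_synthetic.tsv` is a
**synthetic** 19-gene evidence table (the filename says so): its
counts are constructed, not measured, and preserve only the
qualitative structure such a screen produces — nine genes above the
100-article "well-studied" bar and the HIF1A/CREB1/NFKB1 triple
carrying the largest totals.

## Promoter assembly and primer construction

`assemble_promoter()` concatenates, in the given order, the requested
copies of each motif, joining consecutive elements with a spacer
(default empty). The default layout is the D5-style construct: three
copies each of the NF-κB site, the CRE and the HRE, in that order.
Every copy becomes a feature with 0-based half-open coordinates —
chosen because `substr(seq, start + 1, end)` then slices exactly the
motif and the convention matches BED-style tables.

The shipped registry holds canonical consensus motifs (NF-κB
`GGGACTTTCC`, CRE `TGACGTCA`, HRE core `ACGTG`) as documented
stand-ins; real designs should override the registry with their exact
element sequences, and the registry file is the single source of
truth. IUPAC-degenerate consensi are accepted only with a declared
concrete expansion per motif — assembly never makes a silent random
base choice, so constructs are deterministic.

`scan_restriction_sites()` reports exact site occurrences on both
strands at forward coordinates (digestion is strand-agnostic); an
empty scan over the cloning enzymes (MluI, ClaI for the vector; KpnI,
BglII for the insert primers) certifies the construct is clone-safe.
The default 69-bp construct is site-free for all four.

`design_primers()` builds the standard tailed-primer structure
`prefix + site + anneal`, with the reverse primer annealing to the
reverse complement of the target's 3' end. Melting-temperature
optimization is out of scope; the anneal length (default 21 nt) is the
tunable. A warning is attached when an enzyme's site occurs inside the
target, since digestion would then cut the insert.

## Reporter and stain quantification

The ratiometric **expression index** of a construct is

$$\text{Index} =
  \frac{\text{TFI}_{\text{TFBS–GFP}} / \text{TFI}_{\text{AsRed2, test}}}
       {\text{TFI}_{\text{ARE–GFP}} / \text{TFI}_{\text{AsRed2, ctrl}}},$$

where TFI is total fluorescence intensity, AsRed2 normalizes
transfection efficiency within each well, and the ARE construct (the
binding site of the prokaryotic factor ampR, non-responsive in
eukaryotic cells) is the baseline. The printed formula is ambiguous
about whether both ratios share one AsRed2 value; the default uses
each well's matched AsRed2 (the reading under which the index is a
ratio of two self-normalized wells), and
`shared_denominator = TRUE` provides the single-denominator reading.
The index is 1 for a self-control and invariant under common
rescaling of all four intensities — both properties are enforced by
randomized tests.

The synthetic measurement generator places per-well transfection
efficiencies on both channels of a well (they cancel exactly in the
within-well ratios, which is the point of ratiometric normalization)
and a single mean-one Gamma term with the configured CV on the
responsive channel, so the computed index has expectation exactly
equal to the configured truth and is exact at zero noise.

**Section scores** follow the intensity × area convention: intensity
grades 0–3, area levels from the bins [0, 5%), [5, 20%), [20, 40%),
[40, 60%), [60, 80%), [80, 100%]. The printed bin edges overlap
("5–20" then "20–40"); half-open bins with the last bin closed are
adopted so every fraction maps to exactly one level. Scores are
integers in 0–15 (not every integer is attainable — only products of
a 0–3 and a 0–5 grade are). Sections observed over several random
fields are summarized by `mean_field_score()`. Mapping raw pixel
intensity to a 0–3 grade is visual in practice; a three-threshold
quantizer (`intensity_grade()`) is provided for synthetic inputs
only.

Tumor volume is the caliper product length × width × height (mm³),
and `compare_groups()` performs Welch's two-sample t-test by default —
no equal-variance assumption is stated for such comparisons, so the
unequal-variance form is the safer default, with the classical test
selectable.

## Validation experiments and their scale

The test suite validates each operation against hand-computed or
exhaustively enumerated oracles (rank-mean quantile normalization on
2×2 matrices; hypergeometric tails against enumeration of every draw
for all universes up to 12 genes, to 10⁻¹²; primer structure by string
inversion). Two experiments deserve their scale stated:

* **Recovery.** 100 seeded cohorts with 3 planted TFs at effect 2.0,
  penetrance 0.8, 20/20 samples per arm and 3 datasets per type, run
  through the full pipeline (normalize → fold change → select → rank);
  the top-3 must equal the planted triple in at least 95 runs. The
  cohorts use 2000 genes with a 200-TF catalog. The gene count
  matters: quantile normalization pins every column to a common
  distribution, so a gene occupying the extreme top baseline ranks has
  its tumor-vs-normal difference absorbed into the shared reference —
  at a few hundred genes the chance that a planted TF sits there is a
  few percent, an artifact of miniaturization rather than a property
  of the method, while at 2000 genes (and a fortiori at the ~20,000
  genes of real cohorts) it is negligible.
* **Null calibration.** With zero planted effect, the fraction of
  genes passing log2 FC ≥ 1 must match the Gaussian tail
  $P(N(0, \sigma^2(1/n + 1/n)) \geq 1)$ within 3 Monte-Carlo standard
  errors. The calibration runs at higher noise ($\sigma = 2$, 10/10
  samples, one dataset, mean aggregation) so the tail probability
  (~0.13) is measurable; under the recovery-condition noise the tail
  is ~10⁻¹⁰ and the check would be vacuous.

## Known limitations

* The generator's independence assumptions (genes, carriers, noise)
  understate the correlation structure of real cohorts; recovery rates
  here are an upper bound on real-data behaviour.
* GO membership is a flat input set — no ontology traversal or
  evidence-code filtering.
* Evidence counts are an input table; the package does not query
  PubMed, so ranking quality is bounded by the supplied table.
* The shipped motif registry is a consensus stand-in; clone-safety and
  length bookkeeping are guaranteed only for the registry actually
  used.
* Primer design is structural only (no Tm, secondary structure or
  dimer checks).

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  simulation = sim_config(n_genes = 1000, n_tf = 120, seed = 1))
res <- run_pipeline(cfg, "run1")
res$top_tfs        # e.g. "HIF1A" "CREB1" "NFKB1"
res$construct      # 69-bp construct, 9 features
```

The run directory holds every intermediate table (cohort, normalized
matrix, fold changes, candidate funnel, enrichment, ranked
candidates), the construct FASTA with its feature table, and a JSON
manifest (seed, effective configuration, package version, stage
outputs) sufficient to reproduce any artifact byte-identically.
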