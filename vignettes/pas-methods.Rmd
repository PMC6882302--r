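---
title: "Pathway activation strength: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation strength: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasway)
```

## The model

`pasway` quantifies the activity of intracellular signaling pathways (ISPs)
from bulk RNA-seq counts. For a pathway $p$ and a sample $s$, the pathway
activation strength is

$$\mathrm{PAS}_{p,s} \;=\; \sum_{n \in p} \mathrm{ARR}_{n,p} \cdot
\mathrm{BTIF}_{n,s} \cdot \lg(\mathrm{CNR}_{n,s}),$$

with three ingredients:

* **CNR** (case-to-normal ratio): the gene's pseudocounted, normalized
  expression in the sample divided by the mean over the reference (normal)
  group. Reference samples are scored against the whole reference set
  (leave-self-in), so that their PAS values characterize the null spread of
  the statistic.
* **BTIF** (beyond-tolerance-interval flag): a 0/1 gate that admits a gene
  into the sum only when its perturbation is both *large* (CNR outside the
  fold band $[0.66,\,1.5]$, bounds inclusive) and *significant* (its
  $\log_2$ abundance falls outside the reference tolerance interval at
  $\alpha = 0.05$, modelled as a two-sided Gaussian tail test against the
  reference $\log_2$ mean and sd).
* **ARR** (activator/repressor role): a discrete per-gene weight in
  $\{-1, -0.5, 0, +0.5, +1\}$ encoding the gene product's functional role in
  the pathway. Up-regulated activators and down-regulated repressors both
  push PAS positive; the sign of PAS is therefore interpretable as pathway
  activation vs. repression.

$\lg$ is read as the decimal logarithm; any other base would only rescale
every PAS by a constant factor. PAS is *not* divided by pathway size: larger
pathways can accumulate larger sums, matching how the statistic is used to
rank pathway perturbations; a size-normalized variant sits behind
`compute_pas(..., scale_by_size = TRUE)` for users who want comparability
across very differently sized sets.

### The flag polarity

Descriptions of this statistic in the literature are ambiguous about
whether the flag is 1 or 0 for perturbed genes (read literally, one common
phrasing zeroes out exactly the genes that passed both perturbation
criteria, which would make PAS identically zero on any real signal).
`pasway` sets BTIF = 1 for significantly perturbed genes. This is the only
reading under which the statistic measures anything, and it is consistent
with the family's intent: PAS accumulates evidence from genes whose
expression moved materially and reliably.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `normalization` | `cpm` | — | PAS depends only on case/reference ratios, which counts-per-million preserves up to library-size factors; a median-ratio option is provided for robustness studies. |
| `pseudocount` | 1 | normalized counts | guarantees finite, positive CNR for zero counts; applied symmetrically to case and reference, so an all-zero gene gets CNR exactly 1 and contributes nothing. |
| `alpha` | 0.05 | — | tolerance-interval significance level. |
| `fold_low`, `fold_high` | 0.66, 1.5 | fold | the fold band demarking material perturbation; comparisons inclusive. |
| `sd_floor` | 0.1 | log2 units (PAS units for `gaussian_sample_pvalues`) | with 2–5 reference replicates the sample sd collapses for low-variance genes; the floor keeps the tolerance test defined and damps anti-conservative flags. |
| `min_pas` | 0.1 | PAS | the stringency threshold, applied to \|PAS\|, because repressed pathways legitimately carry negative values. |
| `min_reads` | 10 | reads | detection threshold for "expressed" genes and miRNA presence calls. |

Group-level significance uses a two-sided Wilcoxon rank-sum test of case
vs. control per-sample PAS values, computed by exact enumeration of all
rank assignments for combined sizes up to 12 (this handles ties exactly, as
a permutation test) and by the tie-corrected normal approximation with
continuity correction above that. Raw p-values are reported by default — a
deliberate mirror of how such screens are usually presented — with
`p_adjust_method = "BH"` available for honest reuse; across 378 pathways at
$\alpha = 0.05$, roughly 19 null pathways are expected to pass unadjusted.
The per-condition summary (`group_pas`) is the arithmetic mean of the case
samples' PAS, the simplest aggregation consistent with one-number-per-
condition reporting.

## What the simulator emulates

`design_grid()` defaults to the surgical study layout the package was built
around: six procedures (sham, transection, PVL, LLLx, ALPPS, 68%
hepatectomy) crossed with timepoints 0.5, 1, 4, 8, 12 h post surgery, n = 3
replicates, sham as the reference group. `generate_pathway_db()` produces a
knowledge base of 378 pathways of 10–60 genes (about 60% activators), with
a controlled overlap fraction (default 0.2) drawn from a shared gene pool —
pathway overlap is a structural feature of curated knowledge bases and the
reason Jaccard similarity is part of the toolkit.

`simulate_counts()` draws negative-binomial counts (dispersion 0.05, a
tight, pooled-sample-like value) around log-normal baseline means (meanlog
$\log 200$, sdlog 1) with log-normal library-size factors (sdlog 0.2) to
exercise normalization. A planted "activated" pathway multiplies its
activator means by the fold and divides its repressor means by it, so the
planted direction and the sign of true PAS agree by construction — this is
what makes recovery a well-posed target.

What the simulator does **not** emulate: liver-specific expression
distributions, gene–gene correlation beyond shared pathway membership,
batch structure, or read-level artifacts. Passing the recovery and
calibration suites therefore demonstrates that the statistic and its
machinery behave as designed under their own assumptions, not that any
particular biological conclusion from real data is reproduced. The
published per-dataset counts (how many ISPs each surgery affected) depend
on the deposited sequencing data and a proprietary knowledge base and are
out of scope here; their testable counterpart is the null behavior of the
selection (about $\alpha \cdot n_\text{pathways}$ pathways selected on
no-signal data).

## Numerical and design choices

* **Exact Wilcoxon group sizes.** Calibration of the group test is checked
  on 5 vs. 5 contrasts. With n = 3 vs. 3 the exact test's smallest
  achievable two-sided p is 0.1, so no 3v3 contrast can ever be significant
  at 0.05 — a property worth knowing when reading small-n screens. With
  5 vs. 5 the largest achievable p below 0.05 is $12/252 \approx 0.0476$.
  Because many null pathways have several samples with PAS exactly 0 (no
  flagged gene), the permutation p is additionally conservative under these
  ties; observed null rejection rates run around 0.03–0.045 rather than
  exactly 0.05.
* **Validation problem sizes.** The shipped checks use one no-signal
  dataset of 378 pathways (~10,000 genes) with three 5v5 contrasts (1,134
  null tests), and 20 independent recovery simulations (378 pathways, 20
  planted at fold 3, n = 3 per cell). These sizes give stable rates (AUROC
  and rejection-rate estimates move by well under their tolerance across
  seeds) while keeping the whole suite fast.
* **Degenerate inputs.** Constant vectors get maximum Pearson distance (2)
  in clustering and correlation 0 with a warning; all-tied groups return
  Wilcoxon p = 1 with a warning; pathways with no gene present in the
  matrix are *missing* (NA), never 0, so absence of evidence is not scored
  as inactivity; an all-zero expression column is a hard error for CPM.
* **Determinism.** PCA loading vectors are oriented so the
  largest-magnitude element is positive; enrichment ranks break abundance
  ties lexicographically by gene identifier; dendrogram ties resolve by
  original column index; all simulators accept a seed and are byte-stable
  for a fixed seed.
* **"Pearson tau".** Correlation matrices default to the Pearson
  product-moment coefficient; Kendall's tau is exposed as an option since
  the two names are sometimes conflated in methods prose.
* **Single-sample enrichment.** The mitotic cell-cycle signature analysis
  uses a ssGSEA-style running-sum score (step up $1/k$ on the $k$ present
  signature genes, down $1/(N-k)$ otherwise; score = signed maximum
  deviation) rather than a GSVA reimplementation. The scientific claim this
  supports — which sample/timepoint shows the earliest signature shift —
  is a rank-ordering property robust to the choice of single-sample
  scorer; bit-identical GSVA output is a non-goal.
* **ARR domain.** The five-level set $\{-1,-0.5,0,0.5,1\}$ is the minimal
  discrete scheme distinguishing strong/weak activators and repressors plus
  neutral members; a gene duplicated within one pathway is an error (not
  last-wins) so fixture bugs surface instead of silently halving a weight.
* **Pooled vs. replicate designs.** Some study designs pool RNA per
  condition (one column) while reporting biological n; the design table
  supports both layouts, and presence calls use "any replicate over
  threshold" so a pooled single column behaves identically.

## A worked example

```{r example, message = FALSE}
db <- generate_pathway_db(n_pathways = 40, size_range = c(10, 30),
                          overlap_fraction = 0.2, seed = 7)
design <- design_grid(procedures = c("sham", "hx68", "ALPPS"),
                      timepoints = 4, replicates = 5)
truth <- truth_spec("ALPPS", 4, pathway_names(db)[1:3], "activated", 3)
sim <- simulate_counts(db, design, truth, seed = 8)

prof <- pas_profile(sim$counts, sim$design, db)
alpps <- design$sample_id[design$procedure == "ALPPS"]
ref <- design$sample_id[design$is_reference]
sig <- pathway_significance(prof$pas, alpps, ref)
head(sig[order(sig$p_wilcoxon, -abs(sig$group_pas)), ], 5)
select_significant(sig, alpha = 0.05, min_pas = 0.1)
```

The three planted pathways surface with large positive group PAS and small
Wilcoxon p-values; the stringent selection (`min_pas = 0.1`) retains them.
The example uses 5 replicates per cell deliberately: as noted above, with
3 vs. 3 samples the exact rank-sum test bottoms out at p = 0.1 and the
group-level selection is empty however strong the signal (the per-sample
Gaussian p-values, `p_sample_min`, still expose it).

## Known limitations

* The tolerance interval is Gaussian on $\log_2$ abundance; counts from
  very low-expressed genes are noticeably non-Gaussian, and with 2–3
  reference replicates the test leans on the sd floor.
* Raw p-values across hundreds of pathways imply a sizeable expected
  false-positive count; use the BH switch when selection feeds downstream
  claims.
* PAS sums over genes as if independent; co-expression within a pathway
  inflates the variance of PAS relative to the independent-gene intuition,
  which the per-sample Gaussian test absorbs empirically (it fits the
  reference PAS spread) but the gene-level flags do not model.
* The knowledge-base file format carries membership and roles only; no
  topology. Topology-weighted variants are out of scope.
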