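---
title: "Multilayer mutual-information networks across methylation, transcript and miRNA layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer mutual-information networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`mionet` infers co-regulation structure across three omic layers measured
on the same samples: CpG methylation (beta values in [0,1]), transcript
expression and miRNA expression (sequencing counts). Transcripts flagged
as transcription-factor genes (TF-genes) form a fourth, logical layer
inside the transcript omic. The working hypothesis is that a molecule
that regulates a transcript co-varies with it — possibly nonlinearly —
so regulation is detectable as a statistical dependency without assuming
any mechanism, binding motif or chromosomal proximity.

Dependency is measured by mutual information (MI). Each feature's profile
is first copula-transformed, `u = rank/(n+1)` with average ranks for
ties, which makes every marginal near-uniform on (0,1). This is what
lets a *single fixed* kernel bandwidth serve matrices as different as
M-values and log-CPM counts, and it makes the estimate invariant under
any strictly monotone transform of either input. On the transformed
pairs the package uses the plug-in resubstitution estimator

MI = (1/n) Σᵢ log [ f̂₂(uᵢ, vᵢ) / ( f̂₁(uᵢ) f̂₁(vᵢ) ) ]   (nats),

with f̂₁ a 1-D Gaussian kernel density of bandwidth h and f̂₂ the product
kernel with diagonal bandwidth (h, h), each averaged over all n kernels.
The estimator is written so that the kernel normalization cancels and
symmetry in (x, y) is exact at the bit level. Near independence the raw
plug-in value can be slightly negative; it is clamped at 0 and the raw
value kept in an attribute. The all-pairs computation is blocked in
C++ (per-feature kernel matrices are precomputed once per layer), but
its contract is only that it equals the pairwise definition.

### Bandwidth

The bandwidth presets shipped in `mi_config()` are keyed by sample size:
h = 0.211612 (n = 45), 0.18679 (n = 75), 0.165024 (n = 125), 0.16567
(n = 128) and 0.12527 (n = 395) — the five cohort sizes this analysis
was designed around, where bandwidth shrinks as sample size grows. For
any other n, `resolve_bandwidth()` follows the power law h = a·n^b with
(a, b) = (0.5295839, −0.2408892), the least-squares fit of log h on
log n over the presets. This interpolation rule is a design choice of
this package, frozen and pinned by tests; against the analytic value
−½·ln(1−ρ²) for bivariate Gaussians at n = 2000 it yields estimates
about 10% low at ρ = 0.5–0.8 (the resubstitution plug-in is mildly
biased downward at these bandwidths) and within 0.01 nats of zero at
independence. Since downstream selection only uses MI *ranks within a
pair class*, this bias is immaterial to network construction.

### Network construction

Because MI distributions differ systematically between pair classes
(CpG–transcript, CpG–miRNA, transcript–transcript, transcript–miRNA,
miRNA–miRNA), a single MI or p-value threshold would impose different
effective topologies per class. The package therefore keeps, per class
*independently*, the `top_k` (default 10,000) highest-MI pairs, with a
deterministic lexicographic tie-break at the boundary. CpG–CpG pairs are
never scored (their number dwarfs everything else), and no chromosome or
motif restriction is applied. Edge significance is available separately:
a seeded permutation p-value with add-one correction, and a subsampling
z-score — MI recomputed on (by default) 100 subsamples of size 45, the
bandwidth re-resolved at the subsample size so that preset sizes use
their preset bandwidth. ARACNE-style DPI triangle pruning is *not*
applied; the estimator feeds the top-k rule directly.

## Enrichment and pruning

Differential ranking uses a fold-change-threshold moderated statistic:
`sign(logFC)·max(0, |logFC| − log2(T))/SE` with T = 1.5 by default, and
a moderated SE that shrinks each gene's pooled variance toward the
across-gene mean with prior weight d₀ = 4. The established
empirical-Bayes implementation of this idea reports a t-statistic whose
ordering differs *inside* the fold-change band (genes below threshold
get sign-flipped negative values); since the downstream consumer is a
complete signed ranking, this package pins the soft-threshold form
above, which maps the whole null band to exactly 0 and ranks only
beyond-threshold evidence. The full descending ranking (ties broken by
feature id) feeds preranked GSEA — running-sum enrichment scores with
|stat|^weight increments (weight 1 by default), a set-permutation null,
sign-matched NES normalization and BH correction — delegated to the
fgsea implementation and cross-checked in the tests against a
brute-force running-sum oracle.

Sets passing q ≤ 0.01 per subtype are then tested for *network*
over-representation: a one-sided hypergeometric test of the set's
overlap with the network's transcripts, with the universe defined as
all transcripts surviving preprocessing (not all genes in the
collection). Processes at q ≤ 0.05 are "represented"; the boundary is
inclusive because only the "over 0.05" side is excluded by
construction. For the normal-tissue network the candidate list is the
union of processes significant in any subtype. The enriched
(multipartite) network keeps transcripts annotated to a represented
process plus their MI first neighbors; surviving MI edges are
restricted to the CpG–transcript, transcript–miRNA and
transcript–transcript classes, and process nodes join by annotation
edges — a second edge kind, kept separate from MI edges in every
downstream statistic.

## Regulator comparisons

For each process, the potential regulators of type T (CpG, TF-gene,
miRNA) are the nodes of that type MI-adjacent to at least one annotated
transcript. Counts are compared between subtype and normal with
one-tailed Fisher tests on `[[count_T, count_other], [count_T_normal,
count_other_normal]]` — "greater" for CpG, "less" for TF-genes and
miRNAs, the null set opposite to the expected trends — BH-corrected,
and skipped (NA) for processes lacking regulators in either network.
The 2×2 construction (type vs other types × subtype vs normal) is this
package's pinned reading of the per-process comparison; it respects the
stated alternatives and margins. Topology (degree, unweighted shortest
paths, components, per-layer unreachable-target fractions) is computed
on MI edges only, with Wilcoxon rank-sum (normal approximation,
continuity-corrected) comparisons; the unreachable-target fraction
averages per regulator node (the per-node reading of an ambiguous
averaging). Sharing uses the Jaccard index — regulator *node* sets
between processes of one network, regulator-incident *edge* sets
(endpoint pair + class; the MI value is ignored) for the same process
across networks — with exclusivity Fisher tests (same alternatives) and
KS comparisons of the Jaccard distributions. Cross-referencing labels
each regulator-incident edge with exactly one of validated / mapped /
same-chromosome / predicted / unsupported, in that precedence order,
against any local reference table; no external database is queried.

## The synthetic cohort

The generator (`generate_dataset()`) emulates the statistical structure
the analysis assumes, plus the ground truth recovery tests need. Latent
Gaussian signals are drawn per feature and sample; a planted edge makes
the target's latent `s·g(z_reg) + (1−s)·ε` with s the dependence
strength and g a standardized monotone link (identity, signed cube
root, or saturating tanh — nonlinear options are included so MI's
advantage over linear correlation is demonstrable; tails are kept
bounded so exponentiation cannot produce pathological library sizes).
Counts arise by *deterministic* monotone quantization,
`round(2^(μ + σz))` with gene-level μ ~ U(3,9), σ ~ U(0.8,1.5): the
marginals are overdispersed and count-like, while at s = 1 a planted
target remains an exact monotone image of its regulator, which sampled
Poisson/NB noise on top of the latent would destroy — the generator's
determinism contract. Betas are a logistic squashing of the latent,
clipped to [10⁻³, 1−10⁻³] so M-values stay finite, with a configurable
fraction masked missing. Group-level activity shifts add ±`shift_effect`
log2 units to a process's member transcripts in one group only
(relative to the Normal group). Default group sizes are
Basal 125 / Her2+ 45 / LumA 395 / LumB 128 / Normal 75. Planted
transcript targets are drawn preferentially from gene-set members (so
regulatory wiring attaches to annotated processes) and each regulator
gets at most one target while the pool lasts — reusing a regulator
would wire its targets to each other and create high-MI "decoy" pairs
that are dependencies, not noise. All randomness flows from one seed;
identical configurations are byte-identical.

What the generator does *not* emulate: array probe chemistry, batch
structure, copy-number variation, library-composition artifacts beyond
what TMM sees, and the dependence structure of real CpG–miRNA pairs
(no published characterization exists to calibrate against; the
defaults are pragmatic). Passing recovery tests on this cohort shows
the machinery is correct under its assumptions, not that real tissue
satisfies them.

## Preprocessing choices

* Transcript low-count filter: mean CPM across all samples < 10
  (the mean-based reading; a per-sample variant is conceivable but not
  implemented). Exactly 10 is retained ("less than").
* miRNA low-count filter: removed iff in *every* group at least 25% of
  that group's samples have counts < 5 — the all-groups reading of the
  per-subtype rule; the any-group reading would remove anything weak in
  a single subtype, contradicting the rule's per-subtype framing. The
  test suite pins the implemented reading.
* TMM: reference sample by 75th-percentile CPM closest to the mean;
  doubly trimmed (30% on M, 5% on A) precision-weighted mean of log
  ratios; factors rescaled to geometric mean 1. Delegated to edgeR and
  cross-checked against a from-the-description oracle.
* log-CPM: `log2((count + 0.5)/(lib·factor)·10⁶)`.
* CpG sites: optional chrX/chrY removal (on by default), removal at
  missing fraction strictly over 75%, then site-neighbor kNN imputation
  (k = 10): distance is the RMS difference over commonly observed
  samples, neighbors must be observed in the target sample, fewer than
  k candidates fall back to all available with a warning. M-values are
  the standard `log2(β/(1−β))`; the formula is pinned here because
  only the transform's name is conventional.
* Batch correction (ARSyN) and GC/length normalization are deliberately
  not applied; the provenance record marks them "not applied".

## Numerical and degenerate-input policy

Constant profiles copula-map to all 0.5 and are flagged degenerate
(their MI against anything is exactly 0). A zero subsample standard
deviation yields a flagged undefined z-score, not an error. An empty
Jaccard union is flagged undefined. GSEA rejects a set covering the
whole ranking (the down-step is undefined) and drops, with a message,
sets with no ranked member. Ties: copula uses average ranks; top-k
breaks MI ties lexicographically; ranking ties break by feature id —
every tie-break is deterministic so runs are reproducible
checksum-for-checksum.

## Problem sizes in the shipped analyses

The `analysis/` scripts run a 150 CpG × 200 transcript × 40 miRNA
cohort with groups of 45/60/75 — large enough that every pair class has
tens of thousands of candidates while the five scripts finish in
seconds. The GSEA/ORA thresholds there (q ≤ 0.25 and q ≤ 0.6) are
demonstration-scale: eight 12-gene sets against a 200-transcript
universe cannot reach the q-values a genome-wide ontology yields, and
tightening them would simply empty the downstream stages. At this
permissive setting the per-group GSEA occasionally flags a non-shifted
set: planted regulatory wiring makes member genes mutually dependent,
and set-permutation GSEA is anticonservative under inter-gene
correlation — a known property worth remembering with real data too.
The test suite instead checks calibration and power under clean
conditions (200 random sets, binomial bounds at α = 0.05; a 30-gene set
shifted by 1 log2 unit at q < 0.01) and the recovery criteria at the
full study scale (top-10,000 selection over >200,000 scored pairs;
50 planted edges per class against tenfold decoys recovered at ≥90%).
The GSEA calibration check ranks with fold-change threshold 1 rather
than 1.5: on null data the 1.5 threshold maps *every* statistic to
exactly 0, and a ranking of total ties cannot probe calibration.

## Known limitations

MI values are in nats and not converted to bits anywhere. The
permutation p-value floor is 1/(n_perm + 1), so BH-corrected calls near
a threshold need permutation counts sized accordingly. The plug-in
estimator's downward bias means absolute MI values should not be
compared across bandwidths (i.e. across group sizes) — the KS
comparisons of MI distributions between networks deliberately compare
*shapes*, and the subsampling z-scores exist precisely to quantify the
sample-size effect. The kNN imputation is a simple site-neighbor mean;
array-aware methods would do better on real methylation data.
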