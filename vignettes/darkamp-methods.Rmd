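---
title: "Methods: from mixed-target amplicon reads to hierarchical community models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from mixed-target amplicon reads to hierarchical community models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in `darkamp`,
the tunable parameters and their defaults, the numerical choices made where
the design was genuinely open, what the synthetic-data generator does and
does not emulate, and the package's known limitations. All empirical
statements below refer to quantities that the test suite or
`scripts/acceptance.R` compute; nothing is asserted that the shipped code
does not itself measure.

## 1. The measurement model

Each insect library is a mixture of two amplicons — a 418-bp COI fragment
(BF3/BR2) identifying the host, and the 16S rRNA V4 region (515F/806R)
describing its bacteria — plus a synthetic extraction spike-in of known
input copy number. Three consequences drive the design:

* reads must be *assigned to targets* by their primer sequences before any
  denoising;
* host identity (species, genotype) and bacterial community come from the
  *same* library, so host-level QC gates the microbiota analysis;
* the spike-in converts compositional read counts into absolute 16S rRNA
  copy numbers, because the spike's share of reads reflects its share of
  template molecules.

## 2. Read preparation

`split_reads()` assigns a pair to a target when the forward primer matches
the forward read *and* the reverse primer matches the reverse read; a
rescue pass with swapped mate roles is tried before a pair is declared
unassigned. Primer matching (`match_primer()`) is IUPAC-aware and searches
offsets 0–7 (`max_spacer`), accommodating the heterogeneity spacers used in
two-step PCR designs; spacer lengths are unstated in most protocols, so the
window is configurable. One mismatch per primer is tolerated by default —
strict enough to keep the two targets disjoint, loose enough to survive a
sequencing error inside the primer.

`merge_pair()` re-implements overlap merging as the best-scoring ungapped
overlap (score = matches − 2·mismatches, ties to the longer overlap) of the
reverse-complemented mate against the forward read, with at mismatches the
higher-quality base and at matches the larger quality. Defaults:
`min_overlap = 20`, `max_mismatch_frac = 0.25`. An ungapped model is
adequate because substitution errors dominate short-read data and the
amplicons sit in narrow length windows.

`qc_filter()` enforces the expected contig lengths (COI 400–430 nt, 16S-V4
250–260 nt) and rejects contigs containing a *low-quality region*. "Region"
is operationalised — deliberately, since merger wrappers rarely define it —
as **≥ 3 consecutive bases with Phred ≤ 30**; both the run length and the
threshold are arguments.

## 3. Denoising, chimeras, OTUs, taxonomy

Libraries are dereplicated separately and singletons discarded
(`dereplicate()`, `min_count = 2`). `unoise_denoise()` then performs the
UNOISE greedy pass in descending count order: a candidate is absorbed by the
first accepted centroid at edit distance $d \ge 1$ whenever

$$\frac{\mathrm{count}}{\mathrm{count}({\rm centroid})} \le \beta(d) = \frac{1}{2^{\alpha d + 1}}, \qquad \alpha = 2,$$

otherwise it founds a new ZOTU if its count reaches `minsize` (default 2 —
singletons are already gone upstream). Denoising is strictly per library;
ZOTU identity across samples is established afterwards by exact sequence
match (`build_zotu_table()`). The per-candidate search short-circuits when
the count ratio already exceeds $\beta(1)$, since $\beta$ is decreasing
in $d$.

Chimera flagging (`flag_chimeras()`) uses a simplified exact two-parent
test: a ZOTU is chimeric if some breakpoint splits it into a prefix
matching one parent exactly and an end-aligned suffix matching a *different*
parent exactly, with both parents at least twice as abundant and no single
parent matching full length. This is intentionally conservative (exact
segments only); abundance-weighted scoring models are out of scope. The
processing order is dereplicate → denoise → chimera → cluster, a choice the
package fixes explicitly because published pipelines vary.

`cluster_otus()` performs greedy centroid clustering at 97% identity,
visiting ZOTUs by descending total count; identity is matches over
alignment columns of a unit-cost global alignment with penalised end gaps.
With substitutions $S$, insertions $I$, deletions $D$ on the optimal edit
path from a query of length $n$, identity $= (n-S-D)/(n+I)$; this is
computed from `utils::adist()` edit-operation counts, which is exact for
this definition and fast in C.

`classify_taxonomy()` is a SINTAX-style k-mer bootstrap: each of 100
bootstraps draws 32 8-mers with replacement from the query's k-mer set and
votes for the reference sharing most of them (ties broken at random from a
caller-supplied seed); per-rank confidence is the vote fraction for the
winning lineage's label, made monotone non-increasing down the ranks, and
the lineage is truncated at the deepest rank with confidence ≥ 0.80.

## 4. Host barcodes and species proposals

For one sample, after restricting to arthropod-classified, 418-nt,
non-chimeric COI ZOTUs, the dominant OTU must have **≥ 300 reads** and
**≥ 95%** of arthropod reads (both inclusive — the exclusion rules are
"fewer than 300" and "less than 95%"); the barcode is the most abundant
ZOTU within it. Dereplicated barcodes are genotypes.

Species delimitation in dark taxa normally involves expert review of a
dendrogram. The package replaces that judgement with an automated,
flag-don't-decide proposal: average-linkage clustering on pairwise
p-distance (via `ape::dist.dna`, pairwise deletion of sites with N; pairs
overlapping on less than 90% of sites are effectively excluded), cut at 3%,
with any cluster that joins references of more than one named species
flagged `ambiguous` and reported, not resolved. Names are assigned at
**≥ 97%** identity to a named reference, else the classifier's genus- or
family-level label stands in. Species numbers ("sp. 1", "sp. 2", …) follow
descending individual counts, ties by first occurrence.

`sex_ratio_test()` is the 1-df goodness-of-fit statistic
$\sum (O-E)^2/E$, $E = n/2$, with the upper-tail χ² p-value.

## 5. Decontamination and absolute abundance

`quack_filter()` applies the blank-ratio rule on percentages computed from
the *raw* decontamination input table (before any removal): keep a ZOTU iff
its maximum percentage over experimental samples is at least **5×** its
maximum percentage over blanks; ZOTUs absent from every blank are kept
whenever present in an experimental sample. Blanks are the negative
controls only (extraction, first-PCR, indexing); positive controls are
excluded from both sides. Blanks are pooled globally — whether the original
rule compared per batch is unknowable from the outside, and global pooling
is the stricter reading. Decisions are invariant to per-sample depth
rescaling by construction (percentages).

`remove_nontarget()` drops Archaea, Eukaryota, chloroplast, mitochondrial
and chimeric ZOTUs. `split_spikein()` identifies spike-in ZOTUs at ≥ 99%
identity to the reference, tabulates their reads per sample, and removes
them; a PCR spike-in reference, if supplied, is detected and dropped
without further use.

Absolute abundance:
$$\widehat{\mathrm{copies}}_{ij} = \frac{\mathrm{reads}_{ij}}{\mathrm{spike\ reads}_j}\, C_j\, f,$$
with $C_j \in \{10\,000, 20\,000\}$ the batch-dependent spike input (a
sample-sheet column, not a global constant) and $f = 5$ the inverse
proportion of homogenate used (a 40-µl aliquot of ~200 µl). Copies stay
real-valued; samples with zero spike reads are discarded and listed.
Totals are sums over ZOTUs; estimates are linear in reads at fixed spike
depth and invariant to uniform depth rescaling. Richness summaries count
taxa at **≥ 100** estimated copies (inclusive).

The estimator is unbiased under multinomial read sampling; its relative
error scales like $1/\sqrt{\mathrm{spike\ reads}}$, which is why the
calibration checks condition on spike depth ≥ 100 reads.

## 6. Wolbachia COI bycatch

Insect COI primers co-amplify alphaproteobacterial COI. ZOTUs classified to
Rickettsiales are separated; the strain table keeps only *Wolbachia*,
418-nt, non-chimeric sequences. Presence is called at **≥ 2 reads**
(inclusive, monotone in the threshold). Cross-marker concordance against
16S-based detection uses stricter cutoffs — **3** COI reads vs **400** 16S
reads — to exclude cross-contamination; both simple concordance and Cohen's
κ are reported, because "agreement" is ambiguous between the two. The 16S
side aggregates reads of ZOTUs whose OTU is classified *Wolbachia*.

## 7. The hierarchical hurdle model

Zero-inflated abundance tables are analysed as two independent components:

* **presence–absence**: $y_{ij} \in \{0,1\}$ with probit link,
  $P(y_{ij}=1) = \Phi(L_{ij})$;
* **abundance conditional on presence**: natural log of copies, standardised
  per taxon over present cells (mean 0, sd 1; taxa present in < 2 samples
  are excluded, and a taxon constant across its presences is centred to
  zero), Gaussian with residual variance $\sigma_j^2$.

Both share the linear predictor
$$L_{ij} = x_i^\top \beta_j + \sum_{\ell} \eta^{(\ell)}_{g_\ell(i)}{}^\top \lambda^{(\ell)}_j,$$
with $x_i$ = (intercept, season, sex) and latent factors
$\eta^{(\ell)} \in \mathbb{R}^{K_\ell}$ at each random level ℓ (site,
species, genotype, individual). Genotype is treated as crossed with
species (nesting is not enforced) — genotypes are labelled uniquely, so the
crossed coding subsumes the nested one.

**Priors.** $\beta_j \sim N(0, I)$; factors $\eta \sim N(0, I)$; loadings
under the multiplicative-gamma shrinkage prior
($\lambda_{jh} \sim N(0, (\phi_{jh}\tau_h)^{-1})$,
$\phi \sim \mathrm{Ga}(\nu/2,\nu/2)$ with $\nu = 3$,
$\tau_h = \prod_{m\le h}\delta_m$, $\delta_1 \sim \mathrm{Ga}(2,1)$,
$\delta_{h>1} \sim \mathrm{Ga}(3,1)$); $\sigma_j^2 \sim$ inverse-gamma(0.5,
0.5). These are conventional defaults for latent-factor community models;
the upstream package's exact priors are not public in the sources used, so
these are the package's own, stated choices.

**Sampler.** Blocked Gibbs. Presence uses probit data augmentation: latent
$z_{ij}$ are truncated normals, drawn by inverse-CDF in the numerically
safe tail (means clamped at ±37 before `qnorm` on the log-safe side).
Missing abundance cells are imputed each sweep from their conditional —
this keeps every update a balanced matrix operation while leaving the
observed-data posterior untouched. β updates are conjugate normal (one
shared 3×3 solve for presence; per-taxon solves for abundance); η updates
batch groups by size, since all groups of equal size share a posterior
precision; λ updates are K×K solves per taxon per level under the
shrinkage prior; σ² is conjugate inverse-gamma on the completed data.

**Factor counts.** `n_factors` is fixed per level (default 2) rather than
adaptively truncated. At the scales this package targets the identified
quantities (fitted contributions, association matrices) are insensitive to
extra near-zero factors, and a fixed K keeps the per-iteration cost and the
chain diagnostics predictable; the cap is a plain argument where more
factors are wanted.

**Chains and thinning.** Four chains; each runs $375\times$`thin`
iterations, discards the first $125\times$`thin` as burn-in, and retains
every `thin`-th draw — 250 per chain, 1000 total. `psrf_check()` computes
split-chain potential scale reduction factors over the per-taxon season and
sex coefficients and passes when the third quartile is ≤ 1.05;
`fit_community_auto()` escalates thin = 1, 10, … until the check passes.

**Variance partitioning.** Per posterior draw and taxon, each component's
share is the variance over samples of its *fitted contribution*:
$\mathrm{var}_i(x_{ic}\beta_{cj})$ for a covariate,
$\mathrm{var}_i(\eta^{(\ell)}_{g_\ell(i)}{}^\top\lambda^{(\ell)}_j)$ for a
level; shares are normalised per draw and averaged. The realized product
$\eta\lambda$ is used deliberately instead of the loading norm
$\mathrm{diag}(\Lambda^\top\Lambda)$: with few groups (six sites) the split
of scale between factors and loadings is weakly identified, and loading
norms then misattribute variance, which the realized contribution does not.
Shares are non-negative by construction; season and sex are near-orthogonal
in the balanced design, so ignoring their cross-covariance loses nothing.

**Evaluation.** Explanatory metrics use posterior-mean predictions (mean of
$\Phi(L)$ across draws for presence; mean of $L$ for abundance): AUC by the
rank statistic, Tjur $R^2$ = mean($\hat p$ | present) − mean($\hat p$ |
absent), and squared Pearson correlation on observed cells for abundance.
Predictive metrics come from two-fold cross-validation with folds
stratified by species, so each retained species appears in both folds;
held-out samples receive fixed-effect predictions plus contributions of
random-level groups seen in training (unseen groups contribute zero, the
prior mean). Taxa constant within a fold yield missing metrics.

**Support summaries.** A taxon responds positively (negatively) to season
or sex when ≥ 95% of pooled draws of its coefficient are positive
(negative). Residual associations per level use
$\Omega = \Lambda^\top\Lambda$ per draw; a pair is reported when the
fraction of draws agreeing on the sign of $\Omega_{ij}$ reaches 0.90. The
reported mean association matrix is correlation-scaled with unit diagonal.

## 8. The synthetic-data generator

`simulate_truth()` + `simulate_reads()` define the study conditions for all
validation. They emulate: a site × season × sex sampling grid (the
paper-shaped preset uses 6 sites and 88 individuals per cell; the small
preset 2 sites × 3 per cell = 24 flies, 2 blanks, 1 positive control);
log-series host species abundances (a few dominant species, a long rare
tail); 2–3 COI genotypes per species within 1% divergence, species ≥ 5%
apart; endosymbiont strains (*Wolbachia*, *Rickettsia*) tied to specific
species/genotype subsets with female-biased prevalence (0.9 vs 0.5) and
high lognormal loads (median ≈ 8×10⁵ 16S copies, matching the order of
magnitude such infections reach); five generalist genera at 0.6 prevalence
and lower loads; reagent contaminants entering every library — blanks
included — at ~2% relative template abundance, the regime the blank-ratio
rule assumes; spike-ins at 10,000 or 20,000 copies by batch; and *Wolbachia*
COI bycatch at 5% of a host's COI reads.

Sequences are synthetic: genus-level 16S references and a COI ancestor are
random sequences, strains and species radiate from them by seeded
substitutions. Substitution sets are anchored near both sequence ends, so
no pair of planted variants can accidentally satisfy the exact two-parent
chimera bipartition — planted truth stays unambiguous. Reads carry
concretised primers, random heterogeneity spacers (0–3 nt), flat Phred-37
qualities, and optional uniform substitution errors; read allocation is
multinomial over templates weighted by copies/f (bacteria) and C (spike).

Not emulated: realistic Illumina error profiles (quality decay, indels,
flow-cell artefacts), PCR amplification bias and chimera formation during
PCR, variable read-length distributions, index hopping. Passing tests on
these simulations therefore validate the *logic and calibration* of the
pipeline — threshold behaviour, bookkeeping, estimator bias — not its
robustness to instrument-specific noise.

## 9. Problem sizes and numerical choices

The test and acceptance workloads were sized for a single CPU: the
end-to-end cohort uses 24 samples at 600 COI + 2,000 16S reads per library;
quantification calibration uses 200 samples; model recovery uses 500
samples × 30 taxa at the full 4 × 250 chain/retention settings (thinning
escalated only if the PSRF check fails). Tie-breaks are deterministic
throughout: dereplication and ZOTU tables order by count then sequence;
greedy clustering prefers earlier (more abundant) centroids; classifier
tie votes use a caller-supplied seed; chain c of an MCMC run seeds at
`seed + c − 1`. Degenerate inputs are explicit: empty libraries warn and
return empty tables, samples without spike-in reads are discarded and
listed, all-absent or all-present taxa are refused by the presence model,
and rank-deficient fixed designs are an error.

## 10. Known limitations

* 16S copy-number variation per genome is not corrected; "copies" means
  rRNA gene copies, not cells.
* The chimera test requires exact segment matches; real chimeras with
  additional point errors evade it (they are usually removed as singletons
  or low-count uniques instead).
* The reduced-form sampler covers the model structure used here — it is not
  a re-implementation of the full HMSC feature set (no phylogenetic signal,
  traits, or spatial latent factors), and posterior draws are not expected
  to match any other implementation bit for bit.
* Species proposals are flagged, not resolved: ambiguous clusters require
  the expert review they stand in for.
* Cross-validated predictive metrics for abundance are conservative when
  individual-level variance dominates, since held-out individuals have no
  estimated unit factor.
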