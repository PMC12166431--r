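---
title: "Predicting cell-death suppressors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell-death suppressors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deathmark)
```

`deathmark` ranks genes by their potential to be suppressors of a
drug-induced cell-death pathway: genes whose knockdown should both
*sensitize* cells to the drug and *transcriptionally mimic* the drug
response. This vignette describes the statistical machinery, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the places where the design was genuinely open.

## The vulnerability arm

Viability curves are modelled with a four-parameter logistic whose
asymptotes are fixed at 0% and 100% of control:

$$v(x) = \frac{100}{1 + e^{b (x - e)}}, \qquad x = \log_{10}(\text{conc, M}),$$

so $b$ is the (dimensionless) slope and $e$ the log10 EC50; with the fixed
asymptotes the curve crosses 50% exactly at $e$, making $10^{e}$ the IC50.
Fitting is least squares via Levenberg–Marquardt (`minpack.lm::nlsLM`)
started at $b_0 = 1$, $e_0 = \mathrm{median}(x)$ — a neutral initializer
that makes fits deterministic; non-convergence and constant-viability input
are reported as errors rather than guessed around. Each replicate is fit
separately (mirroring a per-curve id), and `fit_logistic4(per = "pooled")`
is available when replicates should share one curve.

The vulnerability summary is deliberately *not* a fitted-curve integral:
`sensitivity_auc()` is 100 minus the range-normalized trapezoid of the
observed points over $x$, which depends only on the log-dose spacing and
the measured viabilities. It is invariant to concentration-unit rescaling,
bounded in [0, 100] (values outside — possible when viability exceeds 100%
of control — are clipped with a warning), and replicate AUCs are averaged
into the cell line × inducer table used downstream, with the per-replicate
values retained.

Per-gene predictors are Pearson correlations between the AUCs and
DepMap-style omics: log-TPM expression and CRISPR gene effect
(≈0 non-essential, ≈−1 essential). Correlations use pairwise-complete
observations per gene with a minimum of 3 complete pairs; genes with zero
variance or fewer pairs are omitted rather than reported as NA, since a
missing predictor and a zero predictor mean different things to the
aggregation. A suppressor is expected to show $r < 0$ in both channels:
abundant in resistant lines, and more essential (more negative gene
effect) in sensitive ones. Expression values are correlated as provided;
no re-log-transformation is applied.

## The similarity arm

Drug-response signatures are per-gene moderated t-statistics from
drug-vs-vehicle RNA-seq. Counts are normalized to offset log2-CPM,
$\log_2\!\big((c + 0.5)/(L + 1) \times 10^6\big)$, filtered at CPM > 1 in at
least `min_group_size` samples (conventional defaults), and fit by ordinary
least squares on a group-means design (one coefficient per cell line ×
condition). Contrasts are always drug − vehicle, a polarity recorded in the
output because every downstream sign convention depends on it. Residual
variances are moderated by inverse-chi-square shrinkage: marginally
$s^2_g \sim s_0^2 F(d, d_0)$, with $(d_0, s_0^2)$ estimated by method of
moments; the moderated t uses $d_0 + d$ degrees of freedom. Precision
weights (voom-style) are intentionally not implemented; the guard for this
simplification is a null-calibration test asserting that the moderated t
rejects at ~5% on null data. $d_0 = 0$ recovers the ordinary t and
$d_0 = \infty$ complete shrinkage, both exposed for testing via
`squeeze_variances()`.

Knockdown signatures live in a `signature_store` (genes × signatures of
moderated z-like scores plus sig-info metadata). Consensus shRNA signatures
are selected by `pert_type == "trt_sh.cgs"` and a time label (default
`"96H"`, applied at extraction time). From each signature the top and
bottom `k = 20` genes form the up and down sets; ties at the k-th score are
broken by ascending gene id so extraction is deterministic and invariant to
row order. Sets round-trip through standard GMT.

Each set is scored in each drug signature by a camera-style competitive
test: with $m$ set genes among $n$, mean difference
$\delta = \bar{t}_{in} - \bar{t}_{out}$, pooled variance, and the set term
inflated by $\mathrm{VIF} = 1 + (m - 1)\rho$ to acknowledge inter-gene
correlation; $\rho$ defaults to 0.01, the conventional value for this test,
and $\rho = 0$ reduces exactly to the textbook pooled two-sample t-test
(asserted against that oracle in the tests). Scores are reported as signed
$-\log_{10} p$: positive when the set is up in the signature.

Aggregation to one number per knockdown gene per drug signature proceeds
in three steps: maximum over the 4–9 knockdown cell lines (taken over
whatever cell lines are present; no imputation), competition ranks within
each drug signature (ties share the smallest rank of the block), and
`total = rank(up) − rank(down)`, an integer in $[-(N-1), N-1]$ for $N$
knockdown genes.

### Score polarity

The rank-difference formula admits two readings — either end of the
$[-(N-1), +(N-1)]$ scale can be labelled "best" depending on how the ranks
are oriented. `deathmark` exposes
`similarity_best` and defaults to `"positive"`: a knockdown that mimics
the drug has its up-set enriched *Up* (large positive signed score, hence
a high up-rank) and its down-set enriched *Down* (low down-rank), so the
mimic lands near $+(N-1)$. Two observations support the default: a known
drug target's knockdown should score *high*, and on synthetic data with
planted mimics only the positive reading recovers them. Every downstream
rank direction keys off this one flag, and outputs are always sorted
strongest-candidate-first so no user-facing surface depends on raw rank
direction.

### Consensus filter

Drug signatures vary across cell lines; an outlier signature injects noise
into the maxima. `consensus_weights()` computes pairwise Pearson
correlations among the log-FC vectors, zeroes the diagonal and all negative
entries, and assigns each signature its percentage of the remaining
correlation mass. Signatures below the threshold (default 9%) are flagged
and removed *before* the max-over-cells aggregation — removing them after
would let an outlier already have won some maxima, defeating the filter's
purpose. For $k$ concordant signatures each weight is $100/k$, so the
default threshold only starts flagging when a signature carries clearly
less than its equal share.

## Aggregation into candidate lists

**Best predictors.** Family means per gene (expression correlations,
essentiality correlations, similarity totals; genes lacking any family are
dropped), competition-ranked with rank 1 = strongest candidate under the
polarity: most negative mean correlation, most positive mean similarity.
`rank_corr` is the element-wise *maximum* (worse) of the two correlation
ranks — a gene must look good in both omics channels. The final
`rank_total` is the competition rank of
`(rank_corr + rank_similarity) / 2`. The larger of the two correlation
means (`biggest_r`) is reported for inspection but never ranked on, as it
feeds no downstream step. Orienting all family ranks the same way is the
only reading under which averaging ranks selects genes strong in *both*
arms; with both families ranked ascending on raw values the two ends would
cancel.

**Nearest neighbours.** Complete predictor rows are standardized to zero
mean and unit variance and embedded in 2D with UMAP
(`min_dist = 0.05`, seed 5023 as configuration defaults; `n_neighbors`
is unstated upstream and defaults to 15, recorded in provenance). The
embedding is deterministic at a fixed seed and input order
(single-threaded layout). Candidates are the `top_n = 75` genes nearest
(Euclidean) to a key pathway gene, boundary ties included. A neighbourhood
*radius* is deliberately not used — only top-n selection — and
`pca_kmeans_fallback()` (first two PCs + k-means) covers data where UMAP
is unstable or rows are too few.

**Novelty filtering.** Citation counts for `"GENE AND term"` queries come
from a pluggable client: an offline JSON fixture (the tested path) or a
live NCBI eutils client with rate limiting and backoff that never
fabricates counts on failure. By default the top 75 are truncated first
and then genes with any pathway-term citation are dropped
(`max_citations = 0`, novelty-first); `filter_first = TRUE` inverts the
order for users who want a full-length list of novel genes. For text-mining
triage of the similarity arm alone, `top_similarity_genes()` forwards the
100 genes with the best mean similarity.

**Validation.** `validate_pancancer()` correlates every gene's expression
with the drug AUCs on a (preferably independent) panel, and tests the
candidate set against that ranking with a preranked GSEA: weighted
Kolmogorov–Smirnov walk with weight exponent 1, ES the signed maximum
deviation, p by gene-label permutation with the $(b+1)/(n_{perm}+1)$
estimator, one-tailed in the direction of the observed ES, seed mandatory.
Suppressor candidates should enrich the negative-correlation tail.

## What the synthetic generator emulates — and what it does not

`scenario_manifest()` fixes a scenario: by default 2000 genes, 20 cell
lines, 500 knockdowns, 2 inducers, 10 planted suppressors, and 10 + 10
partial-evidence decoys. Every generated table is a deterministic function
of the manifest seed.

* **Dose-response:** each cell line carries a latent vulnerability that
  drives its EC50 for every inducer of the pathway (inducer-specific
  jitter on top), so AUCs correlate across inducers as they do for drugs
  hitting one pathway; viability noise is Gaussian (σ = 3 percentage
  points, a typical MTT replicate spread), clipped at 0.
* **Omics:** planted suppressors get expression
  $a - b\,z(\mathrm{AUC}) + \varepsilon$ (slope 1 per SD of AUC, noise SD
  0.35 log-TPM — population $r \approx -0.94$) and gene effect
  $-0.4 - 0.3\,z + \varepsilon$ bounded in $[-1.5, 0.5]$; background genes
  are independent noise.
* **Signatures:** a latent death-program direction $D_0$ over genes;
  each inducer's direction is $\sqrt{0.75}\,D_0$ plus inducer-specific
  variation; counts are negative-binomial (dispersion 0.1) around log2
  means shifted by the inducer direction; planted knockdown signatures are
  $\rho_{sig} D_0 + \sqrt{1-\rho_{sig}^2}\,\text{noise}$ ($\rho_{sig} =
  0.8$) across 4–6 pseudo cell lines, others pure noise. Metadata uses the
  consensus-shRNA conventions, with over-expression and late-time
  distractors included to exercise the filters.

Planting couples all three evidence channels for true positives — the
pipeline's premise is that real suppressors score in both arms — while the
decoys carry correlation-only or signature-only evidence to verify the
aggregation does not reward single-arm genes. The generator does **not**
emulate pan-cancer covariance structure, lineage confounding, batch
effects, or the heavy-tailed noise of real L1000 data; passing the planted
recovery tests therefore demonstrates that the machinery is wired
correctly and has the stated operating characteristics, not that real-data
signal of a given strength will be recovered.

## Numerical choices and problem sizes

Tie-breaks are deterministic everywhere (gene id in set extraction, gene
symbol at selection boundaries). Degenerate inputs error early with the
offending names (constant viability, constant fold-change vectors,
rank-deficient designs, empty cell-line intersections, unknown key genes
with near-miss suggestions). The test suite exercises parameter recovery
to 1e-6 on noise-free curves, equivalence to independent oracles
(pooled t-test, brute-force GSEA walk, counting ranks, grid-search
minimizer) over hundreds of seeded instances, and end-to-end planted
recovery on the default 2000-gene scenario, with a 300-gene scenario used
for the faster integration checks. Validation panels in tests are
regenerated with fresh noise (same planted biology) so that
selection-on-training-noise cannot masquerade as replication.

## Limitations

Both arms are correlational; aggregation reduces but does not eliminate
false positives, and the nearest-neighbours method additionally requires a
trusted key gene. The camera variance-inflation factor treats inter-gene
correlation as a single constant ρ; the rank-based camera variant and
multiple-testing correction across sets are out of scope (the pipeline
consumes raw signed scores). GCTX-backed stores are not supported in this
build — the store contract is implemented over in-memory matrices and
long-format TSV. Live PubMed queries depend on NCBI availability and are
not exercised by the offline test suite.
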