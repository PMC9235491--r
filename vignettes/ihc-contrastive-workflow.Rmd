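---
title: "Donor-masked contrastive learning for IHC cell-type specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor-masked contrastive learning for IHC cell-type specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ihcontrast)
```

## The problem

Single-antibody immunohistochemistry (IHC) screens image one antibody per
tissue section: the stain (brown, against a blue hematoxylin counterstain)
shows where the antibody binds, but nothing in the image says *which cell
type* is stained. Selecting antibody panels for multiplexed tissue imaging
requires exactly that knowledge. `ihcontrast` implements a two-stage answer:

1. learn an embedding of IHC images with a self-supervised contrastive
   objective whose positive and negative sampling is built around the
   structure of such screens, and
2. transfer cell-type labels onto the embedding from an independent
   single-cell expression matrix, via a deliberately low-capacity linear
   classifier, with no human labelling of images anywhere.

## The contrastive objective

Images are grouped by the gene their antibody nominally targets; the gene is
the observational unit. A *positive pair* for gene $g$ is two images drawn
uniformly without replacement from $g$'s equivalence class (pooled across
antibodies and tissue donors; a singleton class degenerates gracefully to
two augmentations of the same image). Each member is independently
augmented: random crop, HSV jitter, scale, rotation (in that fixed order;
rotation fills by reflection so the network cannot latch onto corner
artefacts).

Both views are embedded ($h = f(\tilde x)$) and projected onto the unit
sphere ($z = \phi(h)$, ReLU → linear → $L_2$ normalization; the projection
head exists only inside the loss). With pairwise cosine similarities
$s_{ij} = z_i^\top z'_j$ and temperature $\tau$, the per-anchor loss is

$$
l_i \;=\; -\log
\frac{e^{s_{ii}/\tau}}
     {e^{s_{ii}/\tau} + (B/B_i)\sum_{k \neq i}
       \mathbf{1}[d_i = d_k]\, e^{s_{ik}/\tau}},
\qquad
B_i = \sum_{k=1}^{B} \mathbf{1}[d_i = d_k],
$$

averaged over the batch. The indicator is the *donor mask*: negatives are
restricted to batch members whose donor matches the anchor's, and the
surviving terms are re-weighted by $B/B_i$ ($B_i$ counts the anchor itself,
so it is never zero and a donor-unique anchor contributes exactly zero
loss). Dropping the indicator and the $B/B_i$ factor recovers the standard
NT-Xent denominator (`negative_mode = "uniform"`).

Why mask by donor? Donors do not co-occur uniformly across genes in real
screens (each antibody is typically imaged in a small subset of donors), so
cross-gene positive pairs are donor-imbalanced and the encoder is rewarded
for pushing frequently co-occurring donors together — embeddings cluster by
donor, a nuisance. Restricting negatives to the anchor's donor removes any
discriminative value of donor-specific colour and texture, steering the
representation toward stain morphology.

Three places where the printed operational description and its surrounding
prose could be read differently are resolved by following the operational
form, with the alternatives behind flags:

* the temperature is applied everywhere (`temperature`, default 1.0, at
  which the two readings coincide);
* $B_i$ counts the self term (`count_self = FALSE` switches to the
  "number of negatives" reading);
* the mask compares the anchor's donor against the *first-view* donors
  $d_k$, even though the negative is the second view $z'_k$
  (`donor_mask_source = "negative_view"` uses $d'_k$ instead);
* the loss is one-directional as printed; `symmetrize = TRUE` averages both
  view directions.

## Encoder contract

The encoder is a contract, not a fixed network: any map
*backbone feature grid → spatial average pool → linear map to
$D$ dimensions* fits. The package ships a desk-scale default — four blocks
of 3×3 stride-2 convolution, batch normalization, and ReLU — trained
entirely on CPU. Batch normalization is load-bearing: a normalization-free
stack of positive (ReLU) feature maps produces pooled vectors that share one
dominant direction, the projected vectors start at cosine similarity ≈ 1,
and the contrastive loss sits at its collapsed saddle $\log B$ with
vanishing gradients. Running BN statistics are frozen for inference, so
embeddings are deterministic; inference uses a centre crop and no stochastic
augmentation, and downstream consumers always receive $h$, never $z$.
The loss itself is evaluated via log-sum-exp with the row maximum
subtracted, in double precision.

The reference-scale settings remain the configuration defaults
(`contrastive_config()`: $D = 128$, batch 150, $\tau = 1$, Adam at
$5\times10^{-4}$ for 1000 epochs, 256×256 crops). When the corpus holds
fewer genes than the batch size the sampler falls back to drawing genes with
replacement, with a warning.

## Cross-modal specificity transfer

From a labeled cells × genes expression matrix, the specificity vector of
gene $g$ is its mean expression per cell type, normalized onto the
$K$-simplex ($y_g \in \Delta^K$). Genes with all-zero expression are dropped
(they carry no label signal; mapping them to a uniform target would only
dilute the fit). Expression values are used exactly as provided — any
normalization or log transform is an upstream choice, deliberately outside
this tool.

The classifier minimizes the soft-label cross-entropy
$-\sum_i y_{g(i)}^\top \log\mathrm{softmax}(h_i^\top A)$ over
$A \in \mathbb{R}^{D\times K}$, full-batch Adam (learning rate 0.01, 1000
epochs) on the analytic gradient $H^\top(\mathrm{softmax}(HA) - Y)$. There
is no intercept (none appears in the objective, and embeddings are
unconstrained, so one would be absorbable). The restriction to a *linear*
map is the point: the transcriptomic targets are a noisy proxy for
proteomic specificity, and capacity control is what stops the classifier
from memorizing target noise — which only works while the number of
training images comfortably exceeds $D$. The desk-scale protocol therefore
uses $D = 32$ against 144 images, mirroring the reference regime where
thousands of images stand against $D = 128$. Gene-name matching between
corpus and expression data is exact and case-sensitive; unmatched genes are
dropped with a count, and a holdout gene list can be excluded from training.

## Region-level evaluation

Cell-type probabilities are mapped onto coarser anatomical regions
(many-to-one; cell types that span regions stay unmapped and their mass is
renormalized away), per-image region vectors are averaged into per-gene
predictions, and each region is scored by a one-versus-rest ROC over genes.
Thresholds sit at distinct score values, so the AUC is exactly the
Mann–Whitney pair-counting value (ties count one half) — this is what makes
the brute-force oracle in the test suite exact. Transcriptomic baselines
score each gene × cell type with a one-versus-rest Welch $t$ statistic (the
unequal-variance form is robust to the very unbalanced one-vs-rest split)
or a rank-sum statistic standardized to a $z$ score with tie correction
(comparable across genes, which matters for the max step); a region's score
is the maximum over its mapped types. Constant genes score 0 — "no evidence
of specificity" — rather than NaN or ±∞.

Donor invariance is quantified by a stratified five-fold CV multinomial
logistic regression predicting donor from embeddings (weak $L_2$ decay as a
numerical stabilizer only, no class weighting); the same probe with planted
cell-type labels measures representation quality. Cluster enrichment uses
the hypergeometric upper tail $P(X \ge k)$, reported raw with optional
Benjamini–Hochberg adjustment.

## The synthetic testbed

`synth_config()` defines the desk-scale study conditions: 24 genes × 6
kidney-like cell types mapped onto 4 regions (glomerulus, proximal tubule,
distal tubule, collecting duct), 4 donors, 2 antibodies per gene × 3
replicate images, 64×64 pixels. Each gene's planted cell type controls the
stain morphology (blob radius / density / ring-vs-disc), composited brown
over a blue counterstain. Donor identity contributes a global colour shift
and a low-frequency background texture drawn once per donor — nuisance of
exactly the kind the donor mask is designed to cancel, and deliberately
*global* rather than morphological so the ablation stays interpretable.
Crucially, each gene's replicates are drawn from a per-gene pool of 2 of the
4 donors: this reproduces the donor/gene co-occurrence imbalance that makes
uniform negative sampling drift toward donor-clustered embeddings in real
screens; with donors crossed uniformly the drift mechanism disappears and
the ablation has nothing to remove.

The matching expression matrix plants the same type structure (mean
$1 + \text{marker\_strength}$ in marker-type cells, 1 elsewhere,
multiplicative log-normal noise, 40 cells per type). Setting
`n_decoupled_genes > 0` re-plants the *expression* marker type of a random
subset of genes away from their staining type — emulating markers whose
transcript abundance misrepresents protein staining, the failure mode that
motivates imaging-based specificity in the first place.

What the generator does *not* emulate: nucleus-level morphology, optical
density (Beer–Lambert) stain mixing, tissue tearing/folding artefacts,
antibody cross-reactivity, and donor-specific *morphological* variation.
Passing tests therefore demonstrate that the algorithms behave as specified
under controlled planted structure — not that the method succeeds on any
particular real corpus.

## Desk-scale protocol and problem sizes

The evaluation studies in the test suite and `scripts/acceptance.R` use:
crop 32 of the 64-pixel images (the same half-side ratio as the reference
protocol), mild jitter (hue ±0.02, saturation/value ±0.1, scale 0.9–1.1,
rotation ±45°), $D = 32$, Adam at $10^{-3}$; 300 epochs per run for the
three-replicate sampling-scheme ablation and 800 epochs for the end-to-end
recovery run; classifier at the reference 1000 epochs. One epoch visits
`floor(n_genes / B)` batches (at least one), so with 24 genes a run is a few
hundred gradient steps. These sizes were chosen once as a realistic
desk-scale miniature of the reference protocol.

At full scale one would hold annotated evaluation genes out of classifier
training; with 24 synthetic genes a full holdout would leave nothing to
train on, so the end-to-end study fits on all genes and leans on the
capacity argument above ($N \gg D$) to keep the classifier from memorizing
the decoupled genes' wrong targets. `match_specificity_targets()` exposes
`holdout_genes` for corpora large enough to afford a genuine split.

## Numerical choices

* Contrastive and classifier losses via max-subtracted log-sum-exp.
* Projection normalization epsilon-guarded (`1e-12`) against all-zero rows.
* Cosine similarity errors on exactly zero-norm rows rather than returning
  NaN.
* Augmentation draws a fixed number of variates in a fixed order, so one
  seed determines the batch bit-exactly; the master seed fans out to named
  substreams (initialization / training / each generator stage) via a
  polynomial hash kept below $2^{31}$.
* ROC ties are grouped at distinct thresholds (Mann–Whitney-exact);
  zero-variance groups score 0 in both DE statistics.
* The identity augmentation (all ranges zero) short-circuits resampling and
  returns the crop bit-exactly.

## Known limitations

* The desk-scale CNN is far smaller than the reference backbone; absolute
  probe accuracies and AUCs on the synthetic profile are not comparable to
  full-scale results, only directions and orderings are meaningful.
* Donor-probe accuracy on ~150 images has visible replicate-to-replicate
  variance; the ablation is therefore assessed on replicate means over
  three seeded corpora.
* One-directional loss (as printed) discards half of the available
  gradient signal per batch; `symmetrize = TRUE` is available but is not
  the default, for fidelity.
* The expression matrix is consumed as-is; whether specificity vectors
  should be built from raw counts, normalized, or log-normalized expression
  is delegated upstream and simply documented here.
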