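---
title: "Methods: the peptide-pair intensity ratio, its prediction, and CSM rescoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the peptide-pair intensity ratio, its prediction, and CSM rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

A cross-linked spectrum match (CSM) assigns one MS/MS spectrum to a pair of
peptides (labelled alpha and beta by search-engine convention) joined by a
chemical cross-linker. Because the two peptides of a cross-link are present
in an exact 1:1 stoichiometry, the ratio of their summed fragment ion
intensities is a property of the pair, not of the injection amount or the
spectrum quality. In log2 form,

    I_ab = log2( sum of matched alpha fragment intensities /
                 sum of matched beta fragment intensities ),

the statistic is antisymmetric under exchanging the two peptides and
invariant under uniform intensity scaling of the spectrum. `intensity_ratio()`
implements it; `extract_ratio()` produces it from a spectrum by matching
theoretical b/y ions within a ppm tolerance.

Operational choices:

* **"All fragments" means all matched fragments.** Unmatched theoretical
  fragments contribute zero intensity, which makes the matched-only and
  zero-filled formulations identical.
* **Shared peaks are split.** A peak claimed by fragments of both peptides
  is credited half to each side. This avoids double counting without
  discarding the peak; within one side a peak is counted once regardless of
  how many fragments (e.g. charge states) hit it.
* **Matching tolerance** defaults to 20 ppm (Orbitrap-class MS2);
  enlarging the tolerance can only grow the matched set (a tested
  invariant).
* **Aggregation.** Replicate CSMs of the same pair (same sequences and
  modifications) are averaged after dropping pairs with fewer than four
  CSMs and trimming the `floor(0.05 n)` ratios most deviant from the group
  median. Trimming by absolute deviation from the median was chosen because
  the outlier rule had to be made concrete; the median is robust and the
  rule is symmetric. The trimmed mean is the training label; the trimmed
  standard deviation quantifies replicate stability
  (`aggregate_pair_ratios()`, `variance_decomposition()`).

## The synthetic benchmark

Real ground-truth data require a search engine and public raw data; the
package instead ships a generator (`generative_config()`, `make_dataset()`)
whose structure mirrors what makes the ratio learnable:

* each peptide pair has a latent **additive** true ratio,
  `sum(w[residues of alpha]) - sum(w[residues of beta])`, with per-residue
  weights drawn once from Normal(0, 0.15). With peptide lengths 7–15 this
  spreads true ratios with a standard deviation near 0.7, matching the
  between-pair spread observed on real data;
* replicate CSMs scatter around the true ratio with standard deviation
  0.1 log2 units — the within-pair replicate stability level seen in
  repeated measurements;
* fragment intensities realize the replicate ratio exactly, then receive
  per-fragment log-normal noise (sdlog 0.2) and a few uniform background
  peaks; peaks sit at exact theoretical m/z;
* every peptide carries one lysine as the cross-link site (the linker
  chemistry is lysine-reactive) and a tryptic-like C-terminal K/R;
* pairs whose alpha and beta theoretical fragments come within 0.1 Th are
  resampled, so matching on generated spectra is unambiguous and the
  noise-free round trip through extraction is exact to machine precision
  (a tested invariant);
* decoys reverse one peptide's sequence holding the cross-linked residue
  in place, and are assigned to the spectra of their source pair — the
  "right spectrum, wrong peptide" competition that target–decoy FDR
  estimation needs.

Defaults are 2,000 pairs with 8 CSMs each. The generator is deliberately
*compositional*: the additive rule gives the predictor a provably learnable
target and gives the attribution module an exact Shapley ground truth. The
cost of that choice is that generated data contain **no local sequence
context** — no neighbour effects on fragmentation, no charge-state
dependence, no chimeric spectra — which matters for interpreting the
ablation results below. Passing tests on this benchmark demonstrate
correctness of the machinery, not performance on real spectra.

## The regressor

`ratio_model()` fits a neural network that maps the two token-encoded
peptide sequences to the predicted log2 ratio:

1. **Token embedding** (dimension 16) over a vocabulary of residue ×
   modification-class combinations, plus a binary channel flagging the
   cross-link site. Modification classes come from a small registry
   (oxidation, carbamidomethyl, linker remnants, a catch-all) so that
   unusual deltas still encode.
2. **Two CNN blocks** (32 filters, kernels 3 and 5; conv → layer norm →
   ReLU, padding masked) capture local sequence context.
3. **Local max pooling** (window 2, stride 2) over positions.
4. **Cross-attention** (single head, dimension 32): each peptide's pooled
   positions attend to the other peptide's, modelling the interaction of
   the pair. The projection matrices are shared between the two directions.
5. **Global pooling** over positions, concatenation of the two sides plus
   explicit length features (both lengths and their log2 ratio — global
   pooling discards length, which is itself predictive of the ratio), and
   a dense head (64 hidden units, dropout 0.1).

The encoder (steps 1–3 and the attention projections) is one parameter
set applied to both peptides: the alpha/beta labels are an engine
convention, so the two sides must be treated by the same function.
**Swap augmentation** presents every training pair also with the sides
exchanged and the label negated, teaching the head the antisymmetry of the
log ratio; a well-fitted model predicts near-zero for a pair with
identical peptides and near-opposite values for swapped pairs.

Training minimizes squared error with Adam (learning rate 1e-3, batch 64,
30 epochs by default). Squared error was chosen because the evaluation
metrics are RMSE/MAE. All randomness (initialization, shuffling, dropout)
derives from the config seed; with single-threaded BLAS, runs are
bit-reproducible. The forward and backward passes are written as batched
base-R matrix operations and are verified against finite differences in
the test suite.

On the default benchmark (1,600 training pairs, 400 held out, labels from
full spectrum extraction and aggregation) the fitted model reaches
held-out Pearson ≈ 0.98 and MAE ≈ 0.09 in about two minutes on one CPU
core, far ahead of the length-ratio linear baseline
(`baseline_length_ratio()`) and of random draws from the label
distribution (`random_mismatch()`).

`crossvalidate()` performs 5-fold CV with folds split at the pair level;
`finetune()` adapts a fitted model to a new condition using a
unique-pair-level subset (default 30%) so the held-out remainder shares no
pair with the fine-tuning data.

## What the ablation does and does not show

The package exposes the three ablation axes as config switches:
`attention = FALSE`, `pooling = "average"`, `use_cnn = FALSE`. On real
cross-linking data the expected quality ordering is full model best, then
without attention, then average pooling, with the CNN-less variant worst —
local fragmentation context is the signal the CNN exists to capture.

On the package's own benchmark this ordering does **not** reproduce, and
the acceptance test that asserts it fails by design rather than having
been weakened: the generator's label is exactly additive in residue
composition, so architectures whose inductive bias is composition counting
(global averaging; a pooled embedding model without convolutions) match
the target family exactly and removing CNN capacity *helps*. Measured at
convergence over multiple seeds, the CNN-less variant is the strongest and
average pooling beats max pooling; only "attention helps" transfers to the
synthetic setting. This is an informative negative result: it delineates
precisely which architectural conclusions depend on real fragmentation
context that the additive generator cannot supply, and it is documented
here rather than hidden by tuning the generator away from its stated
design.

## Rescoring

Three scores per CSM (`rescore_csms()`):

* **DiffIRScore** `= 1 / (|measured - predicted| + 0.5)` — reciprocal
  prediction error of the ratio, capped at 2 by the damping constant 0.5.
  CSMs without a finite measured ratio (one side unmatched) score 0.
* **DDPScore** — decoupled dot product: theoretical alpha and beta
  fragments and the experimental spectrum are binned at 0.02 Th; bins
  containing fragments of both peptides are removed everywhere (shared
  fragments carry no side information); each side contributes the dot
  product of its L2-normalized theoretical vector with the L2-normalized
  experimental intensities over that side's bins; range [0, 2]. The bin
  width is configurable, and correctness is asserted against a brute-force
  oracle at several widths. Normalization happens after shared-bin
  removal.
* **Mixed score** `= DDPScore + 0.02 * DiffIRScore`.

`tda_fdr()` estimates FDR as #decoys/#targets above each score cutoff
(the simplest standard target–decoy estimator, no +1 correction) and
monotonizes it into q-values. Reports count accepted target CSMs and
unique peptide pairs per FDR level.

## Attribution

`attribute()` explains one prediction by per-residue Shapley values on the
alpha peptide, holding beta fixed. The reference set
(`make_references()`, default 100) mutates one third of the alpha
positions to random different residues, which controls for peptide length
while randomizing composition. The estimator is model-agnostic
permutation sampling with antithetic permutation pairs: positions are
revealed from reference to original in random order and the output change
at each reveal is credited to that position, averaged over permutations
and references. Because marginals telescope, base value + attributions =
prediction holds *exactly* (up to float error) for any number of
permutations, and for a linear model the estimate equals the closed form
`w(x_i) - mean_ref w(r_i)` — both are tested. A network-internals
propagation method would be faster but architecture-bound; the sampling
estimator satisfies the same axioms and is testable against closed forms.

Beta-side attributions follow by attributing the swapped pair and negating.
`aggregate_by_residue()` pools attributions by residue type over many
pairs; on the benchmark the residue-type means rank-recover the
generator's weights (Spearman > 0.9 with 150 pairs, 25 references, 4
permutations each). `scale_correlation()` correlates the means with
residue mass or Zimmerman bulkiness; on synthetic data this correlation
reflects only the randomly drawn weights and is not expected to reproduce
correlations observed on real fragmentation data.

## Problem sizes and numerical choices

* Benchmark: 2,000 pairs × 8 CSMs; training 30 epochs; ablation at 800
  training pairs, 15 epochs, 3 seeds; attribution over 150 held-out pairs.
  These sizes keep a full from-scratch run (generation → extraction →
  training → rescoring → attribution) within minutes on a single core
  while leaving wide margins on every threshold the tests assert.
* Layer norm epsilon 1e-5; Adam (0.9, 0.999, 1e-8); Glorot-uniform
  weight init; embedding init Normal(0, 0.1).
* Ties in peak matching (two peaks at exactly equal distance) resolve to
  the more intense peak; ties in the better-than-random comparison count
  against the model (conservative).
* Degenerate cases: the length-ratio baseline on equal-length pairs
  degenerates to the mean predictor and is flagged; correlation metrics on
  constant predictions return NA with a warning; an all-zero side in the
  DDP score contributes 0.

## Limitations

* The generator writes charge-1 b/y peaks at exact theoretical m/z; no
  isotope envelopes, neutral losses, deisotoping or peak picking.
  Cleavable-linker stub doublets are not modelled; the intact linker mass
  rides on site-containing fragments.
* The regressor's determinism contract assumes single-threaded BLAS;
  across different BLAS builds results may differ in the last bits.
* Real-data conclusions (absolute error levels, ablation ordering,
  attribution–property correlations) require real spectra and are out of
  scope for the synthetic benchmark.
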