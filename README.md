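# xlratio

Fragment intensity ratios for cross-linking mass spectrometry: measure
them, predict them from sequence, and use them to rescore cross-linked
spectrum matches (CSMs).

## The problem

Cross-linking MS identifies pairs of peptides (alpha/beta) covalently
joined by a chemical linker. Search engines score CSMs almost entirely on
m/z agreement and largely ignore fragment intensities, which limits their
power to separate true matches from plausible false ones. But the two
peptides of a cross-link are present in exactly 1:1 stoichiometry, so the
log2 ratio of their summed fragment ion intensities,

```
I_ab = log2( sum I(alpha fragments) / sum I(beta fragments) )
```

is a stable, pair-intrinsic quantity: invariant to injection amount, and
far less variable across replicate spectra of the same pair than across
different pairs. If that ratio can be predicted from the peptide sequences
alone, the agreement between measured and predicted ratio becomes an
orthogonal score for CSM identification.

`xlratio` provides the full chain for R users:

* **Measurement** — theoretical b/y fragment generation, ppm-tolerance
  peak matching against MGF spectra, the ratio statistic, and per-pair
  aggregation into training labels (`extract_ratio()`,
  `aggregate_pair_ratios()`).
* **Prediction** — `ratio_model()`, a shared-encoder neural network
  (token embedding → CNN blocks → max pooling → cross-attention between
  the two peptides → regression head) fitted by Adam on squared error,
  with swap augmentation encoding the ratio's antisymmetry. Implemented
  in base R with finite-difference-verified gradients; includes 5-fold
  pair-level cross-validation, fine-tuning to new conditions, a
  length-ratio linear baseline and a random-mismatch reference.
* **Rescoring** — DiffIRScore `1/(|measured - predicted| + 0.5)`, the
  decoupled dot product spectral score (DDPScore), their weighted sum
  (mixed score, weight 0.02), and target–decoy FDR with q-values
  (`rescore_csms()`, `tda_fdr()`).
* **Interpretation** — per-residue Shapley attribution with mutated
  reference sets, aggregation by residue type, and correlation against
  residue mass/bulkiness scales (`attribute()`).
* **Synthetic benchmark** — a generator with an additive per-residue
  ground truth, replicate noise and reversed-sequence decoys, so the whole
  pipeline is trainable and testable without any downloads
  (`make_dataset()`).

## Worked example

```r
library(xlratio)

# a synthetic benchmark: 600 pairs x 8 replicate CSMs, decoys included
cfg <- generative_config(seed = 7, n_pairs = 600)
ds  <- make_dataset(cfg, "bench", decoy_fraction = 0.6)
tab     <- read_csm_table(ds$csm)
spectra <- ds$spectra
names(spectra) <- vapply(spectra, function(s) s$scan_id, "")

# measure the ratio of one CSM (replicates scatter around the true value)
pair <- with(tab[1, ], cross_link_pair(
  peptide(alpha_seq, xl_site = alpha_site),
  peptide(beta_seq,  xl_site = beta_site)))
extract_ratio(spectra[[1]], pair, max_frag_charge = 1)$measured_ratio
#> [1] 0.3011272
true_ratio(pair, cfg)
#> [1] 0.5044737

# extract all CSMs, aggregate replicates into labels, fit the regressor
for (i in seq_len(nrow(tab)))
  tab$measured_ratio[i] <- extract_ratio(
    spectra[[tab$scan_id[i]]],
    xlratio:::pair_from_row(tab[i, ]), max_frag_charge = 1)$measured_ratio
tab$pair_id <- xlratio:::pair_id_from_table(tab)
agg   <- aggregate_pair_ratios(tab[!tab$is_decoy, ])
pairs <- lapply(match(agg$pair_id, tab$pair_id),
                function(i) xlratio:::pair_from_row(tab[i, ]))
fit <- ratio_model(pairs[1:480], agg$mean_ratio[1:480],
                   model_config(seed = 1, epochs = 25))
regression_metrics(agg$mean_ratio[481:600], predict(fit, pairs[481:600]))
#>        rmse       mae   pearson  spearman
#> 1 0.3237889 0.2652064 0.9134747 0.8833113
```

The single-CSM extraction (0.30) differs from the pair's true ratio
(0.50) by replicate noise; averaging the pair's eight replicates is what
produces a stable label. Held-out Pearson 0.91 at this reduced size
(480 training pairs, 25 epochs, ~1 min) rises to about 0.98 with MAE
near 0.09 at the full default benchmark (2,000 pairs, 30 epochs). The
printed numbers come from this exact code under seed 7/seed 1; a
different BLAS build may alter the last digits.

A shell front end wrapping the same functions ships in
`inst/scripts/xlratio`:

```sh
Rscript inst/scripts/xlratio simulate --out bench --seed 7 --decoy-fraction 0.6
Rscript inst/scripts/xlratio extract  --csm bench/csms.tsv --mgf bench/spectra.mgf --out extracted
```

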