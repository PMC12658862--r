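# CSM rescoring: DiffIRScore (prediction accuracy of the intensity ratio),
# DDPScore (decoupled dot product spectral similarity), their weighted
# combination, and target-decoy FDR with q-values.

#' DiffIRScore: reciprocal prediction error of the intensity ratio
#'
#' 1 / (|measured - predicted| + epsilon). Strictly decreasing in the
#' absolute prediction error, maximal (1/epsilon) at equality; epsilon
#' prevents division by zero and caps the score.
#'
#' @param measured,predicted log2 intensity ratios (finite; vectorized).
#' @param epsilon Damping constant (default 0.5, giving scores in (0, 2]).
#' @return Numeric score(s).
#' @export
#' @examples
#' diff_ir_score(1.2, 1.2)   # 2: perfect prediction
#' diff_ir_score(1.0, 2.5)   # 0.5
diff_ir_score <- function(measured, predicted, epsilon = 0.5) {
  if (any(!is.finite(measured)) || any(!is.finite(predicted)))
    stop("non-finite intensity ratio passed to diff_ir_score")
  stopifnot(epsilon > 0)
  1 / (abs(measured - predicted) + epsilon)
}

# Bin index on a fixed m/z grid.
mz_bin <- function(mz, bin_width) as.integer(floor(mz / bin_width))

#' DDPScore: decoupled dot product spectral similarity
#'
#' Theoretical alpha and beta fragment m/z values and the experimental
#' spectrum are binned onto a common grid; bins occupied by fragments of
#' both peptides (shared fragments) are removed from all vectors before
#' normalization. Each peptide contributes the dot product of its
#' L2-normalized theoretical vector with the L2-normalized experimental
#' intensity vector over that peptide's bins; the score is the sum of the
#' two dot products, in [0, 2]. A side with no experimental intensity in
#' its bins contributes 0.
#'
#' @param theo_alpha_mz,theo_beta_mz Theoretical fragment m/z vectors.
#' @param spec \code{xl_spectrum}.
#' @param bin_width Grid width in Th (default 0.02, high-resolution MS2).
#' @return Score in [0, 2].
#' @export
ddp_score <- function(theo_alpha_mz, theo_beta_mz, spec, bin_width = 0.02) {
  stopifnot(bin_width > 0, inherits(spec, "xl_spectrum"))
  ba <- unique(mz_bin(theo_alpha_mz, bin_width))
  bb <- unique(mz_bin(theo_beta_mz, bin_width))
  shared <- intersect(ba, bb)
  ba <- setdiff(ba, shared)
  bb <- setdiff(bb, shared)
  if (length(spec$mz) == 0L) return(0)
  eb <- mz_bin(spec$mz, bin_width)
  eint <- rowsum(spec$intensity, group = eb)
  ebin <- as.integer(rownames(eint))
  side <- function(bins) {
    if (length(bins) == 0L) return(0)
    tvec <- rep(1, length(bins))                  # unit theoretical intensity
    evec <- eint[match(bins, ebin), 1L]
    evec[is.na(evec)] <- 0
    en <- sqrt(sum(evec^2))
    if (en == 0) return(0)
    sum((tvec / sqrt(sum(tvec^2))) * (evec / en))
  }
  side(ba) + side(bb)
}

#' Mixed score: spectral similarity plus weighted ratio accuracy
#'
#' DDPScore + gamma * DiffIRScore; linear in both components, monotone
#' increasing in each.
#'
#' @param ddp DDPScore value(s).
#' @param diff_ir DiffIRScore value(s).
#' @param gamma Weight of the intensity-ratio term (default 0.02).
#' @return Numeric score(s).
#' @export
#' @examples
#' mixed_score(1.0, 2.0)  # 1.04
mixed_score <- function(ddp, diff_ir, gamma = 0.02) {
  ddp + gamma * diff_ir
}

#' Fraction of CSMs where the model beats the random-mismatch reference
#'
#' Per CSM the absolute ratio-prediction error (Diff.IR) of the model is
#' compared against that of a random-mismatch draw; strictly smaller
#' counts as better (ties count against the model).
#'
#' @param measured Measured log2 ratios.
#' @param model_preds Model predictions.
#' @param random_preds Random-mismatch predictions
#'   (\code{\link{random_mismatch}}).
#' @return Fraction in [0, 1].
#' @export
fraction_better_than_random <- function(measured, model_preds, random_preds) {
  stopifnot(length(measured) == length(model_preds),
            length(measured) == length(random_preds))
  mean(abs(measured - model_preds) < abs(measured - random_preds))
}

#' Target-decoy FDR estimation with q-values
#'
#' Records are ranked by score (descending). At each cutoff
#' FDR = #decoys >= cutoff / #targets >= cutoff; the q-value is the
#' running minimum of FDR from the lowest score upward (monotone
#' non-increasing with score). Also reports, per requested FDR level, the
#' number of accepted target CSMs and of unique target peptide pairs.
#'
#' @param scores Numeric scores (higher is better).
#' @param is_decoy Logical decoy flags (both classes must be present).
#' @param pair_ids Pair identity keys (for the nonredundant count).
#' @param fdr_levels FDR thresholds to report.
#' @return List: \code{q_values} (aligned with input order),
#'   \code{summary} data.frame (fdr_level, n_target_csms, n_unique_pairs).
#' @export
tda_fdr <- function(scores, is_decoy, pair_ids = NULL,
                    fdr_levels = c(0.01, 0.05)) {
  stopifnot(length(scores) == length(is_decoy))
  if (!any(is_decoy)) stop("FDR undefined: no decoy records")
  if (!any(!is_decoy)) stop("FDR undefined: no target records")
  if (is.null(pair_ids)) pair_ids <- as.character(seq_along(scores))
  o <- order(scores, decreasing = TRUE)
  dec <- is_decoy[o]
  fdr <- cumsum(dec) / pmax(cumsum(!dec), 1L)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  q_values <- numeric(length(scores))
  q_values[o] <- q
  summary <- do.call(rbind, lapply(fdr_levels, function(lv) {
    acc <- !is_decoy & q_values <= lv
    data.frame(fdr_level = lv, n_target_csms = sum(acc),
               n_unique_pairs = length(unique(pair_ids[acc])))
  }))
  list(q_values = q_values, summary = summary)
}

#' Rescore a CSM table
#'
#' Computes DiffIRScore from measured and predicted ratios, DDPScore from
#' the spectra, the mixed score, and target-decoy q-values for both the
#' DDP and mixed rankings. Rows without a finite measured ratio receive
#' the minimum DiffIRScore of 0 (no ratio evidence).
#'
#' @param csms CSM table (data.frame) with the standard columns plus
#'   \code{measured_ratio}.
#' @param predicted Predicted log2 ratio per row.
#' @param spectra Named list of \code{xl_spectrum} (names = scan_id).
#' @param epsilon,gamma,bin_width Score parameters.
#' @param fdr_levels FDR thresholds for the report.
#' @return List: \code{table} (input plus diff_ir_score, ddp_score,
#'   mixed_score, q_value_ddp, q_value_mixed), \code{report} (FDR summary
#'   per scorer and level).
#' @export
rescore_csms <- function(csms, predicted, spectra, epsilon = 0.5,
                         gamma = 0.02, bin_width = 0.02,
                         fdr_levels = c(0.01, 0.05)) {
  stopifnot(nrow(csms) == length(predicted))
  n <- nrow(csms)
  diff_ir <- numeric(n)
  ok <- is.finite(csms$measured_ratio) & is.finite(predicted)
  diff_ir[ok] <- diff_ir_score(csms$measured_ratio[ok], predicted[ok],
                               epsilon)
  ddp <- numeric(n)
  for (i in seq_len(n)) {
    sp <- spectra[[csms$scan_id[i]]]
    if (is.null(sp))
      stop("spectrum not found for scan_id '", csms$scan_id[i], "'")
    pr <- pair_from_row(csms[i, ])
    fa <- theoretical_fragments(pr$alpha, pr$linker_mass, 2L)
    fb <- theoretical_fragments(pr$beta, pr$linker_mass, 2L)
    ddp[i] <- ddp_score(fa$mz, fb$mz, sp, bin_width)
  }
  mixed <- mixed_score(ddp, diff_ir, gamma)
  ids <- pair_id_from_table(csms)
  fd <- tda_fdr(ddp, csms$is_decoy, ids, fdr_levels)
  fm <- tda_fdr(mixed, csms$is_decoy, ids, fdr_levels)
  out <- csms
  out$diff_ir_score <- diff_ir
  out$ddp_score <- ddp
  out$mixed_score <- mixed
  out$q_value_ddp <- fd$q_values
  out$q_value_mixed <- fm$q_values
  report <- rbind(cbind(scorer = "ddp", fd$summary),
                  cbind(scorer = "mixed", fm$summary))
  list(table = out, report = report)
}
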