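# Shapley-style per-residue attribution of the alpha peptide's contribution
# to the predicted intensity ratio.
#
# The estimator is model-agnostic permutation sampling with a mutated
# reference set: for each sampled permutation of the alpha positions and
# each reference, positions are revealed (switched from the reference
# residue back to the true residue) in permutation order, and the change in
# model output at each reveal is credited to that position. Marginals
# telescope, so base value + sum of attributions equals the model
# prediction exactly (up to float error) — the completeness axiom holds by
# construction, and for an additive model the estimate is exact for any
# number of permutations.

#' Mutated reference pairs for attribution
#'
#' The beta peptide is held fixed; each reference replaces a fixed fraction
#' (round(L * mut_fraction), at least 1) of distinct alpha positions with
#' uniformly random different residues, preserving length. Modifications at
#' mutated positions are dropped; the cross-link site index is unchanged.
#'
#' @param pair \code{xl_pair} (alpha length >= 3).
#' @param n_refs Number of references (default 100).
#' @param mut_fraction Fraction of alpha positions replaced (default 1/3).
#' @param seed RNG seed.
#' @return List of \code{xl_pair} references.
#' @export
make_references <- function(pair, n_refs = 100L, mut_fraction = 1 / 3,
                            seed = 1L) {
  L <- peptide_length(pair$alpha)
  if (L < 3L) stop("alpha peptide must have length >= 3")
  n_mut <- max(1L, round(L * mut_fraction))
  set.seed(seed)
  chars <- strsplit(pair$alpha$sequence, "", fixed = TRUE)[[1L]]
  lapply(seq_len(n_refs), function(r) {
    pos <- sample.int(L, n_mut)
    new_chars <- chars
    for (p in pos)
      new_chars[p] <- sample(setdiff(RESIDUES, chars[p]), 1L)
    mods <- pair$alpha$mods
    mods <- mods[!(mods$position %in% pos), , drop = FALSE]
    out <- pair
    out$alpha <- peptide(paste(new_chars, collapse = ""),
                         mods = if (nrow(mods)) mods else NULL,
                         xl_site = pair$alpha$xl_site)
    out
  })
}

# Encode alpha-token rows for a set of alpha residue-composites against a
# fixed beta, producing the encoded-batch form that predict() accepts.
composite_batch <- function(tok_rows, base_enc) {
  n <- nrow(tok_rows)
  rep_mat <- function(v) matrix(v, n, length(v), byrow = TRUE)
  list(tok_a = tok_rows,
       tok_b = rep_mat(base_enc$beta_tokens),
       mask_a = rep_mat(base_enc$alpha_mask),
       mask_b = rep_mat(base_enc$beta_mask),
       xl_a = rep_mat(base_enc$alpha_xl),
       xl_b = rep_mat(base_enc$beta_xl),
       charge = rep(ifelse(is.na(base_enc$charge_feature), 0,
                           base_enc$charge_feature), n),
       L = length(base_enc$alpha_tokens), n = n)
}

#' Per-residue Shapley attribution of the predicted ratio
#'
#' Attributes the model's predicted log2 ratio for a pair to the individual
#' alpha-peptide residues, relative to a reference set of mutated alpha
#' sequences (\code{\link{make_references}}). The base value is the mean
#' prediction over the references; base value plus the attributions equals
#' the prediction of the original pair (completeness), within
#' \code{tolerance}.
#'
#' Attributions for the beta side are obtained by attributing the swapped
#' pair: the ratio statistic is antisymmetric, so beta contributions are
#' the negated alpha contributions of \code{\link{swap_pair}}.
#'
#' @param model Fitted model; \code{predict(model, batch)} must accept the
#'   encoded-batch form produced by \code{encode_pairs_matrix}.
#' @param pair \code{xl_pair}.
#' @param references References from \code{\link{make_references}}.
#' @param n_perms Sampled permutations (antithetic: each draw also
#'   contributes its reverse).
#' @param seed Seed for the permutation draws.
#' @param tolerance Maximum allowed completeness gap.
#' @return Object of class \code{xl_attribution}: \code{per_residue}
#'   data.frame (position, residue, attribution), \code{base_value},
#'   \code{prediction}, \code{completeness_gap}.
#' @export
attribute <- function(model, pair, references, n_perms = 32L, seed = 1L,
                      tolerance = 1e-2) {
  L <- peptide_length(pair$alpha)
  max_len <- if (!is.null(model$config)) model$config$max_len else 50L
  base_enc <- encode_pair(pair, max_len = max(L, peptide_length(pair$beta)))
  orig_tok <- base_enc$alpha_tokens
  Lpad <- length(orig_tok)          # padded row width (>= alpha length L)
  ref_tok <- do.call(rbind, lapply(references, function(rp)
    encode_pair(rp, max_len = Lpad)$alpha_tokens))
  R <- nrow(ref_tok)
  set.seed(seed)
  half <- max(1L, n_perms %/% 2L)
  perms <- vector("list", 2L * half)
  for (i in seq_len(half)) {
    p <- sample.int(L)
    perms[[2L * i - 1L]] <- p
    perms[[2L * i]] <- rev(p)
  }
  P <- length(perms)
  # rows: per (perm, ref) the composites after revealing 1..L-1 positions;
  # the 0-reveal (pure reference) and L-reveal (original) endpoints are
  # computed once.
  n_mid <- if (L > 1L) P * R * (L - 1L) else 0L
  tok_all <- matrix(0L, n_mid + R + 1L, Lpad)
  row <- 0L
  for (p in seq_len(P)) {
    ord <- perms[[p]]
    for (r in seq_len(R)) {
      comp <- ref_tok[r, ]
      for (step in seq_len(L - 1L)) {
        comp[ord[step]] <- orig_tok[ord[step]]
        row <- row + 1L
        tok_all[row, ] <- comp
      }
    }
  }
  tok_all[n_mid + seq_len(R), ] <- ref_tok
  tok_all[n_mid + R + 1L, ] <- orig_tok
  preds <- predict(model, composite_batch(tok_all, base_enc))
  f_ref <- preds[n_mid + seq_len(R)]
  f_orig <- preds[n_mid + R + 1L]
  phi <- numeric(L)
  row <- 0L
  for (p in seq_len(P)) {
    ord <- perms[[p]]
    for (r in seq_len(R)) {
      prev <- f_ref[r]
      for (step in seq_len(L)) {
        cur <- if (step < L) preds[row + step] else f_orig
        phi[ord[step]] <- phi[ord[step]] + (cur - prev)
        prev <- cur
      }
      row <- row + (L - 1L)
    }
  }
  phi <- phi / (P * R)
  base <- mean(f_ref)
  gap <- abs(base + sum(phi) - f_orig)
  if (gap > tolerance)
    stop("completeness violated: |base + sum(phi) - prediction| = ",
         signif(gap, 4), " > ", tolerance)
  chars <- strsplit(pair$alpha$sequence, "", fixed = TRUE)[[1L]]
  structure(list(per_residue = data.frame(position = seq_len(L),
                                          residue = chars,
                                          attribution = phi,
                                          stringsAsFactors = FALSE),
                 base_value = base, prediction = f_orig,
                 completeness_gap = gap, pair_id = pair_key(pair)),
            class = "xl_attribution")
}

#' @export
print.xl_attribution <- function(x, ...) {
  cat("<xl_attribution> base ", signif(x$base_value, 4), ", prediction ",
      signif(x$prediction, 4), " (gap ", signif(x$completeness_gap, 2),
      ")\n", sep = "")
  print(x$per_residue)
  invisible(x)
}

#' Pool attributions by residue type
#'
#' @param results List of \code{xl_attribution}.
#' @return data.frame (residue, n, mean, sd) for residue types present;
#'   absent types are simply absent (not zero rows).
#' @export
aggregate_by_residue <- function(results) {
  per <- do.call(rbind, lapply(results, `[[`, "per_residue"))
  groups <- split(per$attribution, per$residue)
  out <- data.frame(residue = names(groups),
                    n = lengths(groups),
                    mean = vapply(groups, mean, 0),
                    sd = vapply(groups, function(x)
                      if (length(x) > 1L) stats::sd(x) else NA_real_, 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Correlate residue-type mean attributions with a physical scale
#'
#' @param agg Output of \code{\link{aggregate_by_residue}}.
#' @param table Scale table (\code{\link{residue_scales}} by default).
#' @param scale "mass" or "bulkiness".
#' @return Pearson correlation coefficient.
#' @export
scale_correlation <- function(agg, table = residue_scales(),
                              scale = c("mass", "bulkiness")) {
  scale <- match.arg(scale)
  m <- merge(agg, table, by = "residue")
  if (nrow(m) < 3L)
    stop("need at least 3 residue types for a correlation")
  stats::cor(m$mean, m[[scale]])
}
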