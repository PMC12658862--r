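# Integer encoding of peptide pairs for the regressor.
#
# Token vocabulary: 20 residues x modification classes (unmodified, each
# registered class, catch-all "other"), plus 0 for padding. The cross-link
# site is carried as a separate binary channel rather than a token, so the
# vocabulary stays small and the site position stays explicit.

MOD_CLASSES <- c("unmod", names(MOD_REGISTRY), "other")

vocab_size <- function() length(RESIDUES) * length(MOD_CLASSES)

# token id in 1..vocab_size for (residue, mod class); 0 reserved for PAD
token_id <- function(residue, mod_class) {
  r <- match(residue, RESIDUES)
  m <- match(mod_class, MOD_CLASSES)
  (r - 1L) * length(MOD_CLASSES) + m
}

encode_peptide_tokens <- function(p, max_len) {
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L > max_len) stop("peptide length ", L, " exceeds max_len ", max_len)
  cls <- rep("unmod", L)
  if (nrow(p$mods) > 0L)
    cls[p$mods$position] <- vapply(p$mods$delta_mass, mod_class_of, "")
  tok <- integer(max_len)
  tok[seq_len(L)] <- token_id(chars, cls)
  mask <- integer(max_len)
  mask[seq_len(L)] <- 1L
  xl <- integer(max_len)
  xl[p$xl_site] <- 1L
  list(tokens = tok, mask = mask, xl = xl, length = L)
}

#' Encode a cross-linked peptide pair for the model
#'
#' Deterministic integer tokenization: each residue maps to a token indexing
#' its (residue, modification class) combination; positions past the peptide
#' end are padding (token 0, mask 0). The cross-link site is a separate
#' binary indicator channel.
#'
#' @param pair \code{xl_pair}.
#' @param max_len Padded length (both peptides must fit).
#' @return List with alpha_tokens, beta_tokens, alpha_mask, beta_mask,
#'   alpha_xl, beta_xl (each length \code{max_len}) and charge_feature
#'   (precursor charge, NA if absent).
#' @export
encode_pair <- function(pair, max_len = 50L) {
  stopifnot(inherits(pair, "xl_pair"))
  a <- encode_peptide_tokens(pair$alpha, max_len)
  b <- encode_peptide_tokens(pair$beta, max_len)
  list(alpha_tokens = a$tokens, beta_tokens = b$tokens,
       alpha_mask = a$mask, beta_mask = b$mask,
       alpha_xl = a$xl, beta_xl = b$xl,
       charge_feature = pair$precursor_charge)
}

# Encode a list of pairs into batch matrices (n x L). L is the smallest
# padded length that fits every peptide, capped at max_len.
encode_pairs_matrix <- function(pairs, max_len = 50L) {
  lens <- vapply(pairs, function(p)
    max(peptide_length(p$alpha), peptide_length(p$beta)), 0L)
  L <- min(max_len, max(lens))
  if (any(lens > max_len))
    stop("peptide longer than max_len ", max_len)
  n <- length(pairs)
  tok_a <- matrix(0L, n, L); tok_b <- matrix(0L, n, L)
  mask_a <- matrix(0L, n, L); mask_b <- matrix(0L, n, L)
  xl_a <- matrix(0L, n, L); xl_b <- matrix(0L, n, L)
  charge <- numeric(n)
  for (i in seq_len(n)) {
    e <- encode_pair(pairs[[i]], max_len = L)
    tok_a[i, ] <- e$alpha_tokens; tok_b[i, ] <- e$beta_tokens
    mask_a[i, ] <- e$alpha_mask; mask_b[i, ] <- e$beta_mask
    xl_a[i, ] <- e$alpha_xl; xl_b[i, ] <- e$beta_xl
    charge[i] <- ifelse(is.na(e$charge_feature), 0, e$charge_feature)
  }
  list(tok_a = tok_a, tok_b = tok_b, mask_a = mask_a, mask_b = mask_b,
       xl_a = xl_a, xl_b = xl_b, charge = charge, L = L, n = n)
}

# Swap alpha and beta in an encoded batch (for swap augmentation).
swap_encoded <- function(enc) {
  list(tok_a = enc$tok_b, tok_b = enc$tok_a,
       mask_a = enc$mask_b, mask_b = enc$mask_a,
       xl_a = enc$xl_b, xl_b = enc$xl_a,
       charge = enc$charge, L = enc$L, n = enc$n)
}

# Row subset of an encoded batch.
subset_encoded <- function(enc, idx) {
  list(tok_a = enc$tok_a[idx, , drop = FALSE],
       tok_b = enc$tok_b[idx, , drop = FALSE],
       mask_a = enc$mask_a[idx, , drop = FALSE],
       mask_b = enc$mask_b[idx, , drop = FALSE],
       xl_a = enc$xl_a[idx, , drop = FALSE],
       xl_b = enc$xl_b[idx, , drop = FALSE],
       charge = enc$charge[idx], L = enc$L, n = length(idx))
}
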