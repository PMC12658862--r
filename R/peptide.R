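# Peptide and cross-link pair representation, parsing, and theoretical
# b/y fragment generation.

#' Construct a peptide
#'
#' A peptide is a sequence over the 20 canonical one-letter residues plus a
#' (possibly empty) list of modifications, each a signed monoisotopic mass
#' delta attached to a 1-based residue position, and the 1-based position of
#' the cross-linked residue.
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @param mods data.frame with columns \code{position} (1-based integer) and
#'   \code{delta_mass} (Da), or NULL for none. At most one modification per
#'   position; stored sorted by position.
#' @param xl_site 1-based index of the cross-linked residue.
#' @param max_len Maximum allowed length.
#' @return Object of class \code{xl_peptide}.
#' @export
#' @examples
#' peptide("PEPTIDEK", xl_site = 8)
peptide <- function(sequence, mods = NULL, xl_site = 1L, max_len = 50L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, RESIDUES)
  if (length(bad) > 0L)
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  L <- length(chars)
  if (L > max_len) stop("peptide length ", L, " exceeds max_len ", max_len)
  if (is.null(mods)) {
    mods <- data.frame(position = integer(0), delta_mass = numeric(0))
  }
  mods <- as.data.frame(mods)[, c("position", "delta_mass")]
  mods$position <- as.integer(mods$position)
  if (nrow(mods) > 0L) {
    if (any(mods$position < 1L | mods$position > L))
      stop("modification position out of range 1..", L)
    if (anyDuplicated(mods$position))
      stop("more than one modification at a position")
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
  }
  xl_site <- as.integer(xl_site)
  if (xl_site < 1L || xl_site > L) stop("xl_site out of range 1..", L)
  structure(list(sequence = sequence, mods = mods, xl_site = xl_site),
            class = "xl_peptide")
}

#' Parse a modification-annotated peptide string
#'
#' Grammar: residue letters with an optional bracketed signed mass delta
#' immediately after the modified residue, e.g. \code{"PEPTK[+158.0038]R"}.
#' The cross-link site is supplied separately.
#'
#' @param text Annotated sequence string.
#' @param xl_site 1-based cross-link site index.
#' @param max_len Maximum peptide length.
#' @return \code{xl_peptide}.
#' @export
#' @examples
#' parse_peptide("GM[+15.9949]R")
parse_peptide <- function(text, xl_site = 1L, max_len = 50L) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- character(0)
  pos <- integer(0)
  delta <- numeric(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(text, i, n), fixed = TRUE)
      if (close < 0L) stop("malformed bracket: no closing ']' in ", text)
      body <- substr(text, i + 1L, i + close - 2L)
      if (!grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", body))
        stop("malformed bracket contents: '", body, "'")
      if (length(chars) == 0L)
        stop("modification before any residue in ", text)
      pos <- c(pos, length(chars))
      delta <- c(delta, as.numeric(body))
      i <- i + close
    } else {
      chars <- c(chars, ch)
      i <- i + 1L
    }
  }
  mods <- if (length(pos) > 0L)
    data.frame(position = pos, delta_mass = delta) else NULL
  peptide(paste(chars, collapse = ""), mods = mods, xl_site = xl_site,
          max_len = max_len)
}

#' Write a peptide back to its annotated string form
#'
#' Inverse of \code{\link{parse_peptide}} (round-trips exactly for deltas
#' printed with up to 6 significant decimals).
#'
#' @param p \code{xl_peptide}.
#' @return Character scalar.
#' @export
peptide_to_string <- function(p) {
  stopifnot(inherits(p, "xl_peptide"))
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  if (nrow(p$mods) > 0L) {
    ann <- sprintf("[%+.6g]", p$mods$delta_mass)
    chars[p$mods$position] <- paste0(chars[p$mods$position], ann)
  }
  paste(chars, collapse = "")
}

#' @export
print.xl_peptide <- function(x, ...) {
  cat("<xl_peptide> ", peptide_to_string(x),
      "  (length ", nchar(x$sequence), ", xl site ", x$xl_site, ")\n",
      sep = "")
  invisible(x)
}

peptide_length <- function(p) nchar(p$sequence)

# Canonical string key for a peptide: annotated sequence (mods included).
peptide_key <- function(p) peptide_to_string(p)

#' Construct a cross-linked peptide pair
#'
#' The alpha/beta labels follow search-engine convention and carry no
#' physical meaning; \code{\link{swap_pair}} exchanges them.
#'
#' @param alpha,beta \code{xl_peptide} objects.
#' @param linker_mass Intact cross-linker mass (Da); default DSSO.
#' @param precursor_charge Optional positive integer.
#' @param is_decoy Logical decoy flag.
#' @return Object of class \code{xl_pair}.
#' @export
cross_link_pair <- function(alpha, beta, linker_mass = dsso_linker_mass(),
                            precursor_charge = NA_integer_,
                            is_decoy = FALSE) {
  stopifnot(inherits(alpha, "xl_peptide"), inherits(beta, "xl_peptide"),
            is.numeric(linker_mass), linker_mass >= 0)
  if (!is.na(precursor_charge) && precursor_charge < 1L)
    stop("precursor_charge must be a positive integer")
  structure(list(alpha = alpha, beta = beta, linker_mass = linker_mass,
                 precursor_charge = as.integer(precursor_charge),
                 is_decoy = isTRUE(is_decoy)),
            class = "xl_pair")
}

#' Swap the alpha and beta peptides of a pair
#' @param pair \code{xl_pair}.
#' @return \code{xl_pair} with alpha and beta exchanged and nothing else.
#' @export
swap_pair <- function(pair) {
  stopifnot(inherits(pair, "xl_pair"))
  pair[c("alpha", "beta")] <- pair[c("beta", "alpha")]
  pair
}

#' @export
print.xl_pair <- function(x, ...) {
  cat("<xl_pair> ", peptide_to_string(x$alpha), " -- ",
      peptide_to_string(x$beta),
      if (x$is_decoy) "  [decoy]" else "", "\n", sep = "")
  invisible(x)
}

# Canonical pair key: alpha key + "--" + beta key (order-sensitive keys are
# made order-insensitive where grouping demands it; here alpha/beta order is
# part of the identity because the ratio is signed).
pair_key <- function(pair) {
  paste0(peptide_key(pair$alpha), "--", peptide_key(pair$beta))
}

#' Theoretical b/y fragment ions of a cross-linked peptide
#'
#' Generates all b_i and y_i ions, i = 1..L-1, at charges 1..max_frag_charge.
#' Fragments that contain the cross-linked residue carry the intact linker
#' mass (\code{carries_linker = TRUE}). m/z = (neutral mass + z * proton)/z.
#' Only b/y ions are produced; cleavable-linker stub doublets are not
#' modelled.
#'
#' @param p \code{xl_peptide}.
#' @param linker_mass Cross-linker mass added to linker-containing fragments.
#' @param max_frag_charge Highest fragment charge state.
#' @return data.frame with columns ion_type, ordinal, charge, mz,
#'   carries_linker.
#' @export
#' @examples
#' theoretical_fragments(peptide("GG"), linker_mass = 0, max_frag_charge = 1)
theoretical_fragments <- function(p, linker_mass = dsso_linker_mass(),
                                  max_frag_charge = 2L) {
  stopifnot(inherits(p, "xl_peptide"), max_frag_charge >= 1L)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) stop("peptide too short to fragment")
  res_mass <- unname(residue_masses()[chars])
  if (nrow(p$mods) > 0L)
    res_mass[p$mods$position] <- res_mass[p$mods$position] + p$mods$delta_mass
  xl_add <- numeric(L)
  xl_add[p$xl_site] <- linker_mass
  res_mass <- res_mass + xl_add

  prefix <- cumsum(res_mass)          # b_i neutral mass = prefix[i]
  total <- prefix[L]
  ords <- seq_len(L - 1L)
  b_neutral <- prefix[ords]
  y_neutral <- total - prefix[ords] + WATER_MASS   # y_i = last i residues
  y_ord <- L - ords                                 # y ordinal for suffix i..L
  b_linker <- p$xl_site <= ords
  y_linker <- p$xl_site > ords

  out <- do.call(rbind, lapply(seq_len(max_frag_charge), function(z) {
    data.frame(
      ion_type = rep(c("b", "y"), each = L - 1L),
      ordinal = c(ords, y_ord),
      charge = z,
      mz = c((b_neutral + z * PROTON_MASS) / z,
             (y_neutral + z * PROTON_MASS) / z),
      carries_linker = c(b_linker, y_linker),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
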