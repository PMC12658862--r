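# The log2 intensity ratio statistic, its extraction from spectra, the
# per-pair aggregation that builds ground-truth labels, and the CSM table
# interchange format.

#' Log2 intensity ratio between the two peptides of a cross-link
#'
#' The central statistic: log2 of the summed matched fragment intensity of
#' the alpha peptide over that of the beta peptide. Antisymmetric under
#' exchanging the two peptides and invariant to uniform intensity scaling.
#'
#' @param alpha_intensities Matched fragment intensities of the alpha side.
#' @param beta_intensities Matched fragment intensities of the beta side.
#' @return log2 ratio (numeric scalar).
#' @export
#' @examples
#' intensity_ratio(c(300, 100), c(50, 50))  # log2(400/100) = 2
intensity_ratio <- function(alpha_intensities, beta_intensities) {
  sa <- sum(alpha_intensities)
  sb <- sum(beta_intensities)
  if (!is.finite(sa) || !is.finite(sb) || sa <= 0 || sb <= 0)
    stop("undefined intensity ratio: both matched intensity sums must be > 0")
  log2(sa / sb)
}

#' Extract the measured intensity ratio of one CSM
#'
#' Generates theoretical b/y fragments for both peptides, matches them to
#' the spectrum, and computes the log2 intensity ratio from the matched
#' intensity sums (unmatched theoretical fragments contribute zero).
#'
#' @param spec \code{xl_spectrum}.
#' @param pair \code{xl_pair}.
#' @param tol_ppm Matching tolerance (ppm).
#' @param max_frag_charge Highest fragment charge considered.
#' @return List: \code{measured_ratio} (NA if either side has no matched
#'   intensity), \code{n_matched_b_y} (matched fragments, both sides),
#'   \code{matched} (the \code{\link{match_fragments}} result).
#' @export
extract_ratio <- function(spec, pair, tol_ppm = 20, max_frag_charge = 2L) {
  fa <- theoretical_fragments(pair$alpha, pair$linker_mass, max_frag_charge)
  fb <- theoretical_fragments(pair$beta, pair$linker_mass, max_frag_charge)
  fa$parent <- "alpha"
  fb$parent <- "beta"
  m <- match_fragments(spec, rbind(fa, fb), tol_ppm)
  sa <- matched_side_sum(m$alpha)
  sb <- matched_side_sum(m$beta)
  ratio <- if (sa > 0 && sb > 0) log2(sa / sb) else NA_real_
  list(measured_ratio = ratio,
       n_matched_b_y = nrow(m$alpha) + nrow(m$beta),
       matched = m)
}

#' Aggregate CSM-level ratios into per-pair ground-truth labels
#'
#' Groups CSM records by peptide pair identity (sequences plus
#' modifications), drops pairs observed fewer than \code{min_occurrences}
#' times, trims the most extreme ratios (largest absolute deviation from the
#' group median; \code{floor(trim_frac * n)} of them) and returns the
#' trimmed mean as the label together with the trimmed standard deviation.
#'
#' @param records data.frame of CSMs with columns \code{pair_id} (grouping
#'   key) and \code{measured_ratio}; rows with NA ratio are ignored.
#' @param min_occurrences Minimum CSM count per kept pair (default 4, i.e.
#'   pairs with more than three occurrences).
#' @param trim_frac Fraction of each group trimmed as outliers.
#' @return data.frame: pair_id, n_csms, mean_ratio, std_ratio, trimmed.
#' @export
aggregate_pair_ratios <- function(records, min_occurrences = 4L,
                                  trim_frac = 0.05) {
  stopifnot(all(c("pair_id", "measured_ratio") %in% names(records)),
            trim_frac >= 0, trim_frac < 1)
  records <- records[is.finite(records$measured_ratio), , drop = FALSE]
  groups <- split(records$measured_ratio, records$pair_id)
  groups <- groups[lengths(groups) >= min_occurrences]
  if (length(groups) == 0L)
    return(data.frame(pair_id = character(0), n_csms = integer(0),
                      mean_ratio = numeric(0), std_ratio = numeric(0),
                      trimmed = logical(0)))
  out <- lapply(names(groups), function(id) {
    x <- groups[[id]]
    n_trim <- floor(trim_frac * length(x))
    if (n_trim > 0L) {
      dev <- abs(x - stats::median(x))
      keep <- order(dev)[seq_len(length(x) - n_trim)]
      x <- x[keep]
    }
    data.frame(pair_id = id, n_csms = length(groups[[id]]),
               mean_ratio = mean(x),
               std_ratio = if (length(x) > 1L) stats::sd(x) else 0,
               trimmed = n_trim > 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Within- versus between-group spread of intensity ratios
#'
#' The stability summary: mean within-group standard deviation (replicate
#' scatter of the same peptide pair) versus the standard deviation of the
#' group means (spread across different pairs). Stable ratios show
#' within far below between.
#'
#' @param summaries Output of \code{\link{aggregate_pair_ratios}} (>= 2 rows).
#' @return List with \code{within} and \code{between}.
#' @export
variance_decomposition <- function(summaries) {
  if (nrow(summaries) < 2L)
    stop("need at least two peptide-pair groups")
  list(within = mean(summaries$std_ratio),
       between = stats::sd(summaries$mean_ratio))
}

# ---- CSM table interchange (TSV with a versioned header line) ----

CSM_TSV_VERSION <- "xlratio-csm-v1"
CSM_COLUMNS <- c("scan_id", "alpha_seq", "alpha_mods", "alpha_site",
                 "beta_seq", "beta_mods", "beta_site", "precursor_charge",
                 "is_decoy", "engine_score", "measured_ratio")

#' Write a CSM table
#'
#' Tab-separated with a leading \code{# xlratio-csm-v1} version line.
#' Sequence columns use the bracketed-delta dialect of
#' \code{\link{parse_peptide}} split into plain sequence and a
#' \code{pos:delta} modification list (\code{;}-separated, \code{-} if none).
#' Extra columns (scores, q-values) are preserved.
#'
#' @param tab data.frame containing at least the standard columns.
#' @param path Output path.
#' @param force Overwrite an existing file.
#' @return Invisibly, \code{path}.
#' @export
write_csm_table <- function(tab, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  missing_cols <- setdiff(CSM_COLUMNS, names(tab))
  for (mc in missing_cols) tab[[mc]] <- NA
  tab <- tab[, c(CSM_COLUMNS, setdiff(names(tab), CSM_COLUMNS)), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# ", CSM_TSV_VERSION), con, sep = "\n")
  num <- vapply(tab, is.numeric, TRUE) & !vapply(tab, is.integer, TRUE)
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 12))
  })
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Read a CSM table written by \code{\link{write_csm_table}}
#' @param path File path.
#' @return data.frame.
#' @export
read_csm_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("# ", CSM_TSV_VERSION)))
    stop(path, " is not a ", CSM_TSV_VERSION, " table (header: ", first, ")")
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = NA, check.names = FALSE)
  for (cc in c("alpha_mods", "beta_mods"))
    if (cc %in% names(tab)) tab[[cc]] <- as.character(tab[[cc]])
  tab
}

# Serialize/deserialize mods for the TSV mod columns.
mods_to_string <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("-")
  paste(sprintf("%d:%+.6g", mods$position, mods$delta_mass), collapse = ";")
}
mods_from_string <- function(s) {
  if (is.na(s) || s == "-" || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             delta_mass = as.numeric(vapply(parts, `[`, "", 2L)))
}

# Rebuild an xl_pair from one CSM table row.
pair_from_row <- function(row, linker_mass = dsso_linker_mass()) {
  a <- peptide(row$alpha_seq, mods_from_string(row$alpha_mods),
               xl_site = row$alpha_site)
  b <- peptide(row$beta_seq, mods_from_string(row$beta_mods),
               xl_site = row$beta_site)
  cross_link_pair(a, b, linker_mass = linker_mass,
                  precursor_charge = row$precursor_charge,
                  is_decoy = isTRUE(as.logical(row$is_decoy)))
}

# One CSM table row (without measured_ratio) from an xl_pair.
row_from_pair <- function(pair, scan_id = NA_character_) {
  data.frame(scan_id = scan_id,
             alpha_seq = pair$alpha$sequence,
             alpha_mods = mods_to_string(pair$alpha$mods),
             alpha_site = pair$alpha$xl_site,
             beta_seq = pair$beta$sequence,
             beta_mods = mods_to_string(pair$beta$mods),
             beta_site = pair$beta$xl_site,
             precursor_charge = pair$precursor_charge,
             is_decoy = pair$is_decoy,
             engine_score = NA_real_,
             measured_ratio = NA_real_,
             stringsAsFactors = FALSE)
}

# Pair identity key from CSM table columns (used for grouping/aggregation).
pair_id_from_table <- function(tab) {
  paste0(tab$alpha_seq, "|", tab$alpha_mods, "--",
         tab$beta_seq, "|", tab$beta_mods)
}
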