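# MS/MS spectrum container, MGF reading/writing, and fragment-peak matching.

#' Construct an MS/MS spectrum
#'
#' @param mz Numeric vector of peak m/z values (Th).
#' @param intensity Numeric vector of non-negative peak intensities.
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Integer precursor charge.
#' @param scan_id Character scan identifier.
#' @return Object of class \code{xl_spectrum}; peaks stored sorted by m/z.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_, scan_id = "") {
  stopifnot(length(mz) == length(intensity))
  if (length(intensity) > 0L) {
    stopifnot(all(is.finite(intensity)), all(intensity >= 0),
              all(is.finite(mz)), all(mz > 0))
  }
  o <- order(mz)
  structure(list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 scan_id = as.character(scan_id)),
            class = "xl_spectrum")
}

#' @export
print.xl_spectrum <- function(x, ...) {
  cat("<xl_spectrum> ", x$scan_id, ": ", length(x$mz), " peaks",
      if (!is.na(x$precursor_mz))
        paste0(", precursor ", format(x$precursor_mz), " (",
               x$precursor_charge, "+)"),
      "\n", sep = "")
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Supports BEGIN IONS/END IONS blocks with TITLE (used as scan_id), PEPMASS
#' and CHARGE headers followed by "m/z intensity" peak lines.
#'
#' @param path File path.
#' @return List of \code{xl_spectrum}, named by scan_id.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    keyval <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(keyval, `[`, "", 1L)
    vals <- vapply(keyval, function(x) paste(x[-1L], collapse = "="), "")
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0("scan_", k)
    pepmass <- if ("PEPMASS" %in% keys)
      as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1L]][1L])
    else NA_real_
    charge <- if ("CHARGE" %in% keys)
      as.integer(sub("\\+$", "", vals[match("CHARGE", keys)]))
    else NA_integer_
    peaks <- block[!hdr & nzchar(block)]
    if (length(peaks) > 0L) {
      m <- do.call(rbind, strsplit(trimws(peaks), "[ \t]+"))
      mzv <- as.numeric(m[, 1L]); iv <- as.numeric(m[, 2L])
    } else {
      mzv <- numeric(0); iv <- numeric(0)
    }
    out[[k]] <- spectrum(mzv, iv, precursor_mz = pepmass,
                         precursor_charge = charge, scan_id = title)
  }
  names(out) <- vapply(out, function(s) s$scan_id, "")
  out
}

#' Write spectra to an MGF file
#'
#' Deterministic text output: same spectra give byte-identical files.
#'
#' @param spectra List of \code{xl_spectrum}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")  # binary mode: fixed "\n" line endings
  on.exit(close(con))
  for (s in spectra) {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", s$scan_id),
               if (!is.na(s$precursor_mz))
                 paste0("PEPMASS=", formatC(s$precursor_mz, format = "f",
                                            digits = 6)),
               if (!is.na(s$precursor_charge))
                 paste0("CHARGE=", s$precursor_charge, "+"),
               paste(formatC(s$mz, format = "f", digits = 6),
                     formatC(s$intensity, format = "f", digits = 6)),
               "END IONS", "")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Match theoretical fragments to spectrum peaks
#'
#' Each fragment is assigned to at most one peak: the nearest peak by m/z
#' within \code{tol_ppm} parts-per-million (on an exact distance tie the more
#' intense peak wins). A peak claimed by fragments of both peptides (a shared
#' m/z) has its intensity split equally between the two sides to avoid double
#' counting. Within one side a peak is counted once even if several fragments
#' (e.g. charge states) hit it.
#'
#' @param spec \code{xl_spectrum}.
#' @param fragments data.frame as returned by
#'   \code{\link{theoretical_fragments}}, with an extra \code{parent} column
#'   of "alpha"/"beta" values.
#' @param tol_ppm Matching tolerance in ppm (> 0).
#' @return List with elements \code{alpha} and \code{beta}, each a data.frame
#'   of matched fragments with columns of \code{fragments} plus
#'   \code{peak_mz}, \code{peak_index} and \code{intensity} (the intensity
#'   credited to that side, after any shared-peak split).
#' @export
match_fragments <- function(spec, fragments, tol_ppm = 20) {
  stopifnot(inherits(spec, "xl_spectrum"), tol_ppm > 0,
            "parent" %in% names(fragments))
  nf <- nrow(fragments)
  empty <- function() cbind(fragments[0, , drop = FALSE],
                            data.frame(peak_mz = numeric(0),
                                       peak_index = integer(0),
                                       intensity = numeric(0)))
  if (length(spec$mz) == 0L || nf == 0L)
    return(list(alpha = empty(), beta = empty()))

  # nearest peak per fragment via findInterval on the sorted peak list
  idx <- findInterval(fragments$mz, spec$mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(spec$mz))
  d_lo <- abs(spec$mz[lo] - fragments$mz)
  d_hi <- abs(spec$mz[hi] - fragments$mz)
  # tie -> more intense peak
  take_hi <- (d_hi < d_lo) |
    (d_hi == d_lo & spec$intensity[hi] > spec$intensity[lo])
  best <- ifelse(take_hi, hi, lo)
  dist <- pmin(d_lo, d_hi)
  ok <- dist <= fragments$mz * tol_ppm * 1e-6

  matched <- cbind(fragments[ok, , drop = FALSE],
                   data.frame(peak_mz = spec$mz[best[ok]],
                              peak_index = best[ok],
                              intensity = spec$intensity[best[ok]]))
  rownames(matched) <- NULL
  a <- matched[matched$parent == "alpha", , drop = FALSE]
  b <- matched[matched$parent == "beta", , drop = FALSE]
  shared <- intersect(unique(a$peak_index), unique(b$peak_index))
  if (length(shared) > 0L) {
    a$intensity[a$peak_index %in% shared] <-
      a$intensity[a$peak_index %in% shared] / 2
    b$intensity[b$peak_index %in% shared] <-
      b$intensity[b$peak_index %in% shared] / 2
  }
  list(alpha = a, beta = b)
}

# Sum of matched intensities for one side, counting each peak once.
matched_side_sum <- function(side) {
  if (nrow(side) == 0L) return(0)
  sum(side$intensity[!duplicated(side$peak_index)])
}
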