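# Synthetic cross-linking data generator. Every peptide pair carries a
# latent ground-truth log2 intensity ratio built from an additive
# per-residue rule; replicate CSMs scatter around it with Gaussian noise,
# and fragment intensities realize the replicate ratio exactly before
# multiplicative per-fragment noise. This gives every downstream stage —
# extraction, aggregation, model fitting, rescoring, attribution — a known
# truth to be checked against.

#' Configuration of the synthetic data generator
#'
#' The generator emulates the structure that makes the intensity ratio a
#' usable label: a pair-intrinsic ratio (here an exactly additive function
#' of residue composition), replicate-level scatter around it, and
#' fragment-level intensity noise. Defaults: 2,000 pairs of 8 CSMs each,
#' within-pair replicate s.d. 0.1 log2 units (the scatter observed for real
#' repeated CSMs), per-residue weights drawn from Normal(0, 0.15) which
#' spreads true ratios with s.d. about 0.7 across pairs.
#'
#' @param seed Mandatory RNG seed; all draws (weights included) derive from
#'   it.
#' @param n_pairs Number of target peptide pairs.
#' @param csms_per_pair Replicate CSMs generated per pair.
#' @param sigma_within Replicate-level s.d. of the log2 ratio.
#' @param sigma_frag Multiplicative (log-normal sdlog) per-fragment
#'   intensity noise.
#' @param length_range Inclusive peptide length range (min >= 5).
#' @param residue_weights Named log2 contribution per residue; drawn from
#'   Normal(0, 0.15) under \code{seed} when NULL.
#' @param noise_peaks Count of uniform random background peaks per spectrum.
#' @param max_frag_charge Fragment charge states written to spectra.
#' @return Object of class \code{xl_sim_config}.
#' @export
generative_config <- function(seed,
                              n_pairs = 2000L,
                              csms_per_pair = 8L,
                              sigma_within = 0.1,
                              sigma_frag = 0.2,
                              length_range = c(7L, 15L),
                              residue_weights = NULL,
                              noise_peaks = 5L,
                              max_frag_charge = 1L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(sigma_within >= 0, sigma_frag >= 0,
            length(length_range) == 2L, length_range[1L] >= 5L,
            length_range[2L] >= length_range[1L],
            n_pairs >= 1L, csms_per_pair >= 1L)
  if (is.null(residue_weights)) {
    set.seed(seed)
    residue_weights <- stats::setNames(stats::rnorm(20L, 0, 0.15), RESIDUES)
  }
  stopifnot(all(RESIDUES %in% names(residue_weights)))
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 csms_per_pair = as.integer(csms_per_pair),
                 sigma_within = sigma_within, sigma_frag = sigma_frag,
                 length_range = as.integer(length_range),
                 residue_weights = residue_weights,
                 noise_peaks = as.integer(noise_peaks),
                 max_frag_charge = as.integer(max_frag_charge)),
            class = "xl_sim_config")
}

# One random peptide with a lysine forced at a random internal position
# (the cross-linker is lysine-reactive); the terminal residue is K or R to
# mimic tryptic ends.
sample_peptide <- function(cfg) {
  lo <- cfg$length_range[1L]
  hi <- cfg$length_range[2L]
  L <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  chars <- sample(RESIDUES, L, replace = TRUE)
  chars[L] <- sample(c("K", "R"), 1L)
  site <- sample.int(L - 1L, 1L)
  chars[site] <- "K"
  peptide(paste(chars, collapse = ""), xl_site = site)
}

#' Draw one synthetic cross-linked pair
#'
#' Uniform residue draws within the configured length range; each peptide
#' gets one lysine forced as the cross-link site. Pairs whose alpha and
#' beta theoretical fragments fall closer than 0.1 Th anywhere are
#' resampled, so fragment matching is unambiguous on generated spectra.
#'
#' @param cfg \code{\link{generative_config}}. Uses the current RNG state
#'   (seed it, or use \code{\link{make_dataset}}).
#' @return \code{xl_pair} with a random precursor charge of 3 or 4.
#' @export
sample_pair <- function(cfg) {
  for (try in 1:100) {
    a <- sample_peptide(cfg)
    b <- sample_peptide(cfg)
    pr <- cross_link_pair(a, b, precursor_charge = sample(3:4, 1L))
    fa <- theoretical_fragments(a, pr$linker_mass, cfg$max_frag_charge)
    fb <- theoretical_fragments(b, pr$linker_mass, cfg$max_frag_charge)
    gap <- min(abs(outer(fa$mz, fb$mz, `-`)))
    if (gap > 0.1) return(pr)
  }
  stop("could not draw a collision-free pair in 100 attempts")
}

#' Latent ground-truth ratio of a pair
#'
#' The additive per-residue rule: sum of residue weights over the alpha
#' sequence minus the same sum over beta. Exactly antisymmetric under
#' \code{\link{swap_pair}}, and linear in residue counts — so the
#' regressor can provably learn it and Shapley attributions have a closed
#' form.
#'
#' @param pair \code{xl_pair}.
#' @param cfg \code{\link{generative_config}}.
#' @return log2 ratio (numeric scalar).
#' @export
true_ratio <- function(pair, cfg) {
  w <- cfg$residue_weights
  s <- function(p) sum(w[strsplit(p$sequence, "", fixed = TRUE)[[1L]]])
  s(pair$alpha) - s(pair$beta)
}

#' Simulate one CSM: a spectrum and its record row
#'
#' The replicate ratio is \code{true_ratio + Normal(0, sigma_within)}.
#' Fragment intensities are drawn uniformly, the alpha side is rescaled so
#' the summed alpha/beta intensities realize the replicate ratio exactly,
#' then each fragment is perturbed log-normally with sdlog
#' \code{sigma_frag} and background peaks are added. With
#' \code{sigma_frag = 0} and \code{noise_peaks = 0}, extraction recovers
#' the replicate ratio to machine precision.
#'
#' @param pair \code{xl_pair}.
#' @param cfg \code{\link{generative_config}}.
#' @param scan_id Scan identifier written to the spectrum.
#' @return List: \code{spectrum}, \code{row} (CSM table row),
#'   \code{replicate_ratio}.
#' @export
simulate_csm <- function(pair, cfg, scan_id = "scan_1") {
  rho <- true_ratio(pair, cfg) + stats::rnorm(1L, 0, cfg$sigma_within)
  fa <- theoretical_fragments(pair$alpha, pair$linker_mass,
                              cfg$max_frag_charge)
  fb <- theoretical_fragments(pair$beta, pair$linker_mass,
                              cfg$max_frag_charge)
  ia <- stats::runif(nrow(fa), 0.5, 1.5)
  ib <- stats::runif(nrow(fb), 0.5, 1.5)
  ia <- ia * (2^rho * sum(ib) / sum(ia))   # realize the replicate ratio
  scale <- 1e4
  ia <- ia * scale * exp(stats::rnorm(nrow(fa), 0, cfg$sigma_frag))
  ib <- ib * scale * exp(stats::rnorm(nrow(fb), 0, cfg$sigma_frag))
  mz <- c(fa$mz, fb$mz)
  intensity <- c(ia, ib)
  # merge exact-duplicate m/z within the written peak list
  if (anyDuplicated(mz)) {
    agg <- rowsum(intensity, group = mz)
    mz <- as.numeric(rownames(agg))
    intensity <- as.vector(agg)
  }
  if (cfg$noise_peaks > 0L) {
    nmz <- stats::runif(cfg$noise_peaks, 150, 1500)
    nint <- stats::runif(cfg$noise_peaks, 0, 0.05 * scale)
    mz <- c(mz, nmz)
    intensity <- c(intensity, nint)
  }
  pep_mass <- sum(unlist(lapply(list(pair$alpha, pair$beta), function(p) {
    chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
    sum(residue_masses()[chars]) + sum(p$mods$delta_mass)
  }))) + 2 * WATER_MASS + pair$linker_mass
  z <- pair$precursor_charge
  spec <- spectrum(mz, intensity,
                   precursor_mz = (pep_mass + z * PROTON_MASS) / z,
                   precursor_charge = z, scan_id = scan_id)
  row <- row_from_pair(pair, scan_id = scan_id)
  list(spectrum = spec, row = row, replicate_ratio = rho)
}

#' Decoy pairs by sequence reversal
#'
#' For each target pair one peptide (chosen at random) has its sequence
#' reversed with the cross-linked residue held at its original position;
#' the result is flagged as a decoy. n targets in, n decoys out.
#'
#' @param pairs List of target \code{xl_pair}.
#' @return List of decoy \code{xl_pair} of the same length.
#' @export
make_decoys <- function(pairs) {
  reverse_keep_site <- function(p) {
    chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
    rest <- rev(chars[-p$xl_site])
    out <- append(rest, chars[p$xl_site], after = p$xl_site - 1L)
    peptide(paste(out, collapse = ""), mods = NULL, xl_site = p$xl_site)
  }
  lapply(pairs, function(pr) {
    side <- sample(c("alpha", "beta"), 1L)
    pr[[side]] <- reverse_keep_site(pr[[side]])
    pr$is_decoy <- TRUE
    pr
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Draws the configured pairs and CSMs, writes the MGF spectra, the CSM
#' assignment table and the ground-truth table (pair key and true ratio).
#' Regeneration under the same config is byte-identical.
#'
#' @param cfg \code{\link{generative_config}}.
#' @param dir Output directory (created if needed).
#' @param decoy_fraction Fraction of pairs that also contribute a decoy
#'   (reversed-sequence, \code{\link{make_decoys}}) CSM row per target scan
#'   of the source pair — the "right spectrum, wrong peptide" competition
#'   that target-decoy FDR estimation needs.
#' @param force Overwrite existing files.
#' @return Invisibly, a list with the file paths (\code{csm}, \code{mgf},
#'   \code{truth}) plus the in-memory \code{pairs}, \code{truth_table} and
#'   \code{spectra}.
#' @export
make_dataset <- function(cfg, dir, decoy_fraction = 0, force = FALSE) {
  stopifnot(inherits(cfg, "xl_sim_config"),
            decoy_fraction >= 0, decoy_fraction <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  pairs <- replicate(cfg$n_pairs, sample_pair(cfg), simplify = FALSE)
  spectra <- list()
  rows <- vector("list", cfg$n_pairs * cfg$csms_per_pair)
  truth <- data.frame(pair_id = character(cfg$n_pairs),
                      alpha_seq = "", beta_seq = "",
                      true_ratio = 0, stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    truth$pair_id[i] <- pair_key(pr)
    truth$alpha_seq[i] <- pr$alpha$sequence
    truth$beta_seq[i] <- pr$beta$sequence
    truth$true_ratio[i] <- true_ratio(pr, cfg)
    for (j in seq_len(cfg$csms_per_pair)) {
      k <- k + 1L
      sim <- simulate_csm(pr, cfg, scan_id = sprintf("scan_%05d", k))
      spectra[[k]] <- sim$spectrum
      rows[[k]] <- sim$row
    }
  }
  csm <- do.call(rbind, rows)
  n_decoy <- round(decoy_fraction * cfg$n_pairs)
  if (n_decoy > 0L) {
    dpairs <- make_decoys(pairs[seq_len(n_decoy)])
    drows <- lapply(seq_len(n_decoy), function(i) {
      scans <- sprintf("scan_%05d", (i - 1L) * cfg$csms_per_pair +
                         seq_len(cfg$csms_per_pair))
      do.call(rbind, lapply(scans, function(s)
        row_from_pair(dpairs[[i]], scan_id = s)))
    })
    csm <- rbind(csm, do.call(rbind, drows))
  }
  paths <- list(csm = file.path(dir, "csms.tsv"),
                mgf = file.path(dir, "spectra.mgf"),
                truth = file.path(dir, "truth.tsv"))
  if (!force && any(file.exists(unlist(paths))))
    stop("output files exist in ", dir, " (use force = TRUE)")
  write_csm_table(csm, paths$csm, force = force)
  write_mgf(spectra, paths$mgf)
  con <- file(paths$truth, open = "wb")
  utils::write.table(format(truth, digits = 12, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  close(con)
  invisible(c(paths, list(pairs = pairs, truth_table = truth,
                          spectra = spectra)))
}
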