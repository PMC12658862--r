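# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as naive, loop-based computations so they share no
# code path with the package implementation.

# -- independent fragment mass oracle ------------------------------------
# Recomputes b/y m/z by explicit prefix/suffix summation from the shipped
# plain-text mass table.
oracle_mass_table <- function() {
  tab <- read.table(system.file("extdata", "monoisotopic_masses.tsv",
                                package = "xlratio"),
                    sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(tab[[2L]], tab[[1L]])
}

oracle_fragment_mz <- function(seq_chars, mods, xl_site, linker_mass,
                               ion_type, ordinal, charge) {
  mt <- oracle_mass_table()
  proton <- 1.00727646677
  water <- 18.0105646837
  L <- length(seq_chars)
  res <- numeric(L)
  for (i in seq_len(L)) res[i] <- mt[[seq_chars[i]]]
  if (!is.null(mods)) for (r in seq_len(nrow(mods)))
    res[mods$position[r]] <- res[mods$position[r]] + mods$delta_mass[r]
  res[xl_site] <- res[xl_site] + linker_mass
  if (ion_type == "b") {
    neutral <- 0
    for (i in seq_len(ordinal)) neutral <- neutral + res[i]
  } else {
    neutral <- water
    for (i in (L - ordinal + 1L):L) neutral <- neutral + res[i]
  }
  (neutral + charge * proton) / charge
}

# -- independent DDP oracle ----------------------------------------------
# Full-grid construction with explicit vectors; different code path from
# ddp_score (which works on sparse bin sets).
oracle_ddp <- function(amz, bmz, spec_mz, spec_int, width) {
  bins <- function(mz) unique(floor(mz / width))
  ba <- bins(amz); bb <- bins(bmz)
  shared <- ba[ba %in% bb]
  ba <- ba[!(ba %in% shared)]; bb <- bb[!(bb %in% shared)]
  grid <- sort(unique(c(ba, bb, floor(spec_mz / width))))
  evec <- numeric(length(grid))
  for (i in seq_along(spec_mz)) {
    g <- which(grid == floor(spec_mz[i] / width))
    evec[g] <- evec[g] + spec_int[i]
  }
  dotside <- function(bset) {
    if (length(bset) == 0L) return(0)
    tv <- numeric(length(grid)); ev <- numeric(length(grid))
    for (b in bset) {
      g <- which(grid == b)
      tv[g] <- 1
      ev[g] <- evec[g]
    }
    if (sqrt(sum(ev^2)) == 0) return(0)
    sum((tv / sqrt(sum(tv^2))) * (ev / sqrt(sum(ev^2))))
  }
  dotside(ba) + dotside(bb)
}

# -- small builders -------------------------------------------------------
mkpep <- function(s, site = 1L, mods = NULL) peptide(s, mods = mods,
                                                     xl_site = site)
mkpair <- function(a, b, site_a = 1L, site_b = 1L, charge = NA_integer_,
                   linker = dsso_linker_mass()) {
  cross_link_pair(mkpep(a, site_a), mkpep(b, site_b), linker_mass = linker,
                  precursor_charge = charge)
}

random_peptide_string <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Linear surrogate model: prediction = sum of per-token weights over the
# valid alpha positions (beta ignored). Shapley values have the closed
# form phi_i = w(x_i) - mean_r w(ref_i); used to check the attribution
# estimator against exact results.
new_linear_token_model <- function(weights) {
  structure(list(w = weights, config = NULL), class = "linear_token_model")
}
predict_linear_token_model <- function(object, pairs, ...) {
  stopifnot(is.list(pairs), !is.null(pairs$tok_a))
  tok <- pairs$tok_a
  out <- numeric(nrow(tok))
  for (l in seq_len(ncol(tok))) {
    nz <- tok[, l] > 0L
    out[nz] <- out[nz] + object$w[tok[nz, l]]
  }
  out
}
registerS3method("predict", "linear_token_model",
                 predict_linear_token_model,
                 envir = asNamespace("stats"))

# Tiny trained model shared across test files (trained once per run).
tiny_model_env <- new.env(parent = emptyenv())
tiny_trained_model <- function() {
  if (!is.null(tiny_model_env$model)) return(tiny_model_env$fixture)
  cfg <- generative_config(seed = 77L, n_pairs = 320L, csms_per_pair = 1L)
  set.seed(cfg$seed)
  pairs <- replicate(cfg$n_pairs, sample_pair(cfg), simplify = FALSE)
  y <- vapply(pairs, true_ratio, 0, cfg = cfg)
  model <- ratio_model(pairs[1:260], y[1:260],
                       model_config(seed = 9L, epochs = 18L))
  fixture <- list(model = model, pairs = pairs, y = y, cfg = cfg,
                  train_idx = 1:260, test_idx = 261:320)
  tiny_model_env$model <- model
  tiny_model_env$fixture <- fixture
  fixture
}
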