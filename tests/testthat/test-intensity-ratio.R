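# Fragment-peak matching, the log2 intensity ratio, aggregation and the
# spectrum/table interchange formats.

test_that("intensity ratio matches hand-computed values and errors on empty sides", {
  expect_equal(intensity_ratio(c(60, 40), c(100)), 0)
  expect_equal(intensity_ratio(c(300, 100), c(50, 50)), 2)
  expect_error(intensity_ratio(numeric(0), c(1)), "undefined")
  expect_error(intensity_ratio(c(0, 0), c(1)), "undefined")
})

test_that("intensity ratio is antisymmetric and scale invariant", {
  set.seed(11)
  for (i in 1:1000) {
    a <- runif(sample(1:6, 1L), 0.01, 100)
    b <- runif(sample(1:6, 1L), 0.01, 100)
    expect_equal(intensity_ratio(a, b), -intensity_ratio(b, a))
    c <- runif(1, 0.01, 1000)
    expect_equal(intensity_ratio(a * c, b * c), intensity_ratio(a, b),
                 tolerance = 1e-12)
  }
})

test_that("fragment matching picks the nearest in-tolerance peak", {
  frags <- data.frame(ion_type = "b", ordinal = 1L, charge = 1L,
                      mz = 500, carries_linker = FALSE, parent = "alpha")
  sp <- spectrum(c(500, 700), c(10, 20), scan_id = "s1")
  m <- match_fragments(sp, frags, tol_ppm = 10)
  expect_equal(nrow(m$alpha), 1L)
  expect_equal(m$alpha$intensity, 10)
  expect_equal(nrow(m$beta), 0L)

  empty <- spectrum(numeric(0), numeric(0), scan_id = "e")
  m0 <- match_fragments(empty, frags, tol_ppm = 10)
  expect_equal(nrow(m0$alpha), 0L)
  expect_equal(nrow(m0$beta), 0L)

  # two peaks at -5 and +4 ppm: nearer wins; exact tie -> more intense
  sp2 <- spectrum(c(500 * (1 - 5e-6), 500 * (1 + 4e-6)), c(100, 1),
                  scan_id = "s2")
  m2 <- match_fragments(sp2, frags, tol_ppm = 10)
  expect_equal(m2$alpha$intensity, 1)
  sp3 <- spectrum(c(500 - 1e-3, 500 + 1e-3), c(1, 100), scan_id = "s3")
  m3 <- match_fragments(sp3, frags, tol_ppm = 10)
  expect_equal(m3$alpha$intensity, 100)
})

test_that("matching agrees with a brute-force nearest-peak oracle", {
  set.seed(21)
  for (rep in 1:50) {
    nf <- sample(3:10, 1L)
    frags <- data.frame(ion_type = "b", ordinal = seq_len(nf), charge = 1L,
                        mz = runif(nf, 200, 1500), carries_linker = FALSE,
                        parent = "alpha")
    sp <- spectrum(runif(20, 200, 1500), runif(20, 1, 100), scan_id = "r")
    tol <- 50
    m <- match_fragments(sp, frags, tol_ppm = tol)
    for (i in seq_len(nf)) {
      d <- abs(sp$mz - frags$mz[i])
      ok <- d <= frags$mz[i] * tol * 1e-6
      hit <- m$alpha[m$alpha$ordinal == i, , drop = FALSE]
      if (!any(ok)) {
        expect_equal(nrow(hit), 0L)
      } else {
        best <- which(ok)[which.min(d[ok])]
        expect_equal(hit$peak_mz, sp$mz[best])
      }
    }
  }
})

test_that("matching is tolerance-monotone", {
  set.seed(31)
  frags <- data.frame(ion_type = "b", ordinal = 1:8, charge = 1L,
                      mz = runif(8, 200, 1200), carries_linker = FALSE,
                      parent = rep(c("alpha", "beta"), 4))
  sp <- spectrum(runif(30, 200, 1200), runif(30, 1, 10), scan_id = "m")
  sizes <- vapply(c(1, 5, 20, 100, 500), function(tol) {
    m <- match_fragments(sp, frags, tol_ppm = tol)
    nrow(m$alpha) + nrow(m$beta)
  }, 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("peaks claimed by both peptides are split equally", {
  frags <- data.frame(ion_type = "b", ordinal = c(1L, 1L), charge = 1L,
                      mz = c(500, 500.000001), carries_linker = FALSE,
                      parent = c("alpha", "beta"))
  sp <- spectrum(500, 80, scan_id = "sh")
  m <- match_fragments(sp, frags, tol_ppm = 10)
  expect_equal(m$alpha$intensity, 40)
  expect_equal(m$beta$intensity, 40)
})

test_that("aggregation filters rare pairs and trims extreme ratios", {
  rec <- data.frame(pair_id = rep("p1", 5), measured_ratio = rep(1.3, 5))
  agg <- aggregate_pair_ratios(rec)
  expect_equal(agg$mean_ratio, 1.3)
  expect_equal(agg$std_ratio, 0)
  expect_equal(agg$n_csms, 5L)

  rec2 <- data.frame(pair_id = rep("p1", 3), measured_ratio = 1:3)
  expect_equal(nrow(aggregate_pair_ratios(rec2, min_occurrences = 4L)), 0L)

  set.seed(5)
  x <- c(rnorm(19, 1, 0.05), 25)
  rec3 <- data.frame(pair_id = "p", measured_ratio = x)
  agg3 <- aggregate_pair_ratios(rec3, min_occurrences = 4L,
                                trim_frac = 0.05)
  # brute-force oracle: drop the single worst deviation from the median
  keep <- order(abs(x - median(x)))[1:19]
  expect_equal(agg3$mean_ratio, mean(x[keep]))
  expect_equal(agg3$std_ratio, sd(x[keep]))
  expect_true(agg3$trimmed)
})

test_that("variance decomposition separates within from between spread", {
  s <- data.frame(pair_id = c("a", "b", "c"), n_csms = 5L,
                  mean_ratio = c(-1, 0, 2), std_ratio = 0,
                  trimmed = FALSE)
  v <- variance_decomposition(s)
  expect_equal(v$within, 0)
  expect_gt(v$between, 0)
  expect_error(variance_decomposition(s[1, ]), "two")

  # sampling-theory check: recover (0.1, 0.7) within 20% at 50 x 15
  set.seed(99)
  mu <- rnorm(50, 0, 0.7)
  rec <- do.call(rbind, lapply(seq_along(mu), function(g)
    data.frame(pair_id = sprintf("g%02d", g),
               measured_ratio = rnorm(15, mu[g], 0.1))))
  v2 <- variance_decomposition(aggregate_pair_ratios(rec, trim_frac = 0))
  expect_equal(v2$within, 0.1, tolerance = 0.2)
  expect_equal(v2$between, 0.7, tolerance = 0.2)
})

test_that("MGF files round-trip through writer and reader", {
  sps <- list(spectrum(c(100.5, 200.25), c(10, 20), precursor_mz = 512.75,
                       precursor_charge = 3L, scan_id = "scan_a"),
              spectrum(numeric(0), numeric(0), scan_id = "scan_b"))
  path <- tempfile(fileext = ".mgf")
  write_mgf(sps, path)
  rd <- read_mgf(path)
  expect_equal(names(rd), c("scan_a", "scan_b"))
  expect_equal(rd$scan_a$mz, c(100.5, 200.25))
  expect_equal(rd$scan_a$intensity, c(10, 20))
  expect_equal(rd$scan_a$precursor_mz, 512.75)
  expect_equal(rd$scan_a$precursor_charge, 3L)
  expect_equal(length(rd$scan_b$mz), 0L)
})

test_that("CSM tables round-trip losslessly and reject foreign files", {
  pr <- mkpair("GAVLK", "MSTWYK", site_a = 5L, site_b = 6L, charge = 3L)
  tab <- xlratio:::row_from_pair(pr, scan_id = "s1")
  tab$measured_ratio <- 1.23456789
  path <- tempfile(fileext = ".tsv")
  write_csm_table(tab, path)
  rd <- read_csm_table(path)
  expect_equal(rd$alpha_seq, "GAVLK")
  expect_equal(rd$measured_ratio, 1.23456789)
  pr2 <- xlratio:::pair_from_row(rd[1, ])
  expect_equal(pr2$alpha$sequence, pr$alpha$sequence)
  expect_equal(pr2$beta$xl_site, pr$beta$xl_site)

  bad <- tempfile()
  writeLines("not a csm table", bad)
  expect_error(read_csm_table(bad), "not a")
  expect_error(write_csm_table(tab, path), "overwrite")
})
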