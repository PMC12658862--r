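# The ratio regressor: gradients, determinism, parameter sharing,
# training behaviour, cross-validation, fine-tuning and the references.

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- model_config(embed_dim = 4L, cnn = list(c(5L, 3L)), attn_dim = 4L,
                      head_hidden = 6L, dropout = 0, seed = 3L)
  pairs <- list(mkpair("KGAVY", "KLSTM", charge = 3L),
                mkpair("KGG", "KAVLYR"))
  enc <- xlratio:::encode_pairs_matrix(pairs, 50L)
  params <- xlratio:::init_params(cfg)
  y <- c(0.5, -1)
  fw <- xlratio:::nn_forward(params, enc, cfg, train = FALSE)
  grads <- xlratio:::nn_backward(params, enc, fw$cache,
                                 2 * (fw$pred - y) / 2, cfg)
  lossfn <- function(p) {
    mean((xlratio:::nn_forward(p, enc, cfg, train = FALSE)$pred - y)^2)
  }
  eps <- 1e-6
  set.seed(42)
  for (path in list(list("E"), list("conv", 1L, "W"), list("attn", "Wq"),
                    list("attn", "Wv"), list("head", "W1"),
                    list("head", "W2"))) {
    arr <- params; for (k in path) arr <- arr[[k]]
    garr <- grads; for (k in path) garr <- garr[[k]]
    for (i in sample(length(arr), 5L)) {
      bump <- function(d) {
        pp <- params
        ref <- function(pl, pa) if (length(pa) == 1L) {
          pl[[pa[[1L]]]][i] <- pl[[pa[[1L]]]][i] + d; pl
        } else {
          pl[[pa[[1L]]]] <- ref(pl[[pa[[1L]]]], pa[-1L]); pl
        }
        ref(pp, path)
      }
      num <- (lossfn(bump(eps)) - lossfn(bump(-eps))) / (2 * eps)
      expect_equal(garr[i], num, tolerance = 1e-4)
    }
  }
})

test_that("forward passes are deterministic and encoder weights are shared", {
  fx <- tiny_trained_model()
  p <- fx$pairs[fx$test_idx[1:5]]
  expect_identical(predict(fx$model, p), predict(fx$model, p))

  # one parameter set encodes both sides: the model object holds a single
  # encoder (no alpha-/beta-specific weights exist to diverge)
  expect_named(fx$model$params, c("E", "conv", "attn", "head"))
  # and a self-pair scores near zero once swap augmentation has taught the
  # head the log-ratio's antisymmetry
  pr <- mkpair("GAVKLY", "GAVKLY", site_a = 4L, site_b = 4L)
  expect_lt(abs(predict(fx$model, list(pr))), 0.2)
})

test_that("seeded training is reproducible", {
  cfg <- generative_config(seed = 31L, n_pairs = 30L, csms_per_pair = 1L)
  set.seed(cfg$seed)
  pairs <- replicate(30, sample_pair(cfg), simplify = FALSE)
  y <- vapply(pairs, true_ratio, 0, cfg = cfg)
  mc <- model_config(seed = 4L, epochs = 2L)
  m1 <- ratio_model(pairs, y, mc)
  m2 <- ratio_model(pairs, y, mc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("training on constant labels converges to that constant", {
  cfg <- generative_config(seed = 32L, n_pairs = 40L, csms_per_pair = 1L)
  set.seed(cfg$seed)
  pairs <- replicate(40, sample_pair(cfg), simplify = FALSE)
  m <- ratio_model(pairs, rep(0.7, 40),
                   model_config(seed = 2L, epochs = 25L, batch_size = 8L,
                                lr = 5e-3, swap_augmentation = FALSE))
  expect_lt(mean(abs(predict(m, pairs) - 0.7)), 0.1)
})

test_that("swap-trained models are approximately antisymmetric", {
  fx <- tiny_trained_model()
  te <- fx$pairs[fx$test_idx]
  pred <- predict(fx$model, te)
  pred_sw <- predict(fx$model, lapply(te, swap_pair))
  expect_gt(cor(pred, -pred_sw), 0.9)
  expect_lt(median(abs(pred + pred_sw)), 0.2)
})

test_that("the fitted model recovers the additive rule on held-out pairs", {
  fx <- tiny_trained_model()
  met <- regression_metrics(fx$y[fx$test_idx],
                            predict(fx$model, fx$pairs[fx$test_idx]))
  expect_gt(met$pearson, 0.75)
  hist <- fx$model$history
  expect_lt(mean(tail(hist, 3)), mean(head(hist, 3)))
})

test_that("regression metrics match hand-computed cases", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(rmse = 0, mae = 0, pearson = 1, spearman = 1))
  m2 <- regression_metrics(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(m2$pearson, -1)
  m3 <- regression_metrics(c(0, 1, 2), c(0, 2, 1))
  expect_equal(m3$rmse, sqrt(2 / 3))
  expect_equal(m3$mae, 2 / 3)
  expect_equal(m3$spearman, 0.5)
  expect_warning(m4 <- regression_metrics(c(1, 2), c(5, 5)), "constant")
  expect_true(is.na(m4$pearson))
})

test_that("cross-validation partitions pairs into balanced reproducible folds", {
  cfg <- generative_config(seed = 33L, n_pairs = 100L, csms_per_pair = 1L)
  set.seed(cfg$seed)
  pairs <- replicate(100, sample_pair(cfg), simplify = FALSE)
  y <- vapply(pairs, true_ratio, 0, cfg = cfg)
  mc <- model_config(seed = 6L, epochs = 2L)
  cv <- crossvalidate(pairs, y, k = 5L, config = mc)
  expect_equal(unname(table(cv$assignment)), rep(20L, 5L),
               ignore_attr = TRUE)
  expect_equal(sort(unique(cv$assignment)), 1:5)
  expect_equal(nrow(cv$folds), 5L)
  expect_true(all(is.finite(cv$folds$rmse)))
  cv2 <- crossvalidate(pairs, y, k = 5L, config = mc)
  expect_identical(cv$assignment, cv2$assignment)
  expect_error(crossvalidate(pairs[1:3], y[1:3], k = 5L, config = mc),
               "exceeds")
})

test_that("fine-tuning splits pairs without leakage and adapts to a shifted domain", {
  fx <- tiny_trained_model()
  # shifted domain: same generator seedable config, perturbed weights
  w2 <- fx$cfg$residue_weights + setNames(rnorm(20, 0, 0.1) * 0 + 0.08 *
                                            sign(fx$cfg$residue_weights),
                                          names(fx$cfg$residue_weights))
  cfg2 <- generative_config(seed = 55L, n_pairs = 100L, csms_per_pair = 1L,
                            residue_weights = w2)
  set.seed(cfg2$seed)
  new_pairs <- replicate(100, sample_pair(cfg2), simplify = FALSE)
  new_y <- vapply(new_pairs, true_ratio, 0, cfg = cfg2)

  ft <- finetune(fx$model, new_pairs, new_y, fraction = 0.30,
                 epochs = 8L, seed = 2L)
  expect_length(intersect(ft$train_idx, ft$heldout_idx), 0L)
  expect_equal(sort(c(ft$train_idx, ft$heldout_idx)), 1:100)
  n_ft_pairs <- length(unique(vapply(new_pairs[ft$train_idx],
                                     xlratio:::pair_key, "")))
  expect_equal(n_ft_pairs, 30L)

  before <- mean(abs(new_y[ft$heldout_idx] -
                       predict(fx$model, new_pairs[ft$heldout_idx])))
  after <- mean(abs(new_y[ft$heldout_idx] -
                      predict(ft$model, new_pairs[ft$heldout_idx])))
  expect_lt(after, before)

  # near-zero fraction still fine-tunes on a single pair
  ft1 <- finetune(fx$model, new_pairs, new_y, fraction = 0.005,
                  epochs = 1L, seed = 2L)
  expect_gte(length(ft1$train_idx), 1L)
})

test_that("the length-ratio baseline fits its own feature and flags degeneracy", {
  cfg <- generative_config(seed = 35L, n_pairs = 60L, csms_per_pair = 1L)
  set.seed(cfg$seed)
  pairs <- replicate(60, sample_pair(cfg), simplify = FALSE)
  y_len <- vapply(pairs, function(p)
    log2(nchar(p$alpha$sequence) / nchar(p$beta$sequence)), 0)
  bl <- baseline_length_ratio(pairs, 2 * y_len + 0.3)
  expect_false(bl$degenerate)
  expect_equal(cor(predict(bl, pairs), 2 * y_len + 0.3), 1,
               tolerance = 1e-9)

  cfg5 <- generative_config(seed = 36L, length_range = c(6L, 6L))
  set.seed(cfg5$seed)
  eq_pairs <- replicate(10, sample_pair(cfg5), simplify = FALSE)
  bl2 <- baseline_length_ratio(eq_pairs, rnorm(10))
  expect_true(bl2$degenerate)
  expect_equal(sd(predict(bl2, eq_pairs)), 0)
})

test_that("random mismatch reproduces the empirical label distribution", {
  expect_length(random_mismatch(c(1, 2, 3), 0L), 0L)
  set.seed(1)
  labels <- rnorm(500)
  d1 <- random_mismatch(labels, 100L, seed = 7L)
  d2 <- random_mismatch(labels, 100L, seed = 7L)
  expect_identical(d1, d2)
  expect_true(all(d1 %in% labels))
  big <- random_mismatch(labels, 1e5, seed = 8L)
  ks <- suppressWarnings(ks.test(big, ecdf(labels))$statistic)
  expect_lt(unname(ks), 0.01)
})

test_that("model checkpoints save and load losslessly", {
  fx <- tiny_trained_model()
  path <- tempfile(fileext = ".rds")
  save_model(fx$model, path)
  m2 <- load_model(path)
  p <- fx$pairs[fx$test_idx[1:5]]
  expect_identical(predict(m2, p), predict(fx$model, p))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), bad)
  expect_error(load_model(bad), "checkpoint")
})
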