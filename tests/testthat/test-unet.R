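test_that("checkpoint selection is the argmin of recorded test loss", {
  # fabricated 160-epoch curve with its unique minimum at epoch 69
  loss <- 0.5 + 0.3 * cos(seq(0, 3, length.out = 160)) +
    seq(0, 0.4, length.out = 160)
  loss[69] <- min(loss) - 0.01
  curve <- data.frame(epoch = 1:160, test_loss = loss)
  expect_identical(select_checkpoint(curve), 69L)
  # ties resolve to the first argmin
  expect_identical(select_checkpoint(data.frame(test_loss = c(2, 1, 1))), 2L)
  expect_error(select_checkpoint(data.frame(loss = 1)), "test_loss")
})

test_that("spec and config constructors validate their invariants", {
  expect_error(unet_spec(depth = 1), "depth")
  expect_error(unet_spec(base_channels = 2), "base_channels")
  expect_error(train_config(train_fraction = 1), "train_fraction")
  expect_error(train_config(batch_size = 0), ">= 1")
  expect_error(train_striosome_unet(separable_cohort(),
                                    unet_spec(depth = 3),
                                    train_config(tile_size = 50L)),
               "divisible")
})

test_that("analytic gradients match finite differences", {
  spec <- list(depth = 2L, base_channels = 4L, n_classes = 2L,
               residual_blocks = TRUE)
  shapes <- unet_shapes_cpp(spec)
  set.seed(12)
  w <- list(W = lapply(shapes, function(s) {
    rows <- s[["k"]]^2 * s[["cin"]]
    matrix(rnorm(rows * s[["cout"]], sd = sqrt(2 / rows)), rows, s[["cout"]])
  }), b = lapply(shapes, function(s) rnorm(s[["cout"]], sd = 0.01)))
  x <- matrix(runif(64, 0, 255), 8, 8)
  y <- matrix(as.integer(runif(64) < 0.3), 8, 8)
  g <- unet_lossgrad_cpp(x, y, spec, w, 255)
  eps <- 1e-3
  for (li in c(1, 2, length(w$W))) {
    idx <- order(-abs(g$grad_W[[li]]))[1:3]   # check the largest entries
    for (i in idx) {
      wp <- w; wp$W[[li]][i] <- wp$W[[li]][i] + eps
      wm <- w; wm$W[[li]][i] <- wm$W[[li]][i] - eps
      fd <- (unet_lossgrad_cpp(x, y, spec, wp, 255)$loss -
               unet_lossgrad_cpp(x, y, spec, wm, 255)$loss) / (2 * eps)
      expect_equal(g$grad_W[[li]][i], fd, tolerance = 5e-3)
    }
  }
})

test_that("training is reproducible for identical seeds", {
  co <- separable_cohort()[1:6]
  cfg <- train_config(batch_size = 4L, total_epochs = 2L, tile_size = 96L,
                      train_fraction = 0.7, seed = 9L)
  m1 <- train_striosome_unet(co, unet_spec(depth = 2L, base_channels = 4L),
                             cfg)
  m2 <- train_striosome_unet(co, unet_spec(depth = 2L, base_channels = 4L),
                             cfg)
  expect_identical(m1$curve, m2$curve)
  expect_identical(m1$weights, m2$weights)
})

test_that("the trained model approaches the Otsu oracle on separable data", {
  model <- small_model()
  co <- separable_cohort()
  ev <- evaluate_model(model, co)
  expect_gte(ev$macro$dice, 0.95)
  # Otsu oracle on the same held-out sections
  for (i in model$test_sections[1]) {
    rec <- co[[i]]
    sm <- rec$labels == 1L | rec$labels == 2L
    draft <- otsu_preannotate(rec$section$reference, tissue = sm)
    pred <- predict_striosomes(model, rec$section, tissue = sm)
    agree <- segmentation_score(confusion_counts(pred$labels, draft,
                                                 region = sm))
    expect_gte(agree$dice, 0.95)
  }
})

test_that("held-out accuracy is nondecreasing in training-set size", {
  co <- separable_cohort()
  spec <- unet_spec(depth = 3L, base_channels = 8L)
  accs <- vapply(c(6L, 12L, 23L), function(n) {
    cfg <- train_config(batch_size = 8L, total_epochs = 6L, tile_size = 96L,
                        train_fraction = n / (n + 1), seed = 5L)
    m <- train_striosome_unet(co[seq_len(n + 1)], spec, cfg)
    m$curve$test_accuracy[m$selected_epoch]
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.005))
})

test_that("binarization sends probability 0.5 ties to striosome", {
  prob <- matrix(c(0.4, 0.5, 0.6, 0.5), 2, 2)
  lab <- binarize_probability(prob)
  expect_identical(as.vector(unclass(lab)), c(1L, 2L, 2L, 2L))
  # all-probability-one map becomes an all-striosome mask
  expect_true(all(binarize_probability(matrix(1, 4, 4)) == 2L))
  # tissue restriction: outside pixels stay background
  tis <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  expect_identical(as.vector(unclass(binarize_probability(prob, tis))),
                   c(1L, 0L, 2L, 2L))
})

test_that("tiled inference stitches consistently across tile sizes", {
  model <- small_model()
  rec <- separable_cohort()[[model$test_sections[1]]]
  p1 <- predict_striosomes(model, rec$section, tile_size = 96L)
  p2 <- predict_striosomes(model, rec$section, tile_size = 48L)
  # identical away from the 48-px tile seams (margin 2^(depth-1) = 4 px)
  H <- nrow(p1$prob); W <- ncol(p1$prob)
  seam_r <- unlist(lapply(seq(48, H - 1, by = 48), function(s) (s - 3):(s + 4)))
  seam_c <- unlist(lapply(seq(48, W - 1, by = 48), function(s) (s - 3):(s + 4)))
  interior <- matrix(TRUE, H, W)
  interior[seam_r, ] <- FALSE
  interior[, seam_c] <- FALSE
  agree <- mean(abs(p1$prob[interior] - p2$prob[interior]) < 0.05)
  expect_gte(agree, 0.99)
  # and the binary masks agree nearly everywhere
  sc <- segmentation_score(confusion_counts(p2$labels, p1$labels))
  expect_gte(sc$dice, 0.97)
})

test_that("section-size mismatch with the depth contract errors", {
  model <- small_model()
  expect_error(unet_predict_cpp(matrix(0, 50, 50), unclass(model$spec),
                                model$weights, 255), "divisible")
})
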