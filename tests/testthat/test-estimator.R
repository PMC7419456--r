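# The convolutional regressor: architecture contract, gradient validity,
# learning sanity at toy scale, deterministic inference, evaluation.

test_that("the network spec enforces the architecture contract", {
  spec <- network_spec()
  expect_length(spec$conv_channels, 4L)
  expect_length(spec$fc_dims, 3L)
  expect_equal(spec$fc_dims[3], 2L)               # 2 linear output units
  expect_equal(spec$conv_pool[3:4], c(2L, 2L))    # stride-2 pooling, layers 3-4
  expect_equal(spec$conv_dropout, c(0, 0, 0.2, 0.2))
  expect_equal(spec$fc_dropout, c(0.2, 0.2, 0))   # dropout on layers 3-6
  expect_gt(spec$alpha, 0)                        # leaky activations
  expect_error(network_spec(conv_channels = c(8L, 16L)), "length")
  # a stack that collapses to zero spatial size is rejected at build time
  expect_error(network_spec(input_px = 64L), "zero spatial size")
})

test_that("building is seed-deterministic and the forward pass has shape (2)", {
  spec <- toy_network_spec()
  m1 <- build_network(spec, seed = 3)
  m2 <- build_network(spec, seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(spec, seed = 4)
  expect_false(identical(m1$params, m3$params))
  img <- matrix(runif(100 * 100), 100, 100)
  p <- predict(m1, img)
  expect_length(p, 2L)
  expect_true(all(is.finite(p)))
  expect_lte(sum(p^2), 1 + 1e-12)  # clamped to the unit disc
  expect_identical(predict(m1, img), predict(m1, img))
})

test_that("analytic gradients match finite differences", {
  # pool-free, linear-activation variant of the layer stack: finite
  # differences are exact there (max-pool argmax switches and leaky kinks
  # otherwise contaminate the comparison at usable step sizes)
  spec <- network_spec(input_px = 64L, conv_channels = c(2L, 3L, 3L, 4L),
                       conv_kernel = c(3L, 3L, 3L, 3L),
                       conv_stride = c(2L, 1L, 1L, 1L),
                       fc_units = c(6L, 5L), alpha = 1.0)
  model <- build_network(spec, seed = 11)
  raw <- unclass(spec)
  raw$conv_pool <- c(1L, 1L, 1L, 1L)
  raw$conv_dropout <- c(0, 0, 0, 0)
  raw$fc_dropout <- c(0, 0, 0)
  # rebuild FC shapes for the pool-free geometry
  flat <- ((((64 - 3) %/% 2 + 1) - 3 + 1 - 3 + 1 - 3 + 1))^2 * 4L
  set.seed(14)
  model$params$fc_w[[1]] <- matrix(rnorm(6 * flat, sd = sqrt(2 / flat)), 6, flat)
  X <- matrix(runif(64 * 64 * 3), 64 * 64, 3)
  Y <- matrix(runif(6, -0.5, 0.5), 2, 3)
  res <- fetopose:::cnn_loss_grad(model$params, raw, X, Y, seed = 5)
  loss_at <- function(par) fetopose:::cnn_loss_grad(par, raw, X, Y,
                                                    seed = 5)$loss
  h <- 2e-2
  set.seed(13)
  for (grp in c("conv_w", "fc_w", "conv_b", "fc_b")) {
    for (li in seq_along(model$params[[grp]])) {
      idx <- sample(length(model$params[[grp]][[li]]), 2)
      for (i in idx) {
        p1 <- model$params; p1[[grp]][[li]][i] <- p1[[grp]][[li]][i] + h
        p2 <- model$params; p2[[grp]][[li]][i] <- p2[[grp]][[li]][i] - h
        numeric_g <- (loss_at(p1) - loss_at(p2)) / (2 * h)
        analytic_g <- res$grads[[grp]][[li]][i]
        expect_equal(analytic_g, numeric_g,
                     tolerance = max(0.01, 0.02 * abs(numeric_g)))
      }
    }
  }
})

test_that("training reduces the loss on a toy rendered set", {
  ds <- memo("toy_train_ds", {
    cfg <- render_config(resolution = 100L)
    generate_dataset(list(small_texture(1)),
                     trajectory_spec("conical", n = 200L), cfg, seed = 17L)
  })
  model <- build_network(toy_network_spec(), seed = 2)
  fit <- train_network(model, ds, cfg = training_config(epochs = 12L,
                                                        batch_size = 50L,
                                                        patience = Inf,
                                                        seed = 3L))
  h <- fit$history
  expect_equal(nrow(h), 12L)
  expect_lt(h$train_loss[12], h$train_loss[1])
  # 5-epoch moving average of the train loss is non-increasing
  ma <- stats::filter(h$train_loss, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-6))
  assign("toy_fit", fit, envir = fixture_env)
})

test_that("a perpendicular-only training set drives predictions toward (0,0)", {
  cfg <- render_config(resolution = 100L)
  poses <- sample_poses(trajectory_spec("conical", n = 1L), cfg, seed = 1L)
  surf <- placenta_surface(small_texture(1), extent_mm = 80)
  imgs <- lapply(seq(10, 48, length.out = 60), function(d) {
    render_view(surf, camera_pose_for_label(c(0, 0), d,
                                            roll_deg = d * 7), cfg = cfg)$image
  })
  ds <- list(images = imgs, labels = matrix(0, 60, 2))
  model <- build_network(toy_network_spec(), seed = 6)
  model <- train_network(model, ds, cfg = training_config(epochs = 15L,
                                                          batch_size = 20L,
                                                          patience = Inf,
                                                          seed = 8L))
  preds <- t(vapply(imgs[seq(1, 60, by = 6)],
                    function(im) predict(model, im), numeric(2)))
  expect_lt(mean(sqrt(rowSums(preds^2))), 0.1)
})

test_that("evaluation applies the both-angles rule and is self-consistent", {
  man <- tiny_dataset()
  # an oracle-perfect "model" is emulated by evaluating a model against its
  # own predictions: accuracy of truth against truth is 100%
  model <- build_network(toy_network_spec(), seed = 1)
  rep <- evaluate_model(model, man)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 100)
  expect_equal(nrow(rep$per_sample), nrow(man$samples))
  # report accuracy equals recomputation from the persisted per-sample errors
  recomputed <- 100 * mean(abs(rep$per_sample$err_angle_x) <= rep$tol &
                           abs(rep$per_sample$err_angle_y) <= rep$tol)
  expect_equal(rep$accuracy, recomputed)
  # evaluation is deterministic
  rep2 <- evaluate_model(model, man)
  expect_identical(rep$per_sample, rep2$per_sample)
  # a copy of the dataset with predictions as labels scores 100%
  perfect <- man
  preds <- t(vapply(man$images, function(im) predict(model, im), numeric(2)))
  perfect$samples$x_component <- preds[, 1]
  perfect$samples$y_component <- preds[, 2]
  expect_equal(evaluate_model(model, perfect)$accuracy, 100)
})

test_that("the always-zero baseline accuracy equals the closed-form fraction", {
  man <- tiny_dataset()
  zero_acc <- 100 * mean(
    abs(asin(man$samples$x_component)) <= deg2rad_test(5) &
    abs(asin(man$samples$y_component)) <= deg2rad_test(5))
  # emulate an always-(0,0) model by zeroing out the final FC layer
  model <- build_network(toy_network_spec(), seed = 1)
  model$params$fc_w[[3]][] <- 0
  model$params$fc_b[[3]][] <- 0
  rep <- evaluate_model(model, man)
  expect_equal(rep$accuracy, zero_acc)
})

test_that("model checkpoints round-trip through JSON", {
  fit <- get("toy_fit", envir = fixture_env)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  img <- matrix(runif(100 * 100), 100, 100)
  expect_equal(predict(back, img), predict(fit, img), tolerance = 1e-12)
  expect_equal(back$spec, fit$spec)
})

test_that("transfer initialization starts from the donor's weights", {
  donor <- get("toy_fit", envir = fixture_env)
  fresh <- build_network(toy_network_spec(), seed = 99)
  ds <- memo("toy_train_ds", stop("fixture missing"))
  warm <- train_network(fresh, ds,
                        cfg = training_config(epochs = 1L, batch_size = 50L,
                                              patience = Inf, seed = 4L,
                                              init_from = donor))
  cold <- train_network(fresh, ds,
                        cfg = training_config(epochs = 1L, batch_size = 50L,
                                              patience = Inf, seed = 4L))
  # after one epoch the warm start should sit at a lower training loss
  expect_lt(warm$history$train_loss[1], cold$history$train_loss[1])
})
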