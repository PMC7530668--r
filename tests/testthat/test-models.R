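# a tiny architecture reused for training-mechanics tests: same layer
# types as the full nets, scaled inputs so each test runs in seconds
tiny_dig_spec <- function() {
  s <- cnn_dig_spec(n_blocks_short = 2L, n_blocks_long = 2L, kernel = 5L,
                    base_channels = 3L, cap_channels = 4L, dropout = 0,
                    fc_width = 6L)
  s$input_short <- c(40L, 2L); s$input_long <- c(60L, 1L)
  s
}

# separable 2-class toy signals for the tiny spec: class 1 carries a
# strong low-frequency component in both branches
tiny_data <- function(n, seed) {
  ecgduo:::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    short <- array(rnorm(40 * 2 * n, 0, 0.3), c(40, 2, n))
    long <- array(rnorm(60 * 1 * n, 0, 0.3), c(60, 1, n))
    for (i in which(y == 1)) {
      short[, , i] <- short[, , i] + sin(seq_len(40) / 3)
      long[, 1, i] <- long[, 1, i] + sin(seq_len(60) / 4)
    }
    list(x = list(short = short, long = long), y = y)
  })
}

test_that("CNN-dig introspection matches its architecture contract", {
  m <- build_cnn_dig()
  d <- describe_model(m)
  expect_identical(sum(d$branch == "short"), 6L)
  expect_identical(sum(d$branch == "long"), 8L)
  expect_true(all(d$kernel == "17"))
  expect_true(all(d$stride == 2L))
  expect_true(all(d$dropout == 0.1))
})

test_that("CNN-ima introspection matches its architecture contract", {
  m <- build_cnn_ima()
  d <- describe_model(m)
  expect_identical(nrow(d), 7L)
  expect_true(all(d$kernel == "7x7"))
  expect_true(all(d$stride == 2L))
})

test_that("full-size forward passes run on CPU and give P in [0, 1]", {
  md <- build_cnn_dig(seed = 1)
  batch <- ecgduo:::with_seed(1, list(
    short = array(rnorm(1250 * 12 * 2), c(1250, 12, 2)),
    long = array(rnorm(5000 * 2), c(5000, 1, 2))))
  P <- predict(md, batch)
  expect_length(P, 2L)
  expect_true(all(P >= 0 & P <= 1))
  mi <- build_cnn_ima(seed = 1)
  img <- ecgduo:::with_seed(2, array(runif(675 * 1450 * 3) * 255,
                                     c(675, 1450, 3, 1)))
  Pi <- predict(mi, img)
  expect_length(Pi, 1L)
  expect_true(Pi >= 0 && Pi <= 1)
})

test_that("analytic gradients match numerical gradients", {
  m <- ecgduo:::build_cnn_dig(tiny_dig_spec(), seed = 3)
  td <- tiny_data(3, seed = 4)
  fw <- ecgduo:::forward_model(m, td$x, training = TRUE)
  glogit <- (ecgduo:::sigmoid(fw$logit) - td$y) / 3
  grads <- ecgduo:::backward_model(fw$model, fw$cache, glogit)
  params <- ecgduo:::collect_params(fw$model)
  loss_at <- function(pp) {
    f <- ecgduo:::forward_model(ecgduo:::restore_params(fw$model, pp), td$x,
                                training = TRUE)
    ecgduo:::bce_with_logits(f$logit, td$y)
  }
  set.seed(11)
  for (nm in c("short.1.w", "short.2.gamma", "long.2.beta", "fc.1.w", "fc.2.w")) {
    for (i in sample(length(params[[nm]]), 2L)) {
      eps <- 1e-5; pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss_at(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- loss_at(pp)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][i]),
                1e-6 * (1 + abs(num)))
    }
  }
})

test_that("batched prediction equals per-record prediction, empty in empty out", {
  m <- ecgduo:::build_cnn_dig(tiny_dig_spec(), seed = 5)
  td <- tiny_data(5, seed = 6)
  P_batch <- predict(m, td$x)
  P_single <- vapply(1:5, function(i) {
    predict(m, list(short = td$x$short[, , i, drop = FALSE],
                    long = td$x$long[, , i, drop = FALSE]))
  }, numeric(1))
  expect_equal(P_batch, P_single, tolerance = 1e-12)
  expect_identical(predict(m, list(short = td$x$short[, , 0, drop = FALSE],
                                   long = td$x$long[, , 0, drop = FALSE])),
                   numeric(0))
})

test_that("training is seed-deterministic and learns a separable toy task", {
  spec <- tiny_dig_spec()
  tr <- tiny_data(60, seed = 7); va <- tiny_data(20, seed = 8)
  cfg <- train_config(lr = 3e-3, batch_size = 20L, max_epochs = 5L,
                      patience = 5L)
  a <- train_model(ecgduo:::build_cnn_dig(spec), tr$x, tr$y, va$x, va$y, cfg,
                   seed = 9)
  b <- train_model(ecgduo:::build_cnn_dig(spec), tr$x, tr$y, va$x, va$y, cfg,
                   seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(ecgduo:::collect_params(a$model),
                   ecgduo:::collect_params(b$model))
  # loss decreases over the first epochs on separable data
  expect_lt(a$history$train_loss[3], a$history$train_loss[1])
  expect_identical(nrow(a$history), 5L)
})

test_that("early stopping waits `patience` epochs and keeps the best checkpoint", {
  spec <- tiny_dig_spec()
  tr <- tiny_data(40, seed = 10); va <- tiny_data(16, seed = 12)
  # learning rate 0: validation loss is exactly constant across epochs,
  # so with patience 1 training stops after epoch 2
  cfg0 <- train_config(lr = 0, batch_size = 20L, max_epochs = 50L,
                       patience = 1L)
  frozen <- train_model(ecgduo:::build_cnn_dig(spec), tr$x, tr$y, va$x, va$y,
                        cfg0, seed = 13)
  expect_identical(nrow(frozen$history), 2L)
  expect_identical(frozen$best_epoch, 1L)
  # best-checkpoint policy: returned parameters reproduce the minimum
  # validation loss, which is <= the final epoch's validation loss
  cfg <- train_config(lr = 5e-3, batch_size = 20L, max_epochs = 8L,
                      patience = 8L)
  tm <- train_model(ecgduo:::build_cnn_dig(spec), tr$x, tr$y, va$x, va$y, cfg,
                    seed = 14)
  expect_identical(tm$history$val_loss[tm$best_epoch], min(tm$history$val_loss))
  expect_lte(tm$history$val_loss[tm$best_epoch],
             tm$history$val_loss[nrow(tm$history)])
  restored <- ecgduo:::eval_loss(tm$model,
                                 ecgduo:::model_inputs(tm$model, va$x), va$y)
  expect_equal(restored, min(tm$history$val_loss), tolerance = 1e-10)
})

test_that("degenerate training inputs are rejected", {
  spec <- tiny_dig_spec()
  tr <- tiny_data(10, seed = 15); va <- tiny_data(4, seed = 16)
  expect_error(train_model(ecgduo:::build_cnn_dig(spec), tr$x, rep(1, 10),
                           va$x, va$y, train_config()), "both classes")
  expect_error(train_model(ecgduo:::build_cnn_dig(spec), tr$x, tr$y[1:5],
                           va$x, va$y, train_config()), "label length")
})

test_that("the disease panel trains independent per-condition models", {
  recs <- generate_cohort(8, class_mix = c(AF = 0.5, Normal = 0.5),
                          duration_range = c(10, 10), seed = 17)
  ds <- dataset_from_records(standard_records_from_recordings(recs))
  spec <- cnn_dig_spec(base_channels = 2, cap_channels = 2, fc_width = 4L)
  cfg <- train_config(lr = 1e-3, batch_size = 16L, max_epochs = 1L,
                      patience = 1L)
  panel <- train_disease_panel(ds, ds, diseases = c("AF", "Normal"),
                               config = cfg, spec = spec, seed = 18)
  expect_named(panel, c("AF", "Normal"))
  expect_false(identical(ecgduo:::collect_params(panel$AF$model),
                         ecgduo:::collect_params(panel$Normal$model)))
  pm <- predict_panel(panel, ds)
  expect_identical(dim(pm), c(ds$n, 9L))
  expect_true(all(pm[, c("AF", "Normal")] >= 0 & pm[, c("AF", "Normal")] <= 1))
  expect_true(all(is.na(pm[, "PVC"])))
  expect_error(train_disease_panel(ds, ds, diseases = "NotADisease",
                                   config = cfg, spec = spec), "unknown")
  expect_error(train_disease_panel(ds, ds, diseases = character(0)), "at least one")
})
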