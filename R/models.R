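# Per-condition binary classifiers.
#
# CNN-dig: dual-branch temporal network on digital signals — 6 stacked
# conv blocks (kernel 17, stride 2) over the 12 x 1250 short block, 8
# over the 1 x 5000 long lead, features flattened, concatenated and fed
# to a fully connected head with a sigmoid scalar output P in [0, 1].
# CNN-ima: 7 stacked 2-D conv blocks (kernel 7 x 7, stride 2) over the
# [675, 1450, 3] plot image, then the same head. Each conv block is
# convolution -> batch normalization -> ReLU -> dropout. One model is
# trained per condition, so a panel of models yields 9 independent
# probabilities per record (no softmax coupling).

conv_widths <- function(base, n, cap) pmin(base * 2^(seq_len(n) - 1L), cap)

#' Architecture specification for CNN-dig
#'
#' @param n_blocks_short,n_blocks_long Conv block depths of the
#'   short-lead and long-lead branches (defaults 6 and 8).
#' @param kernel Temporal kernel length (default 17).
#' @param stride Convolution stride (fixed default 2).
#' @param base_channels,cap_channels Channel widths double from
#'   `base_channels` per block, capped at `cap_channels`.
#' @param dropout Dropout probability per block (default 0.1).
#' @param fc_width Width of the fully connected hidden layer.
#' @return A `cnn_dig_spec`.
#' @export
cnn_dig_spec <- function(n_blocks_short = 6L, n_blocks_long = 8L, kernel = 17L,
                         stride = 2L, base_channels = 16L, cap_channels = 256L,
                         dropout = 0.1, fc_width = 64L) {
  structure(list(n_blocks_short = as.integer(n_blocks_short),
                 n_blocks_long = as.integer(n_blocks_long),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 base_channels = base_channels, cap_channels = cap_channels,
                 dropout = dropout, fc_width = as.integer(fc_width),
                 input_short = c(WIN_SAMPLES, 12L),
                 input_long = c(SEG_SAMPLES, 1L)),
            class = "cnn_dig_spec")
}

#' Architecture specification for CNN-ima
#'
#' @param n_blocks Conv block depth (default 7).
#' @param kernel 2-D kernel size (default c(7, 7)).
#' @param input_shape Image input shape (default c(675, 1450, 3)).
#' @inheritParams cnn_dig_spec
#' @return A `cnn_ima_spec`.
#' @export
cnn_ima_spec <- function(n_blocks = 7L, kernel = c(7L, 7L), stride = 2L,
                         base_channels = 16L, cap_channels = 256L,
                         dropout = 0.1, fc_width = 64L,
                         input_shape = c(675L, 1450L, 3L)) {
  structure(list(n_blocks = as.integer(n_blocks), kernel = as.integer(kernel),
                 stride = as.integer(stride), base_channels = base_channels,
                 cap_channels = cap_channels, dropout = dropout,
                 fc_width = as.integer(fc_width),
                 input_shape = as.integer(input_shape)),
            class = "cnn_ima_spec")
}

conv_out_len <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

#' Build an untrained CNN-dig model
#'
#' @param spec A [cnn_dig_spec()].
#' @param seed Seed for the initial parameter draw (training re-draws
#'   parameters under its own seed).
#' @return An `ecg_model` of type "dig".
#' @export
build_cnn_dig <- function(spec = cnn_dig_spec(), seed = 1L) {
  ws <- conv_widths(spec$base_channels, spec$n_blocks_short, spec$cap_channels)
  wl <- conv_widths(spec$base_channels, spec$n_blocks_long, spec$cap_channels)
  short <- list(); long <- list()
  cin <- spec$input_short[2]; len <- spec$input_short[1]
  for (i in seq_len(spec$n_blocks_short)) {
    short[[i]] <- new_conv_layer("conv1d", spec$kernel, cin, ws[i],
                                 spec$stride, spec$dropout)
    len <- conv_out_len(len, spec$kernel, spec$stride, short[[i]]$pad)
    cin <- ws[i]
  }
  feat_short <- len * cin
  cin <- spec$input_long[2]; len <- spec$input_long[1]
  for (i in seq_len(spec$n_blocks_long)) {
    long[[i]] <- new_conv_layer("conv1d", spec$kernel, cin, wl[i],
                                spec$stride, spec$dropout)
    len <- conv_out_len(len, spec$kernel, spec$stride, long[[i]]$pad)
    cin <- wl[i]
  }
  feat_long <- len * cin
  fc <- list(new_dense_layer(feat_short + feat_long, spec$fc_width, "relu"),
             new_dense_layer(spec$fc_width, 1L, "linear"))
  model <- structure(list(type = "dig", spec = spec,
                          parts = c("short", "long", "fc"),
                          short = short, long = long, fc = fc,
                          feat_short = feat_short, feat_long = feat_long),
                     class = "ecg_model")
  init_model(model, seed)
}

#' Build an untrained CNN-ima model
#'
#' @param spec A [cnn_ima_spec()].
#' @param seed Seed for the initial parameter draw.
#' @return An `ecg_model` of type "ima".
#' @export
build_cnn_ima <- function(spec = cnn_ima_spec(), seed = 1L) {
  wc <- conv_widths(spec$base_channels, spec$n_blocks, spec$cap_channels)
  conv <- list()
  cin <- spec$input_shape[3]
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  for (i in seq_len(spec$n_blocks)) {
    conv[[i]] <- new_conv_layer("conv2d", spec$kernel, cin, wc[i],
                                spec$stride, spec$dropout)
    h <- conv_out_len(h, spec$kernel[1], spec$stride, conv[[i]]$pad)
    w <- conv_out_len(w, spec$kernel[2], spec$stride, conv[[i]]$pad)
    if (h < 1L || w < 1L) stopf("input too small for %d conv blocks", spec$n_blocks)
    cin <- wc[i]
  }
  feat <- h * w * cin
  fc <- list(new_dense_layer(feat, spec$fc_width, "relu"),
             new_dense_layer(spec$fc_width, 1L, "linear"))
  model <- structure(list(type = "ima", spec = spec, parts = c("conv", "fc"),
                          conv = conv, fc = fc, feat = feat),
                     class = "ecg_model")
  init_model(model, seed)
}

init_model <- function(model, seed) {
  with_seed(seed, {
    for (part in model$parts)
      for (i in seq_along(model[[part]]))
        model[[part]][[i]] <- init_layer(model[[part]][[i]])
  })
  model
}

#' Describe a model's convolution blocks
#'
#' Introspection table: one row per convolution block with its branch,
#' kernel size, stride, output channels and dropout.
#'
#' @param model An `ecg_model` or `trained_ecg_model`.
#' @return data.frame.
#' @export
describe_model <- function(model) {
  if (inherits(model, "trained_ecg_model")) model <- model$model
  rows <- list()
  for (part in setdiff(model$parts, "fc")) {
    for (i in seq_along(model[[part]])) {
      ly <- model[[part]][[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        branch = part, block = i, kind = ly$kind,
        kernel = paste(ly$k, collapse = "x"), stride = ly$stride,
        channels_out = ly$cout, dropout = ly$dropout)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.ecg_model <- function(x, ...) {
  d <- describe_model(x)
  cat(sprintf("<ecg_model> CNN-%s: %d conv blocks (%s), fc width %d\n",
              x$type, nrow(d), paste(unique(d$kernel), collapse = "/"),
              x$spec$fc_width))
  invisible(x)
}

# ---- forward / backward -------------------------------------------------

forward_model <- function(model, batch, training = FALSE) {
  if (model$type == "dig") {
    rs <- branch_fw(model$short, batch$short, training, 2L)
    rl <- branch_fw(model$long, batch$long, training, 2L)
    if (training) { model$short <- rs$layers; model$long <- rl$layers }
    fs <- flatten_maps(rs$out); fl <- flatten_maps(rl$out)
    f <- cbind(fs, fl)
    d1 <- dense_fw(model$fc[[1]], f, training)
    d2 <- dense_fw(model$fc[[2]], d1$out, training)
    list(logit = d2$out[, 1], model = model,
         cache = list(rs = rs, rl = rl, d1 = d1, d2 = d2,
                      dim_s = dim(rs$out), dim_l = dim(rl$out)))
  } else {
    x <- batch$x / 255 - 0.5
    rc <- branch_fw(model$conv, x, training, 3L)
    if (training) model$conv <- rc$layers
    f <- flatten_maps(rc$out)
    d1 <- dense_fw(model$fc[[1]], f, training)
    d2 <- dense_fw(model$fc[[2]], d1$out, training)
    list(logit = d2$out[, 1], model = model,
         cache = list(rc = rc, d1 = d1, d2 = d2, dim_c = dim(rc$out)))
  }
}

backward_model <- function(model, cache, glogit) {
  g <- matrix(glogit, ncol = 1L)
  b2 <- dense_bw(model$fc[[2]], cache$d2$cache, g)
  b1 <- dense_bw(model$fc[[1]], cache$d1$cache, b2$gx)
  grads <- list()
  grads[["fc.2.w"]] <- b2$grads$w; grads[["fc.2.b"]] <- b2$grads$b
  grads[["fc.1.w"]] <- b1$grads$w; grads[["fc.1.b"]] <- b1$grads$b
  add_branch <- function(grads, prefix, glist) {
    for (i in seq_along(glist))
      for (nm in names(glist[[i]]))
        grads[[paste0(prefix, i, ".", nm)]] <- glist[[i]][[nm]]
    grads
  }
  if (model$type == "dig") {
    ns <- prod(cache$dim_s[-3]); gf <- b1$gx
    gs <- unflatten_maps(gf[, seq_len(ns), drop = FALSE], cache$dim_s)
    gl <- unflatten_maps(gf[, -seq_len(ns), drop = FALSE], cache$dim_l)
    grads <- add_branch(grads, "short.",
                        branch_bw(model$short, cache$rs$caches, gs, 2L))
    grads <- add_branch(grads, "long.",
                        branch_bw(model$long, cache$rl$caches, gl, 2L))
  } else {
    gc_ <- unflatten_maps(b1$gx, cache$dim_c)
    grads <- add_branch(grads, "conv.",
                        branch_bw(model$conv, cache$rc$caches, gc_, 3L))
  }
  grads
}

# ---- input plumbing -----------------------------------------------------

dig_inputs <- function(data) {
  if (inherits(data, "ecg_dataset"))
    return(list(short = data$short,
                long = array(data$long, c(SEG_SAMPLES, 1L, data$n)),
                n = data$n))
  if (is.list(data) && !is.null(data$short) && !is.null(data$long)) {
    n <- dim(data$short)[3]
    long <- data$long
    if (length(dim(long)) == 2L) long <- array(long, c(SEG_SAMPLES, 1L, n))
    return(list(short = data$short, long = long, n = n))
  }
  if (is.list(data) && length(data) && inherits(data[[1]], "standard_record"))
    return(dig_inputs(dataset_from_records(data)))
  stopf("cannot interpret input for CNN-dig (need dataset or short/long arrays)")
}

ima_inputs <- function(data, input_shape) {
  if (is.list(data) && !is.list(data[[1]]) && !is.null(data$x)) data <- data$x
  if (is.list(data)) data <- simplify2array(lapply(data, unclass))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (!all(dim(data)[1:3] == input_shape))
    stopf("image batch shape %s does not match model input [%s]",
          paste(dim(data)[1:3], collapse = ","),
          paste(input_shape, collapse = ","))
  list(x = data, n = dim(data)[4])
}

slice_batch <- function(model, inputs, idx) {
  if (model$type == "dig")
    list(short = inputs$short[, , idx, drop = FALSE],
         long = inputs$long[, , idx, drop = FALSE])
  else list(x = inputs$x[, , , idx, drop = FALSE])
}

model_inputs <- function(model, data) {
  if (model$type == "dig") dig_inputs(data)
  else ima_inputs(data, model$spec$input_shape)
}

# ---- training -----------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the package's reference settings: Adam optimizer,
#' binary cross-entropy loss, learning rate 1e-4 (from the tested set
#' 1e-3..1e-6), batch size 256 for CNN-dig (150 for CNN-ima), at most
#' 100 epochs, early stopping on validation loss with patience 10 for
#' CNN-dig (5 for CNN-ima), keeping the best checkpoint by validation
#' loss.
#'
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping.
#' @param optimizer Only "adam" is implemented.
#' @param loss Only "bce" (binary cross-entropy) is implemented.
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 256L, max_epochs = 100L,
                         patience = 10L, optimizer = "adam", loss = "bce") {
  stopifnot(optimizer == "adam", loss == "bce")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 optimizer = optimizer, loss = loss),
            class = "train_config")
}

eval_loss <- function(model, inputs, y, batch_size = 64L) {
  n <- inputs$n; tot <- 0
  for (i0 in seq(1L, n, by = batch_size)) {
    idx <- i0:min(n, i0 + batch_size - 1L)
    fw <- forward_model(model, slice_batch(model, inputs, idx), training = FALSE)
    tot <- tot + bce_with_logits(fw$logit, y[idx]) * length(idx)
  }
  tot / n
}

#' Train a binary classifier on one target condition
#'
#' Minimizes binary cross-entropy with Adam; after every epoch the model
#' is evaluated on the validation set and the best checkpoint (lowest
#' validation loss) is kept. Training stops at `max_epochs` or once the
#' validation loss has failed to improve for `patience` consecutive
#' epochs. Deterministic given `seed` and fixed data order: the seed
#' drives parameter initialization, batch shuffling and dropout.
#'
#' @param model An untrained `ecg_model` from [build_cnn_dig()] or
#'   [build_cnn_ima()].
#' @param train_data,val_data Input data (an `ecg_dataset`, a
#'   short/long array pair, or an image array, matching the model type).
#' @param y_train,y_val Binary target vectors (1 = condition present);
#'   each set must contain both classes.
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @param disease Optional condition name recorded on the result.
#' @param verbose Print per-epoch losses.
#' @return A `trained_ecg_model`: list with the fitted `model`, the
#'   per-epoch `history` data.frame, `best_epoch`, `config`, `disease`.
#' @export
train_model <- function(model, train_data, y_train, val_data, y_val,
                        config = train_config(), seed = 1L, disease = NA_character_,
                        verbose = FALSE) {
  stopifnot(inherits(model, "ecg_model"))
  tin <- model_inputs(model, train_data)
  vin <- model_inputs(model, val_data)
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(y_train) != tin$n || length(y_val) != vin$n)
    stopf("label length does not match number of records")
  if (length(unique(y_train)) < 2L)
    stopf("training set must contain both classes")
  model <- init_model(model, child_seed(seed, 1L))
  state <- list(); t_step <- 0L
  best <- Inf; best_params <- NULL; best_bn <- NULL; best_epoch <- 0L
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    epoch_loss <- 0
    with_seed(child_seed(seed, 1000L + epoch), {
      idx_all <- sample(tin$n)
      for (i0 in seq(1L, tin$n, by = config$batch_size)) {
        idx <- idx_all[i0:min(tin$n, i0 + config$batch_size - 1L)]
        fw <- forward_model(model, slice_batch(model, tin, idx), training = TRUE)
        model <- fw$model
        z <- fw$logit; yb <- y_train[idx]
        loss <- bce_with_logits(z, yb)
        epoch_loss <- epoch_loss + loss * length(idx)
        glogit <- (sigmoid(z) - yb) / length(idx)
        grads <- backward_model(model, fw$cache, glogit)
        t_step <- t_step + 1L
        up <- adam_step(collect_params(model), grads, state, config$lr, t_step)
        state <- up$state
        model <- restore_params(model, up$params)
      }
    })
    train_loss <- epoch_loss / tin$n
    val_loss <- eval_loss(model, vin, y_val)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, train_loss,
                      val_loss))
    if (val_loss < best - 1e-12) {
      best <- val_loss; best_epoch <- epoch; wait <- 0L
      best_params <- collect_params(model); best_bn <- collect_bn_stats(model)
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (!is.null(best_params)) {
    model <- restore_params(model, best_params)
    model <- restore_bn_stats(model, best_bn)
  }
  structure(list(model = model, history = hist, best_epoch = best_epoch,
                 config = config, disease = disease, seed = seed),
            class = "trained_ecg_model")
}

#' @export
print.trained_ecg_model <- function(x, ...) {
  cat(sprintf("<trained_ecg_model> CNN-%s%s: %d epochs, best epoch %d (val loss %.4f)\n",
              x$model$type,
              if (is.na(x$disease)) "" else paste0(" [", x$disease, "]"),
              nrow(x$history), x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Predict condition probabilities
#'
#' Stateless batched inference; a batch of n records gives exactly the
#' same probabilities as n single-record calls.
#'
#' @param object A `trained_ecg_model` (or bare `ecg_model`).
#' @param newdata Input records (see [train_model()]).
#' @param batch_size Internal evaluation batch size.
#' @param ... Unused.
#' @return Numeric vector of probabilities P in \[0, 1\].
#' @export
predict.trained_ecg_model <- function(object, newdata, batch_size = 64L, ...) {
  predict(object$model, newdata, batch_size = batch_size, ...)
}

#' @rdname predict.trained_ecg_model
#' @export
predict.ecg_model <- function(object, newdata, batch_size = 64L, ...) {
  inputs <- model_inputs(object, newdata)
  if (inputs$n == 0L) return(numeric(0))
  out <- numeric(inputs$n)
  for (i0 in seq(1L, inputs$n, by = batch_size)) {
    idx <- i0:min(inputs$n, i0 + batch_size - 1L)
    fw <- forward_model(object, slice_batch(object, inputs, idx),
                        training = FALSE)
    out[idx] <- sigmoid(fw$logit)
  }
  out
}

#' Train one binary classifier per condition
#'
#' Independent models, one per requested condition, sharing the same
#' architecture spec; each model's targets are that condition's column
#' of the one-hot labels, so predictions over a record form a vector of
#' independent probabilities (multi-label capable).
#'
#' @param train_ds,val_ds `ecg_dataset`s (patient-disjoint).
#' @param diseases Character vector of conditions from [ECG_CLASSES].
#' @param config A [train_config()].
#' @param spec Architecture spec (default [cnn_dig_spec()]).
#' @param seed Integer seed (one substream per condition).
#' @return Named list of `trained_ecg_model`s.
#' @export
train_disease_panel <- function(train_ds, val_ds, diseases = ECG_CLASSES,
                                config = train_config(),
                                spec = cnn_dig_spec(), seed = 1L) {
  if (length(diseases) < 1L) stopf("need at least one disease")
  bad <- setdiff(diseases, ECG_CLASSES)
  if (length(bad)) stopf("unknown disease name(s): %s", paste(bad, collapse = ", "))
  models <- list()
  for (d in diseases) {
    di <- match(d, ECG_CLASSES)
    model <- build_cnn_dig(spec)
    models[[d]] <- train_model(model, train_ds, train_ds$labels[di, ],
                               val_ds, val_ds$labels[di, ], config,
                               seed = child_seed(seed, di), disease = d)
  }
  models
}

#' Panel predictions as a 9-column probability matrix
#'
#' @param models Named list from [train_disease_panel()] (names must be
#'   conditions).
#' @param newdata Input records.
#' @return Matrix \[n records x 9\] of probabilities; columns in
#'   [ECG_CLASSES] order are filled for modeled conditions and NA
#'   elsewhere.
#' @export
predict_panel <- function(models, newdata) {
  n <- model_inputs(models[[1]]$model, newdata)$n
  out <- matrix(NA_real_, n, 9L, dimnames = list(NULL, ECG_CLASSES))
  for (d in names(models)) out[, d] <- predict(models[[d]], newdata)
  out
}
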