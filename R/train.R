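# Training protocol: ratio-controlled mini-batches, SGD with a stepped
# learning-rate schedule, per-sample augmentation, and 3-fold cross-validated
# early stopping with folds split by tile.

#' Training configuration
#'
#' Defaults follow the reference protocol: SGD at learning rate 1e-3, decayed
#' by a factor of 10 every 10 epochs, at most 50 epochs, 3 cross-validation
#' folds, and class-ratio-controlled mini-batches. The mini-batch size
#' defaults to 32 for 64 px synthetic patches (128, the protocol's original
#' size, remains available). Momentum 0.9 is the optimiser's conventional
#' default.
#'
#' @param learning_rate initial SGD learning rate.
#' @param lr_decay_factor divide the rate by this ...
#' @param lr_decay_every ... every this many epochs.
#' @param momentum classical momentum coefficient.
#' @param batch_size mini-batch size (>= 2).
#' @param epochs number of training epochs (maximum when early stopping).
#' @param folds cross-validation folds for [early_stop_epoch()].
#' @param ratio fraction of the cancer class in every mini-batch, in (0, 1).
#' @param augment apply random translation/rotation augmentation per sample.
#' @param jitter_frac translation jitter as a fraction of the patch side.
#' @param rotations admissible rotations (degrees, multiples of 90).
#' @param seed master seed for sampling, augmentation and initialisation.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, lr_decay_factor = 10,
                         lr_decay_every = 10L, momentum = 0.9,
                         batch_size = 32L, epochs = 50L, folds = 3L,
                         ratio = 0.5, augment = TRUE, jitter_frac = 0.25,
                         rotations = c(0, 90, 180, 270), seed = 0L) {
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie in (0, 1)")
  if (batch_size < 2) stopf("batch_size must be >= 2")
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 ratio = ratio, augment = isTRUE(augment),
                 jitter_frac = jitter_frac, rotations = rotations,
                 seed = as.integer(seed)), class = "train_config")
}

#' Learning rate at a given epoch
#'
#' The rate is divided by `lr_decay_factor` every `lr_decay_every` epochs:
#' with the defaults, epochs 1-9 run at 1e-3, epoch 10 drops to 1e-4, epoch
#' 20 to 1e-5, and so on.
#'
#' @param config a [train_config()].
#' @param epoch epoch number (1-based).
#' @export
learning_rate_at <- function(config, epoch) {
  config$learning_rate / config$lr_decay_factor^(epoch %/% config$lr_decay_every)
}

#' Ratio-controlled mini-batch sampler
#'
#' Returns a sampler closure emitting index vectors in which every batch
#' holds exactly `round(ratio * batch_size)` cancer patches and the remainder
#' no-cancer patches. Each class is drawn from its own shuffled pool, which is
#' reshuffled and reused once exhausted, so the minority class is oversampled
#' with replacement across refills. Draws come from the current RNG stream.
#'
#' @param labels character vector of `"cancer"` / `"no_cancer"` labels.
#' @param ratio cancer fraction per batch, in (0, 1).
#' @param batch_size batch size.
#' @return A function `function()` returning `batch_size` indices into
#'   `labels`.
#' @export
compose_batches <- function(labels, ratio, batch_size) {
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie in (0, 1)")
  idx_can <- which(labels == "cancer")
  idx_no <- which(labels == "no_cancer")
  if (!length(idx_can) || !length(idx_no))
    stopf("both classes must be present in the dataset")
  n_can <- round(ratio * batch_size)
  n_no <- batch_size - n_can
  pools <- list(cancer = sample(idx_can), no_cancer = sample(idx_no))
  draw <- function(class, n, source) {
    out <- integer(0)
    while (n > 0) {
      pool <- pools[[class]]
      take <- min(n, length(pool))
      out <- c(out, pool[seq_len(take)])
      pool <- pool[-seq_len(take)]
      if (!length(pool)) pool <- sample(source)
      pools[[class]] <<- pool
      n <- n - take
    }
    out
  }
  function() {
    c(draw("cancer", n_can, idx_can), draw("no_cancer", n_no, idx_no))
  }
}

# Backward pass: gradient of mean softmax cross-entropy w.r.t. parameters.
# `fb` comes from forward_batch(..., keep = TRUE); y is the 1-based class
# index per sample. Returns list of per-layer gradients (NULL for
# parameter-free layers).
backward_batch <- function(net, fb, y) {
  b <- nrow(fb$scores)
  probs <- softmax_rows(fb$scores)
  dz <- probs
  dz[cbind(seq_len(b), y)] <- dz[cbind(seq_len(b), y)] - 1
  dz <- dz / b
  grads <- vector("list", length(net$layers))
  dy <- dz
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- fb$caches[[i]]
    x <- cache$input
    dy <- switch(l$kind,
      dense = {
        grads[[i]] <- list(weights = crossprod(x, dy), bias = colSums(dy))
        dy %*% t(l$weights)
      },
      global_avgpool = {
        d <- dim(x)
        array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
      },
      flatten = {
        d <- dim(x)
        aperm(array(t(dy), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      },
      relu = {
        da <- if (is.matrix(dy)) dy else array(dy, dim(x))
        da * (x > 0)
      },
      maxpool = {
        d <- dim(x)
        dx <- numeric(prod(d))
        win <- cbind(seq_along(cache$argmax), cache$argmax)
        # non-overlapping windows: winner indices are unique
        dx[cache$idx[win]] <- as.vector(dy)
        array(dx, d)
      },
      avgpool = {
        d <- dim(x)
        dx <- numeric(prod(d))
        dyv <- as.vector(dy) / (l$k * l$k)
        for (j in seq_len(ncol(cache$idx))) {
          ind <- cache$idx[, j]
          dx[ind] <- dx[ind] + dyv
        }
        array(dx, d)
      },
      conv = {
        dymat <- matrix(dy, ncol = l$out_ch)
        grads[[i]] <- list(wmat = crossprod(cache$xc, dymat),
                           bias = colSums(dymat))
        if (i == 1L) NULL else {   # input-layer gradient is never consumed
          d <- dim(x)
          dxc <- tcrossprod(dymat, l$wmat)
          dx <- numeric(prod(d))
          for (j in seq_len(ncol(cache$idx))) {
            ind <- cache$idx[, j]
            dx[ind] <- dx[ind] + dxc[, j]
          }
          array(dx, d)
        }
      },
      stopf("unknown layer kind '%s'", l$kind))
  }
  grads
}

#' Train a layered network by SGD
#'
#' Mini-batch SGD on softmax cross-entropy with the stepped learning-rate
#' schedule of [learning_rate_at()], ratio-controlled batch composition, and
#' optional per-sample translation/rotation augmentation. Deterministic given
#' `config$seed`. Aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param network a `"layered_network"`.
#' @param patches list of `"labelled_patch"` training patches.
#' @param config a [train_config()].
#' @param tiles named list of source tiles (required for translation jitter).
#' @param val_patches optional validation patches; when given, the history
#'   records the per-epoch validation error rate.
#' @param epochs optional override of `config$epochs`.
#' @return list with `network` (trained) and `history` (data.frame with one
#'   row per epoch: `epoch`, `lr`, `loss`, and `val_error` if applicable).
#' @export
train_network <- function(network, patches, config = train_config(),
                          tiles = NULL, val_patches = NULL, epochs = NULL) {
  labels <- vapply(patches, `[[`, character(1), "label")
  if (!all(labels %in% network$classes))
    stopf("patch labels must be one of: %s", paste(network$classes, collapse = ", "))
  epochs <- as.integer(epochs %||% config$epochs)
  y_all <- match(labels, network$classes)
  n <- length(patches)
  steps_per_epoch <- max(1L, ceiling(n / config$batch_size))
  jit <- if (config$augment) config$jitter_frac else 0

  with_local_seed(config$seed, {
    sampler <- compose_batches(labels, config$ratio, config$batch_size)
    vel <- vector("list", length(network$layers))
    hist_loss <- numeric(epochs); hist_lr <- numeric(epochs)
    hist_val <- rep(NA_real_, epochs)
    for (epoch in seq_len(epochs)) {
      lr <- learning_rate_at(config, epoch)
      losses <- numeric(steps_per_epoch)
      for (step in seq_len(steps_per_epoch)) {
        ids <- sampler()
        batch <- lapply(ids, function(i) {
          p <- patches[[i]]
          if (config$augment)
            p <- augment_patch(p, tile = tiles[[p$source$tile_id]],
                               jitter_frac = if (is.null(tiles)) 0 else jit,
                               rotations = config$rotations)
          p
        })
        x <- patches_to_batch(batch)
        if (anyNA(x))
          stopf("training diverged (non-finite input batch) at epoch %d step %d",
                epoch, step)
        fb <- forward_batch(network, x, keep = TRUE)
        yb <- y_all[ids]
        pr <- softmax_rows(fb$scores)
        loss <- -mean(log(pmax(pr[cbind(seq_along(yb), yb)], 1e-12)))
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d step %d", epoch, step)
        losses[step] <- loss
        grads <- backward_batch(network, fb, yb)
        for (i in seq_along(network$layers)) {
          g <- grads[[i]]
          if (is.null(g)) next
          if (is.null(vel[[i]])) vel[[i]] <- lapply(g, function(gg) gg * 0)
          for (nm in names(g)) {
            vel[[i]][[nm]] <- config$momentum * vel[[i]][[nm]] - lr * g[[nm]]
            network$layers[[i]][[nm]] <- network$layers[[i]][[nm]] + vel[[i]][[nm]]
          }
        }
      }
      hist_loss[epoch] <- mean(losses)
      hist_lr[epoch] <- lr
      if (!is.null(val_patches)) {
        pred <- predict_label(network, val_patches)
        truth <- vapply(val_patches, `[[`, character(1), "label")
        hist_val[epoch] <- mean(pred != truth)
      }
    }
    history <- data.frame(epoch = seq_len(epochs), lr = hist_lr, loss = hist_loss)
    if (!is.null(val_patches)) history$val_error <- hist_val
    list(network = network, history = history)
  })
}

#' Early-stopping epoch by cross-validation over tiles
#'
#' Splits the training patches into `config$folds` folds by source tile (a
#' tile never contributes patches to more than one fold), trains one model
#' per fold on the remaining folds, and returns the epoch with the lowest
#' validation error averaged over folds — the earliest such epoch on ties.
#' The final model is then conventionally retrained on the full set for that
#' many epochs.
#'
#' @param patches list of `"labelled_patch"`.
#' @param config a [train_config()].
#' @param tiles named list of source tiles (for augmentation).
#' @param network_factory function(seed) returning an untrained network.
#' @return list with `epoch` (integer), `mean_val_error` (numeric vector over
#'   epochs) and `fold_assignment` (tile id to fold).
#' @export
early_stop_epoch <- function(patches, config = train_config(), tiles = NULL,
                             network_factory = function(seed) default_network(seed)) {
  tile_ids <- vapply(patches, function(p) p$source$tile_id, character(1))
  tiles_u <- unique(tile_ids)
  if (length(tiles_u) < config$folds)
    stopf("need at least %d tiles for %d-fold cross-validation, got %d",
          config$folds, config$folds, length(tiles_u))
  fold_of <- with_local_seed(derive_seed(config$seed, 17L), {
    stats::setNames(rep_len(seq_len(config$folds), length(tiles_u)),
                    sample(tiles_u))
  })
  val_err <- matrix(NA_real_, config$epochs, config$folds)
  for (f in seq_len(config$folds)) {
    in_val <- fold_of[tile_ids] == f
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + f)
    fit <- train_network(network_factory(cfg$seed), patches[!in_val], cfg,
                         tiles = tiles, val_patches = patches[in_val])
    val_err[, f] <- fit$history$val_error
  }
  mean_err <- rowMeans(val_err)
  list(epoch = which.min(mean_err),  # which.min returns the earliest minimum
       mean_val_error = mean_err, fold_assignment = fold_of)
}
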