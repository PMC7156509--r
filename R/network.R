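# Layered convolutional network: definition and forward pass.
#
# Feature maps are stored as arrays of shape (H, W, B, C) — batch before
# channel so that per-channel pooling can treat (B, C) as one flat batch and
# convolution output lands in the right memory order without a permute.
# Convolutions are evaluated by gathering receptive fields into an im2col
# matrix (one BLAS product per layer per batch); the gather indices depend
# only on the geometry and are cached.

.geom_cache <- new.env(parent = emptyenv())

# im2col gather indices for a (H, W, [B,] C) array and a k x k window moved
# with the given stride. Returns a (n_positions x k*k*C) 1-based index matrix
# for batch sample 1 / batch size 1; other samples are reached by offsetting.
# Column order is (ky, kx, c), matching the column-major flattening of a
# (k, k, C) weight block.
im2col_index <- function(h, w, n_batch, n_chan, k, stride) {
  key <- paste(h, w, n_batch, n_chan, k, stride, sep = "_")
  cached <- .geom_cache[[key]]
  if (!is.null(cached)) return(cached)
  ho <- (h - k) %/% stride + 1L
  wo <- (w - k) %/% stride + 1L
  if (ho < 1 || wo < 1) stopf("window of size %d does not fit a %dx%d input", k, h, w)
  oy <- rep(seq_len(ho), times = wo)
  ox <- rep(seq_len(wo), each = ho)
  base <- (oy - 1L) * stride + ((ox - 1L) * stride) * h  # 0-based partial index
  ky <- rep(seq_len(k), times = k * n_chan)
  kx <- rep(rep(seq_len(k), each = k), times = n_chan)
  cc <- rep(seq_len(n_chan), each = k * k)
  off <- ky + (kx - 1L) * h + (cc - 1L) * h * w * n_batch
  idx <- outer(base, off, "+")
  out <- list(idx = idx, ho = ho, wo = wo, n_pos = ho * wo)
  .geom_cache[[key]] <- out
  out
}

# Gather the im2col matrix for a (H, W, B, C) batch: (n_pos * B) x (k*k*C),
# rows ordered position-fastest within each sample.
im2col_gather <- function(x, k, stride) {
  d <- dim(x)
  g <- im2col_index(d[1], d[2], d[3], d[4], k, stride)
  b <- d[3]
  if (b > 1L) {
    bkey <- paste("big", d[1], d[2], b, d[4], k, stride, sep = "_")
    big <- .geom_cache[[bkey]]
    if (is.null(big)) {
      big <- g$idx[rep(seq_len(g$n_pos), b), , drop = FALSE] +
        rep((seq_len(b) - 1L) * d[1] * d[2], each = g$n_pos)
      .geom_cache[[bkey]] <- big
    }
    g$idx <- big
  }
  # index with a vector: a matrix subscript would be read as coordinates
  xc <- matrix(x[as.vector(g$idx)], g$n_pos * b, ncol(g$idx))
  list(xc = xc, idx = g$idx, ho = g$ho, wo = g$wo, n_pos = g$n_pos)
}

#' Layer constructors for a layered network
#'
#' Build the ordered layer list of a [layered_network()]. Convolutions are
#' `valid` (no padding) with square kernels; `maxpool` uses non-overlapping
#' windows; `global_avgpool` averages each channel map to a scalar, which
#' makes the network applicable to any input size at least as large as its
#' receptive field.
#'
#' @param in_ch,out_ch channel counts.
#' @param k kernel / window side.
#' @param stride stride (defaults: 1 for conv, `k` for pooling).
#' @param weights,bias optional parameter initialisation; conv weights are a
#'   `(k, k, in_ch, out_ch)` array, dense weights an `(in_f, out_f)` matrix.
#' @param in_f,out_f dense layer fan-in/fan-out.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv <- function(in_ch, out_ch, k, stride = 1L, weights = NULL, bias = NULL) {
  nk <- k * k * in_ch
  if (is.null(weights)) weights <- array(0, c(k, k, in_ch, out_ch))
  stopifnot(all(dim(weights) == c(k, k, in_ch, out_ch)))
  if (is.null(bias)) bias <- numeric(out_ch)
  list(kind = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride),
       wmat = matrix(weights, nk, out_ch), bias = bias)
}

#' @rdname layers
#' @export
layer_relu <- function() list(kind = "relu")

#' @rdname layers
#' @export
layer_maxpool <- function(k = 2L, stride = k)
  list(kind = "maxpool", k = as.integer(k), stride = as.integer(stride))

#' @rdname layers
#' @export
layer_avgpool <- function(k = 2L, stride = k)
  list(kind = "avgpool", k = as.integer(k), stride = as.integer(stride))

#' @rdname layers
#' @export
layer_global_avgpool <- function() list(kind = "global_avgpool")

#' @rdname layers
#' @export
layer_flatten <- function() list(kind = "flatten")

#' @rdname layers
#' @export
layer_dense <- function(in_f, out_f, weights = NULL, bias = NULL) {
  if (is.null(weights)) weights <- matrix(0, in_f, out_f)
  stopifnot(all(dim(weights) == c(in_f, out_f)))
  if (is.null(bias)) bias <- numeric(out_f)
  list(kind = "dense", in_f = as.integer(in_f), out_f = as.integer(out_f),
       weights = weights, bias = bias)
}

#' Assemble a layered network
#'
#' @param layers ordered list built from the [layers] constructors; the final
#'   layer must be a dense head with one output per class, preceded by exactly
#'   one `global_avgpool` or `flatten`.
#' @param input_shape `c(H, W, C)` of the expected input. When the head is a
#'   global average pool, other spatial sizes are accepted at run time.
#' @param classes class names; the second is the positive ("cancer") class.
#' @return An object of class `"layered_network"`.
#' @export
layered_network <- function(layers, input_shape = c(64L, 64L, 3L),
                            classes = c("no_cancer", "cancer")) {
  kinds <- vapply(layers, `[[`, character(1), "kind")
  if (kinds[length(kinds)] != "dense")
    stopf("final layer must be dense")
  n_head <- sum(kinds %in% c("global_avgpool", "flatten"))
  if (n_head != 1)
    stopf("exactly one global_avgpool or flatten must precede the dense head")
  net <- structure(list(layers = layers, input_shape = as.integer(input_shape),
                        classes = classes), class = "layered_network")
  check_network_shapes(net)
  net
}

# Walk the declared shapes once; errors on chain-incompatible layers.
check_network_shapes <- function(net) {
  sh <- net$input_shape  # (H, W, C)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    sh <- switch(l$kind,
      conv = {
        if (sh[3] != l$in_ch) stopf("layer %d: expects %d channels, gets %d", i, l$in_ch, sh[3])
        c((sh[1] - l$k) %/% l$stride + 1L, (sh[2] - l$k) %/% l$stride + 1L, l$out_ch)
      },
      maxpool = ,
      avgpool = c((sh[1] - l$k) %/% l$stride + 1L, (sh[2] - l$k) %/% l$stride + 1L, sh[3]),
      relu = sh,
      global_avgpool = c(1L, 1L, sh[3]),
      flatten = c(1L, 1L, prod(sh)),
      dense = {
        if (length(sh) != 3 || prod(sh[1:2]) != 1L || sh[3] != l$in_f)
          stopf("layer %d: dense expects %d features, gets %s", i, l$in_f, paste(sh, collapse = "x"))
        c(1L, 1L, l$out_f)
      },
      stopf("unknown layer kind '%s'", l$kind))
    if (any(sh[1:2] < 1)) stopf("layer %d: spatial dimensions collapse to zero", i)
  }
  invisible(sh)
}

#' Default small tumour-patch classifier
#'
#' conv(3 to 8) - relu - maxpool(2) - conv(8 to 16) - relu - maxpool(2) -
#' conv(16 to 32) - relu - maxpool(2) - flatten - dense, with He-uniform
#' initialised weights. The spatially resolved flatten head lets the dense
#' layer read *where* evidence occurs, which is what makes small localised
#' artefacts (such as a corner marker) learnable at this scale; a global
#' average pool head summarises that information away. The dense fan-in is
#' derived from `input_shape`, so networks are input-size-specific.
#'
#' @param seed integer seed for the weight initialisation.
#' @param input_shape `c(H, W, C)` of training patches.
#' @param widths channel widths of the three conv stages.
#' @return A `"layered_network"`.
#' @export
default_network <- function(seed = 0L, input_shape = c(64L, 64L, 3L),
                            widths = c(8L, 16L, 32L)) {
  he_init <- function(k, cin, cout) {
    lim <- sqrt(6 / (k * k * cin))
    array(stats::runif(k * k * cin * cout, -lim, lim), c(k, k, cin, cout))
  }
  stage <- function(s) (s - 2L) %/% 2L   # conv 3x3 valid, then maxpool 2
  h3 <- stage(stage(stage(input_shape[1])))
  w3 <- stage(stage(stage(input_shape[2])))
  if (h3 < 1 || w3 < 1) stopf("input %dx%d is too small for the default architecture",
                              input_shape[1], input_shape[2])
  n_feat <- h3 * w3 * widths[3]
  with_local_seed(seed, {
    layers <- list(
      layer_conv(input_shape[3], widths[1], 3L, weights = he_init(3, input_shape[3], widths[1])),
      layer_relu(),
      layer_maxpool(2L),
      layer_conv(widths[1], widths[2], 3L, weights = he_init(3, widths[1], widths[2])),
      layer_relu(),
      layer_maxpool(2L),
      layer_conv(widths[2], widths[3], 3L, weights = he_init(3, widths[2], widths[3])),
      layer_relu(),
      layer_maxpool(2L),
      layer_flatten(),
      layer_dense(n_feat, 2L,
                  weights = matrix(stats::runif(n_feat * 2, -sqrt(6 / n_feat),
                                                sqrt(6 / n_feat)), n_feat, 2))
    )
    layered_network(layers, input_shape)
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass over a (H, W, B, C) batch. When `keep = TRUE` the per-layer
# inputs and pooling argmaxes needed for backprop / relevance propagation are
# retained.
forward_batch <- function(net, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    d <- dim(x)
    cache <- list(input = x)
    x <- switch(l$kind,
      conv = {
        g <- im2col_gather(x, l$k, l$stride)
        y <- g$xc %*% l$wmat
        y <- y + rep(l$bias, each = nrow(y))
        if (keep) { cache$xc <- g$xc; cache$idx <- g$idx; cache$geom <- g[c("ho", "wo", "n_pos")] }
        array(y, c(g$ho, g$wo, d[3], l$out_ch))
      },
      relu = pmax(x, 0),
      maxpool = ,
      avgpool = {
        flat <- array(x, c(d[1], d[2], d[3] * d[4], 1L))  # (B*C) as batch, 1 channel
        g <- im2col_gather(flat, l$k, l$stride)
        if (l$kind == "avgpool") {
          y <- rowMeans(g$xc)
        } else {
          y <- g$xc[, 1]
          wm <- rep(1L, length(y))
          for (j in 2:ncol(g$xc)) {
            upd <- g$xc[, j] > y   # strict: first index wins ties
            upd[is.na(upd)] <- FALSE   # NaN activations propagate via y
            wm[upd] <- j
            y[upd] <- g$xc[upd, j]
          }
          if (keep) { cache$argmax <- wm; cache$idx <- g$idx }
        }
        if (keep) cache$geom <- g[c("ho", "wo", "n_pos")]
        array(y, c(g$ho, g$wo, d[3], d[4]))
      },
      global_avgpool = {
        y <- .colMeans(matrix(x, d[1] * d[2], d[3] * d[4]), d[1] * d[2], d[3] * d[4])
        matrix(y, d[3], d[4])  # B x C
      },
      flatten = {
        xp <- aperm(x, c(1, 2, 4, 3))  # (H, W, C, B): features in (y, x, c) order
        t(matrix(xp, d[1] * d[2] * d[4], d[3]))
      },
      dense = {
        y <- x %*% l$weights
        y + rep(l$bias, each = nrow(y))
      })
    if (keep) caches[[i]] <- cache
  }
  list(scores = x, caches = caches)
}

# Convert a list of patches/images to a (H, W, B, C) batch array.
patches_to_batch <- function(patches) {
  imgs <- lapply(patches, function(p) if (inherits(p, "labelled_patch")) p$image else p)
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], length(imgs), d[3]))
  for (b in seq_along(imgs)) x[, , b, ] <- imgs[[b]]
  x
}

#' Forward pass with full activation trace
#'
#' Runs one patch through the network and records every layer's input and
#' output, the final pre-softmax scores and the softmax probabilities. The
#' trace carries all pre-activations that the relevance engine needs.
#'
#' @param network a `"layered_network"`.
#' @param patch an H x W x C array in [0, 1] (or a `"labelled_patch"`).
#' @return An object of class `"activation_trace"`.
#' @export
forward <- function(network, patch) {
  img <- if (inherits(patch, "labelled_patch")) patch$image else patch
  d <- dim(img)
  if (length(d) != 3 || d[3] != network$input_shape[3])
    stopf("input has shape %s; network expects %d channels",
          paste(d, collapse = "x"), network$input_shape[3])
  has_flatten <- any(vapply(network$layers, `[[`, character(1), "kind") == "flatten")
  if (has_flatten && !all(d == network$input_shape))
    stopf("network with flatten head requires input shape %s",
          paste(network$input_shape, collapse = "x"))
  x <- array(img, c(d[1], d[2], 1L, d[3]))
  fb <- forward_batch(network, x, keep = TRUE)
  drop_b <- function(a) {
    if (is.matrix(a) && nrow(a) == 1) return(as.vector(a))
    da <- dim(a)
    if (length(da) == 4) return(array(a, da[c(1, 2, 4)]))
    a
  }
  layers_out <- lapply(seq_along(network$layers), function(i) {
    cache <- fb$caches[[i]]
    out <- if (i < length(network$layers)) fb$caches[[i + 1]]$input else fb$scores
    list(input = drop_b(cache$input), output = drop_b(out),
         argmax = cache$argmax, idx = cache$idx, geom = cache$geom)
  })
  scores <- as.vector(fb$scores)
  names(scores) <- network$classes
  probs <- as.vector(softmax_rows(fb$scores))
  names(probs) <- network$classes
  structure(list(layers = layers_out, scores = scores, probs = probs,
                 input_dim = d), class = "activation_trace")
}

#' Class probabilities for a list of patches
#'
#' @param network a trained `"layered_network"`.
#' @param patches list of patches (or arrays), all of one shape.
#' @param batch_size internal forward batch size.
#' @return Numeric matrix, one row per patch, columns named by class; rows
#'   sum to 1.
#' @export
predict_proba <- function(network, patches, batch_size = 64L) {
  n <- length(patches)
  out <- matrix(0, n, length(network$classes),
                dimnames = list(NULL, network$classes))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- patches_to_batch(patches[i:j])
    out[i:j, ] <- softmax_rows(forward_batch(network, x)$scores)
    i <- j + 1L
  }
  out
}

#' Predicted labels for a list of patches
#' @inheritParams predict_proba
#' @return Character vector of class names.
#' @export
predict_label <- function(network, patches, batch_size = 64L) {
  p <- predict_proba(network, patches, batch_size)
  network$classes[max.col(p, ties.method = "first")]
}
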