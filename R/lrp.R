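# Layer-wise relevance propagation.
#
# The backward pass is seeded with the target class's pre-softmax score and
# redistributes it layer by layer: the epsilon-rule for the dense head, the
# alpha-beta-rule for convolutions (and, with uniform weights 1/n, for
# average/global-average pooling), winner-take-all for max pooling, and
# identity for relu/flatten. Bias terms enter the denominators (they are part
# of the pre-activation) but their relevance share is absorbed, which is the
# source of mild non-conservation whenever biases are non-zero.

#' Relevance-rule parameters
#'
#' @param epsilon stabiliser of the dense-layer rule (>= 0); the convention
#'   `sign(0) = +1` guards the denominator at exactly zero pre-activation.
#' @param alpha,beta weights of the positive and negative pre-activation
#'   shares in the convolutional rule. Conservation requires
#'   `alpha + beta = 1`; the defaults `alpha = 1`, `beta = 0` propagate only
#'   excitatory evidence. The beta term is applied with a plus sign, exactly
#'   as in the rule's printed form; a message flags any non-zero beta because
#'   part of the literature subtracts that term instead.
#' @return An object of class `"rule_params"`.
#' @export
rule_params <- function(epsilon = 1, alpha = 1, beta = 0) {
  if (epsilon < 0) stopf("epsilon must be >= 0")
  if (beta != 0)
    message("beta != 0: the beta term is added as printed; ",
            "check the sign convention you expect")
  structure(list(epsilon = epsilon, alpha = alpha, beta = beta),
            class = "rule_params")
}

#' Default layer-kind to rule assignment
#'
#' dense: epsilon-rule; conv: alpha-beta-rule; maxpool: winner-take-all;
#' avgpool/global_avgpool: alpha-beta with uniform weights 1/n; relu and
#' flatten: pass-through.
#'
#' @return Named character vector mapping layer kind to rule name.
#' @export
rule_assignment <- function() {
  c(dense = "epsilon", conv = "alphabeta", maxpool = "winner_take_all",
    avgpool = "alphabeta_uniform", global_avgpool = "alphabeta_uniform",
    relu = "pass_through", flatten = "pass_through")
}

sign0 <- function(x) ifelse(x >= 0, 1, -1)  # sign(0) := +1

#' Epsilon-rule relevance propagation through a dense layer
#'
#' Redistributes upper-layer relevance R_j to the layer inputs as
#' `R_i = sum_j z_ij / (sum_i' z_i'j + eps * sign(sum_i' z_i'j)) * R_j`
#' with `z_ij = x_i w_ij`; the denominator is the unit's full pre-activation
#' (bias included), whose relevance share is absorbed. With `epsilon = 0`,
#' units with exactly zero pre-activation absorb their relevance.
#'
#' @param layer a dense layer (see [layer_dense()]).
#' @param input the layer's input activation vector.
#' @param R_upper relevance vector of the layer's outputs.
#' @param epsilon stabiliser.
#' @return Relevance vector over the layer's inputs.
#' @export
relprop_dense_epsilon <- function(layer, input, R_upper, epsilon = 1) {
  z <- input * layer$weights           # z_ij, recycled by column
  denom <- colSums(z) + layer$bias
  if (epsilon > 0) {
    factor <- R_upper / (denom + epsilon * sign0(denom))
  } else {
    factor <- ifelse(denom == 0, 0, R_upper / denom)
  }
  as.vector(z %*% factor)
}

#' Alpha-beta-rule relevance propagation through a convolution
#'
#' Treats the convolution in its unrolled linear form and applies
#' `R_i = sum_j (alpha * z+_ij / sum z+_i'j + beta * z-_ij / sum z-_i'j) R_j`.
#' The positive/negative bias parts enter the respective denominator sums;
#' when a unit's positive (resp. negative) sum is zero that term contributes
#' nothing and the unit's relevance share is absorbed.
#'
#' @param layer a conv layer (see [layer_conv()]).
#' @param input the layer's input activation array (H x W x C).
#' @param R_upper relevance array over the layer's outputs (Ho x Wo x Cout).
#' @param alpha,beta share weights.
#' @return Relevance array with the shape of `input`.
#' @export
relprop_conv_alphabeta <- function(layer, input, R_upper, alpha = 1, beta = 0) {
  d <- dim(input)
  x <- array(input, c(d[1], d[2], 1L, d[3]))
  g <- im2col_gather(x, layer$k, layer$stride)
  rmat <- matrix(R_upper, g$n_pos, layer$out_ch)
  racc <- matrix(0, g$n_pos, ncol(g$xc))
  bpos <- pmax(layer$bias, 0)
  bneg <- pmin(layer$bias, 0)
  for (co in seq_len(layer$out_ch)) {
    z <- g$xc * rep(layer$wmat[, co], each = g$n_pos)
    zp <- pmax(z, 0)
    sp <- rowSums(zp) + bpos[co]
    coefp <- ifelse(sp == 0, 0, alpha * rmat[, co] / sp)
    racc <- racc + zp * coefp
    if (beta != 0) {
      zm <- pmin(z, 0)
      sm <- rowSums(zm) + bneg[co]
      coefm <- ifelse(sm == 0, 0, beta * rmat[, co] / sm)
      racc <- racc + zm * coefm
    }
  }
  rx <- numeric(prod(d))
  for (j in seq_len(ncol(g$idx))) {
    ind <- g$idx[, j]
    rx[ind] <- rx[ind] + racc[, j]
  }
  array(rx, d)
}

#' Relevance propagation through pooling and shape layers
#'
#' Max pooling routes each output's relevance entirely to the argmax input of
#' its window (lowest linear index on ties); average and global-average
#' pooling are treated as convolutions with uniform weights 1/n under the
#' alpha-beta-rule; flatten reshapes relevance without changing values.
#'
#' @param layer a maxpool/avgpool/global_avgpool/flatten layer.
#' @param input the layer's input activation array.
#' @param R_upper relevance of the layer's outputs.
#' @param alpha,beta alpha-beta weights for the average-pooling case.
#' @return Relevance array with the shape of `input`.
#' @export
relprop_pool <- function(layer, input, R_upper, alpha = 1, beta = 0) {
  d <- dim(input)
  if (layer$kind == "flatten") {
    # forward flattening of (H, W, C) used feature order (y, x, c)
    return(array(R_upper, d))
  }
  if (layer$kind == "global_avgpool") {
    n <- d[1] * d[2]
    rx <- array(0, d)
    for (ch in seq_len(d[3])) {
      z <- input[, , ch] / n
      zp <- pmax(z, 0); sp <- sum(zp)
      zm <- pmin(z, 0); sm <- sum(zm)
      out <- if (sp > 0) alpha * R_upper[ch] * zp / sp else 0 * z
      if (beta != 0 && sm < 0) out <- out + beta * R_upper[ch] * zm / sm
      rx[, , ch] <- out
    }
    return(rx)
  }
  x <- array(input, c(d[1], d[2], d[3], 1L))  # channels as flat batch
  g <- im2col_gather(x, layer$k, layer$stride)
  rv <- as.vector(R_upper)
  rx <- numeric(prod(d))
  if (layer$kind == "maxpool") {
    y <- g$xc[, 1]
    wm <- rep(1L, length(y))
    for (j in 2:ncol(g$xc)) {
      upd <- g$xc[, j] > y
      wm[upd] <- j
      y[upd] <- g$xc[upd, j]
    }
    win <- g$idx[cbind(seq_along(wm), wm)]
    acc <- rowsum(rv, win)  # winners can repeat when windows overlap
    rx[as.integer(rownames(acc))] <- acc
    return(array(rx, d))
  }
  if (layer$kind == "avgpool") {
    n <- layer$k^2
    z <- g$xc / n
    zp <- pmax(z, 0); sp <- rowSums(zp)
    zm <- pmin(z, 0); sm <- rowSums(zm)
    coefp <- ifelse(sp == 0, 0, alpha * rv / sp)
    racc <- zp * coefp
    if (beta != 0) racc <- racc + zm * ifelse(sm == 0, 0, beta * rv / sm)
    for (j in seq_len(ncol(g$idx))) {
      ind <- g$idx[, j]
      rx[ind] <- rx[ind] + racc[, j]
    }
    return(array(rx, d))
  }
  stopf("relprop_pool: unsupported layer kind '%s'", layer$kind)
}

#' Pixel-wise relevance heatmap for one patch
#'
#' Seeds the backward pass with a pre-softmax quantity — never the softmax
#' output, since the redistribution rules act on linear pre-activations and
#' softmax would couple the classes — and applies the assigned rule per
#' layer from the head down to the input. Per-pixel relevance is the sum
#' over the three colour channels.
#'
#' Two seed quantities are available. `"margin"` (the default for the
#' two-class head) explains the logit difference between the target class
#' and the other class: the softmax decision depends only on this
#' difference, so its sign separates evidence for the target class from
#' evidence against it, and the backward pass starts from a virtual output
#' unit whose weights are the difference of the two class columns.
#' `"logit"` explains the target class's raw pre-softmax score.
#'
#' @param network a trained `"layered_network"`.
#' @param patch an H x W x C array in [0, 1] or a `"labelled_patch"`.
#' @param target_class class to explain (default `"cancer"`).
#' @param params a [rule_params()].
#' @param seed `"margin"` or `"logit"`.
#' @param trace optional precomputed [forward()] trace of the patch.
#' @return An object of class `"relevance_map"`: `values` (signed H x W
#'   raster), `channel_values` (H x W x C), `target_class`, `seed_value` (the
#'   propagated score), `normalisation` (`"raw"`) and the rule parameters.
#' @export
explain <- function(network, patch, target_class = "cancer",
                    params = rule_params(), seed = c("margin", "logit"),
                    trace = NULL) {
  seed <- match.arg(seed)
  if (!target_class %in% network$classes)
    stopf("unknown target class '%s'", target_class)
  if (seed == "margin" && length(network$classes) != 2)
    stopf("margin seeding is defined for two-class networks")
  if (is.null(trace)) trace <- forward(network, patch)
  target <- match(target_class, network$classes)
  n_layer <- length(network$layers)
  if (seed == "margin") {
    other <- setdiff(seq_along(network$classes), target)
    seed_value <- unname(trace$scores[target] - trace$scores[other])
    R <- seed_value
  } else {
    seed_value <- unname(trace$scores[target])
    R <- numeric(length(trace$scores))
    R[target] <- seed_value
  }
  for (i in rev(seq_len(n_layer))) {
    l <- network$layers[[i]]
    x <- trace$layers[[i]]$input
    if (l$kind == "dense" && i == n_layer && seed == "margin") {
      # virtual difference unit: weights w_target - w_other
      l <- layer_dense(l$in_f, 1L,
                       weights = l$weights[, target, drop = FALSE] -
                         l$weights[, other, drop = FALSE],
                       bias = l$bias[target] - l$bias[other])
    }
    R <- switch(l$kind,
      dense = relprop_dense_epsilon(l, x, R, params$epsilon),
      conv = relprop_conv_alphabeta(l, x, R, params$alpha, params$beta),
      relu = array(R, dim(x)),
      maxpool = ,
      avgpool = ,
      global_avgpool = ,
      flatten = relprop_pool(l, x, R, params$alpha, params$beta),
      stopf("no relevance rule for layer kind '%s'", l$kind))
  }
  channel_values <- R
  values <- channel_values[, , 1]
  for (ch in seq_len(dim(channel_values)[3] - 1) + 1)
    values <- values + channel_values[, , ch]
  structure(list(values = values, channel_values = channel_values,
                 target_class = target_class, seed_value = seed_value,
                 seed_quantity = seed, normalisation = "raw",
                 params = unclass(params)), class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map> %dx%d, class '%s', seed value %.4g, sum %.4g (%s)\n",
              nrow(x$values), ncol(x$values), x$target_class, x$seed_value,
              sum(x$values), x$normalisation))
  invisible(x)
}
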