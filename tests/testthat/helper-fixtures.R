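# Shared fixtures: all built in code, sized for speed.

small_spec <- function(...) {
  generator_spec(tile_size = 128, patch_size = 64, n_tumour = 8, n_normal = 14,
                 necrosis_count_range = c(1L, 1L),
                 necrosis_radius_range = c(12, 18), ...)
}

small_tile <- function(seed = 1, spec = small_spec(), ...) {
  generate_tile(spec, seed = seed, ...)
}

# A hand-built tile-like object with known cell positions (no drawing).
manual_tile <- function(h, w, cells, patch_size = 200L, regions = list(),
                        id = "manual") {
  structure(list(image = array(0.5, c(h, w, 3)), cells = cells,
                 regions = regions, seed = 0L, id = id,
                 spec = list(patch_size = as.integer(patch_size))),
            class = "tissue_tile")
}

# Reference convolution: direct nested loops, valid padding.
naive_conv <- function(x, l) {
  d <- dim(x); k <- l$k; s <- l$stride
  ho <- (d[1] - k) %/% s + 1; wo <- (d[2] - k) %/% s + 1
  W <- array(l$wmat, c(k, k, l$in_ch, l$out_ch))
  out <- array(0, c(ho, wo, l$out_ch))
  for (co in seq_len(l$out_ch)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    blk <- x[((i - 1) * s + 1):((i - 1) * s + k),
             ((j - 1) * s + 1):((j - 1) * s + k), , drop = FALSE]
    out[i, j, co] <- sum(blk * W[, , , co]) + l$bias[co]
  }
  out
}

# Reference forward pass composed from naive per-layer evaluations.
naive_forward <- function(net, x) {
  a <- x
  for (l in net$layers) {
    a <- switch(l$kind,
      conv = naive_conv(a, l),
      relu = pmax(a, 0),
      maxpool = {
        d <- dim(a); ho <- (d[1] - l$k) %/% l$stride + 1
        wo <- (d[2] - l$k) %/% l$stride + 1
        o <- array(0, c(ho, wo, d[3]))
        for (c in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo))
          o[i, j, c] <- max(a[((i - 1) * l$stride + 1):((i - 1) * l$stride + l$k),
                              ((j - 1) * l$stride + 1):((j - 1) * l$stride + l$k), c])
        o
      },
      avgpool = {
        d <- dim(a); ho <- (d[1] - l$k) %/% l$stride + 1
        wo <- (d[2] - l$k) %/% l$stride + 1
        o <- array(0, c(ho, wo, d[3]))
        for (c in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo))
          o[i, j, c] <- mean(a[((i - 1) * l$stride + 1):((i - 1) * l$stride + l$k),
                               ((j - 1) * l$stride + 1):((j - 1) * l$stride + l$k), c])
        o
      },
      global_avgpool = apply(a, 3, mean),
      flatten = as.vector(a),
      dense = as.vector(a %*% l$weights) + l$bias)
  }
  a
}

# Random small conv net (all layer kinds) for property tests.
random_small_net <- function(seed, positive = FALSE, zero_bias = TRUE) {
  net <- default_network(seed = seed, input_shape = c(24L, 24L, 3L),
                         widths = c(3L, 4L, 5L))
  if (positive) {
    for (i in seq_along(net$layers)) {
      if (!is.null(net$layers[[i]]$wmat))
        net$layers[[i]]$wmat <- abs(net$layers[[i]]$wmat)
      if (!is.null(net$layers[[i]]$weights))
        net$layers[[i]]$weights <- abs(net$layers[[i]]$weights)
    }
  }
  if (!zero_bias) {
    for (i in seq_along(net$layers))
      if (!is.null(net$layers[[i]]$bias))
        net$layers[[i]]$bias <- stats::rnorm(length(net$layers[[i]]$bias), 0, 0.05)
  }
  net
}

# Two-colour trivially separable toy patches.
toy_patches <- function(n_per_class = 8, size = 22) {
  mk <- function(value, label, k) {
    img <- array(value, c(size, size, 3)) +
      array(stats::runif(size * size * 3, 0, 0.02), c(size, size, 3))
    structure(list(image = img, label = label,
                   source = list(tile_id = "toy", row = 0L, col = 0L),
                   bias_flags = character(0)), class = "labelled_patch")
  }
  c(lapply(seq_len(n_per_class), function(k) mk(0.2, "cancer", k)),
    lapply(seq_len(n_per_class), function(k) mk(0.8, "no_cancer", k)))
}

toy_net <- function(seed = 1, size = 22L) {
  default_network(seed = seed, input_shape = c(size, size, 3L),
                  widths = c(2L, 3L, 4L))
}
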