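# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions are pure
#' in (arguments, seed) and do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index; stays < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Rotate an H x W (x C) raster clockwise by k * 90 degrees.
rot90 <- function(img, k) {
  k <- ((k %% 360) / 90) %% 4
  if (k == 0) return(img)
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  one <- function(a) {
    if (length(dim(a)) == 2) return(rot1(a))
    out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (ch in seq_len(dim(a)[3])) out[, , ch] <- rot1(a[, , ch])
    out
  }
  for (i in seq_len(k)) img <- one(img)
  img
}

# Per-pixel luminance of an H x W x 3 array in [0, 1].
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
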