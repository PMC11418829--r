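# Internal numeric helpers shared across modules.

# Half-up rounding (R's round() is banker's); used for frame index selection.
round_half_up <- function(x) floor(x + 0.5)

# numpy-gradient-style finite differences on a matrix indexed (row=y, col=x):
# centered in the interior, one-sided at the borders, unit pixel spacing.
grad_x <- function(m) {
  W <- ncol(m)
  if (W < 2L) return(matrix(0, nrow(m), W))
  g <- m
  g[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
  g[, 1] <- m[, 2] - m[, 1]
  g[, W] <- m[, W] - m[, W - 1]
  g
}

grad_y <- function(m) {
  H <- nrow(m)
  if (H < 2L) return(matrix(0, H, ncol(m)))
  g <- m
  g[2:(H - 1), ] <- (m[3:H, ] - m[1:(H - 2), ]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[H, ] <- m[H, ] - m[H - 1, ]
  g
}

# Local box mean with replicated borders (structure-tensor smoothing).
box_mean <- function(m, window) {
  window <- min(window, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (window < 3L) return(m)
  k <- matrix(1 / (window * window), window, window)
  EBImage::filter2(m, k, boundary = "replicate")
}

resize_bilinear <- function(m, nr, nc) {
  EBImage::resize(m, w = nr, h = nc, filter = "bilinear")
}

# Bilinear sampling of `img` at fractional (row, col) positions, clamped to
# the image border. yy/xx are same-length vectors of 1-based coordinates.
bilinear_sample <- function(img, yy, xx) {
  H <- nrow(img); W <- ncol(img)
  yy <- pmin(pmax(yy, 1), H)
  xx <- pmin(pmax(xx, 1), W)
  y0 <- floor(yy); x0 <- floor(xx)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  fy <- yy - y0; fx <- xx - x0
  i00 <- img[cbind(y0, x0)]; i01 <- img[cbind(y0, x1)]
  i10 <- img[cbind(y1, x0)]; i11 <- img[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Backward-warp an image by a dense displacement field: out(y,x) = img(y+v, x+u).
warp_by_flow <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  yy <- matrix(seq_len(H), H, W) + v
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) + u
  matrix(bilinear_sample(img, as.vector(yy), as.vector(xx)), H, W)
}

# Deterministic substream seeds below 2^31 derived from one master seed.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
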