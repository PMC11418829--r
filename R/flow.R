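#' Dense-flow backend configuration
#'
#' Settings of the default dense motion estimator: a coarse-to-fine pyramidal
#' Lucas-Kanade scheme with iterative warping. The displacement convention is
#' forward flow: `frame_t(x) ~ frame_t1(x + (u, v))`, `u` along columns (x),
#' `v` along rows (y), in pixels/frame. Defaults are frozen for determinism.
#'
#' @param levels Number of pyramid levels.
#' @param scale Per-level downscale factor.
#' @param window Side of the square integration window (pixels, odd).
#' @param iterations Warping iterations per level.
#' @param max_disp Magnitude clamp on each displacement component (pixels).
#' @param reg Tikhonov regularizer added to the structure tensor diagonal.
#' @param sigma Gaussian pre-smoothing before each pyramid downscale.
#' @return A list of class `flow_config`.
#' @export
flow_config <- function(levels = 4L, scale = 0.5, window = 15L,
                        iterations = 3L, max_disp = 10, reg = 1e-4,
                        sigma = 1) {
  structure(list(levels = as.integer(levels), scale = scale,
                 window = as.integer(window), iterations = as.integer(iterations),
                 max_disp = max_disp, reg = reg, sigma = sigma,
                 backend = "pyramidal-lucas-kanade"),
            class = "flow_config")
}

#' Construct a dense displacement field
#'
#' Container for a per-pixel displacement field in pixels/frame: `u` is the
#' column-direction (x) component, `v` the row-direction (y) component.
#' Mostly produced by [estimate_flow_pair]; exported so analytic fields can
#' be built directly for the kinematic operators.
#'
#' @param u,v Numeric matrices of identical shape, finite everywhere.
#' @param config Optional [flow_config] recording the producing backend.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(u, v, config = NULL) {
  stopifnot(identical(dim(u), dim(v)), all(is.finite(u)), all(is.finite(v)))
  structure(list(u = u, v = v, config = config), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<flow_field> %dx%d px; |flow| median %.3f, max %.3f px/frame\n",
              nrow(x$u), ncol(x$u), stats::median(mag), max(mag)))
  invisible(x)
}

#' Estimate dense displacement between two frames
#'
#' Computes the per-pixel forward displacement field `(u, v)` such that
#' `frame_t(x) ~ frame_t1(x + (u, v))`, via a coarse-to-fine pyramidal
#' Lucas-Kanade solver with iterative backward warping of `frame_t1`.
#' Deterministic for a fixed `config`.
#'
#' @param frame_t,frame_t1 Numeric matrices of identical shape, intensities
#'   in `[0, 1]`.
#' @param config A [flow_config].
#' @return A `flow_field` with components `u` (columns/x) and `v` (rows/y) in
#'   pixels/frame, each bounded by `config$max_disp`.
#' @export
estimate_flow_pair <- function(frame_t, frame_t1, config = flow_config()) {
  if (!identical(dim(frame_t), dim(frame_t1)))
    stopf("frame shapes differ: %s vs %s",
          paste(dim(frame_t), collapse = "x"),
          paste(dim(frame_t1), collapse = "x"))
  stopifnot(inherits(config, "flow_config"))

  # image pyramids, coarsest last; stop before frames get degenerate
  p1 <- list(frame_t); p2 <- list(frame_t1)
  for (l in seq_len(config$levels - 1L)) {
    prev <- p1[[l]]
    nr <- ceiling(nrow(prev) * config$scale)
    nc <- ceiling(ncol(prev) * config$scale)
    if (min(nr, nc) < 12L) break
    blur <- function(m) EBImage::gblur(m, sigma = config$sigma)
    p1[[l + 1L]] <- resize_bilinear(blur(p1[[l]]), nr, nc)
    p2[[l + 1L]] <- resize_bilinear(blur(p2[[l]]), nr, nc)
  }

  nl <- length(p1)
  u <- matrix(0, nrow(p1[[nl]]), ncol(p1[[nl]]))
  v <- u
  for (l in rev(seq_len(nl))) {
    f1 <- p1[[l]]; f2 <- p2[[l]]
    if (!identical(dim(u), dim(f1))) {
      u <- resize_bilinear(u, nrow(f1), ncol(f1)) / config$scale
      v <- resize_bilinear(v, nrow(f1), ncol(f1)) / config$scale
    }
    clamp <- config$max_disp * config$scale^(l - 1L)
    for (it in seq_len(config$iterations)) {
      f2w <- warp_by_flow(f2, u, v)
      avg <- (f1 + f2w) / 2
      Ix <- grad_x(avg); Iy <- grad_y(avg)
      It <- f2w - f1
      Sxx <- box_mean(Ix * Ix, config$window) + config$reg
      Syy <- box_mean(Iy * Iy, config$window) + config$reg
      Sxy <- box_mean(Ix * Iy, config$window)
      Sxt <- box_mean(Ix * It, config$window)
      Syt <- box_mean(Iy * It, config$window)
      det <- Sxx * Syy - Sxy * Sxy
      du <- -(Syy * Sxt - Sxy * Syt) / det
      dv <- -(Sxx * Syt - Sxy * Sxt) / det
      u <- pmin(pmax(u + du, -clamp), clamp)
      v <- pmin(pmax(v + dv, -clamp), clamp)
    }
  }
  flow_field(u, v, config)
}

#' Estimate the flow sequence of a cine stack
#'
#' Runs [estimate_flow_pair] on each consecutive frame pair, so an `L`-frame
#' sequence yields `L - 1` displacement fields (13 frames -> 12 fields, the
#' temporal depth of the network input).
#'
#' @param seq A preprocessed [cine_sequence].
#' @param config A [flow_config].
#' @return A `flow_sequence`: list with `fields` (length `L - 1`),
#'   `patient_id`, `slice_index`, `label`.
#' @export
estimate_flow_sequence <- function(seq, config = flow_config()) {
  stopifnot(inherits(seq, "cine_sequence"))
  L <- dim(seq$frames)[1]
  fields <- vector("list", L - 1L)
  for (t in seq_len(L - 1L))
    fields[[t]] <- estimate_flow_pair(seq_frame(seq, t), seq_frame(seq, t + 1L),
                                      config)
  structure(list(fields = fields, patient_id = seq$patient_id,
                 slice_index = seq$slice_index, label = seq$label,
                 config = config),
            class = "flow_sequence")
}

#' @export
length.flow_sequence <- function(x) length(x$fields)

#' @export
print.flow_sequence <- function(x, ...) {
  d <- dim(x$fields[[1]]$u)
  cat(sprintf("<flow_sequence> patient %s slice %d: %d fields of %dx%d px (%s)\n",
              x$patient_id, x$slice_index, length(x$fields), d[1], d[2],
              x$config$backend))
  invisible(x)
}
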