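KINEMATIC_CHANNELS <- c("u", "v", "div", "vor", "a_N", "a_T", "intensity")

#' Divergence of a displacement field
#'
#' `div v = du/dx + dv/dy`, computed with centered finite differences in the
#' interior and one-sided differences at the borders (unit pixel spacing).
#' Negative values indicate local myocardial contraction. Units: 1/frame.
#'
#' @param flow A `flow_field` (see [estimate_flow_pair]).
#' @return A numeric matrix of the same shape as the field.
#' @export
divergence_map <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  grad_x(flow$u) + grad_y(flow$v)
}

#' Vorticity of a displacement field
#'
#' The scalar curl `dv/dx - du/dy`, measuring local rotational motion
#' (myocardial twist) during contraction and relaxation. Same differencing
#' scheme as [divergence_map]. Units: 1/frame.
#'
#' @inheritParams divergence_map
#' @return A numeric matrix of the same shape as the field.
#' @export
vorticity_map <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  grad_x(flow$v) - grad_y(flow$u)
}

#' Tangential and normal acceleration maps
#'
#' The temporal velocity change `a = v(t+1) - v(t)` (forward difference of
#' consecutive displacement fields) is decomposed relative to the local
#' velocity direction: the tangential component `a_T = (v . a)/|v|` measures
#' the rate of speed change, the normal component
#' `a_N = |u a_y - v a_x|/|v| >= 0` the rate of direction change. Where the
#' local speed falls below `eps` both are defined as 0. Units: px/frame^2.
#'
#' @param flow_t,flow_t1 Consecutive `flow_field`s of identical shape.
#' @param eps Speed floor (px/frame) below which accelerations are zeroed.
#' @return A list with matrices `a_T` and `a_N`; wherever `|v| >= eps` the
#'   decomposition satisfies `a_T^2 + a_N^2 = |a|^2`.
#' @export
acceleration_maps <- function(flow_t, flow_t1, eps = 1e-3) {
  stopifnot(inherits(flow_t, "flow_field"), inherits(flow_t1, "flow_field"))
  if (!identical(dim(flow_t$u), dim(flow_t1$u)))
    stopf("flow field shapes differ")
  if (eps <= 0) stopf("eps must be > 0")
  ax <- flow_t1$u - flow_t$u
  ay <- flow_t1$v - flow_t$v
  sp <- sqrt(flow_t$u^2 + flow_t$v^2)
  ok <- sp >= eps
  a_T <- matrix(0, nrow(ax), ncol(ax))
  a_N <- a_T
  a_T[ok] <- (flow_t$u[ok] * ax[ok] + flow_t$v[ok] * ay[ok]) / sp[ok]
  a_N[ok] <- abs(flow_t$u[ok] * ay[ok] - flow_t$v[ok] * ax[ok]) / sp[ok]
  list(a_T = a_T, a_N = a_N)
}

#' Assemble the multi-channel kinematic input tensor
#'
#' Builds the `T x H x W x C` network input from a flow sequence. Supported
#' channels: raw flow components `u`, `v`; `div` and `vor` (per field);
#' `a_N`, `a_T` (from consecutive field pairs -- the final time index
#' repeats the last available pair so `T` is preserved); and `intensity`
#' (requires `frames`). Each channel is z-score standardized per sequence;
#' a constant channel maps to zeros.
#'
#' @param flow_seq A `flow_sequence`.
#' @param channels Character vector of channel names, in the order they are
#'   stacked.
#' @param eps Speed floor for the acceleration channels.
#' @param frames Optional `L x H x W` array of preprocessed frames, needed
#'   only for the `intensity` channel (frame `t` pairs with field `t`).
#' @return A `kinematic_stack`: list with `data` (`T x H x W x C`),
#'   `channel_names`, `label`, `patient_id`, `slice_index`.
#' @export
build_kinematic_stack <- function(flow_seq, channels, eps = 1e-3,
                                  frames = NULL) {
  stopifnot(inherits(flow_seq, "flow_sequence"))
  if (length(channels) == 0) stopf("channels must be non-empty")
  bad <- setdiff(channels, KINEMATIC_CHANNELS)
  if (length(bad))
    stopf("unknown channel(s): %s (supported: %s)",
          paste(bad, collapse = ", "), paste(KINEMATIC_CHANNELS, collapse = ", "))
  Tn <- length(flow_seq$fields)
  d <- dim(flow_seq$fields[[1]]$u)
  if ("intensity" %in% channels && is.null(frames))
    stopf("the 'intensity' channel requires `frames`")

  data <- array(0, dim = c(Tn, d[1], d[2], length(channels)))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    for (t in seq_len(Tn)) {
      f <- flow_seq$fields[[t]]
      m <- switch(ch,
        u = f$u,
        v = f$v,
        div = divergence_map(f),
        vor = vorticity_map(f),
        a_N = ,
        a_T = {
          t0 <- min(t, Tn - 1L)           # last index repeats the last pair
          if (Tn == 1L) matrix(0, d[1], d[2]) else {
            acc <- acceleration_maps(flow_seq$fields[[t0]],
                                     flow_seq$fields[[t0 + 1L]], eps)
            acc[[ch]]
          }
        },
        intensity = frames[t, , ])
      data[t, , , ci] <- m
    }
    mu <- mean(data[, , , ci])
    s <- sd(as.vector(data[, , , ci]))
    data[, , , ci] <- if (s < 1e-12) 0 else (data[, , , ci] - mu) / s
  }
  structure(list(data = data, channel_names = channels, eps = eps,
                 label = flow_seq$label, patient_id = flow_seq$patient_id,
                 slice_index = flow_seq$slice_index),
            class = "kinematic_stack")
}

#' @export
dim.kinematic_stack <- function(x) dim(x$data)

#' @export
print.kinematic_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kinematic_stack> patient %s slice %d (%s): %dx%dx%dx%d [%s]\n",
              x$patient_id, x$slice_index, x$label, d[1], d[2], d[3], d[4],
              paste(x$channel_names, collapse = ",")))
  invisible(x)
}
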