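#' @useDynLib cardiokin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd predict
#' @importFrom utils head tail
NULL

CARDIAC_CLASSES <- c("MINF", "DCM", "HCM", "RV", "N")

#' Construct a cine sequence
#'
#' A `cine_sequence` holds one short-axis slice's 2D+t grayscale image stack
#' together with its patient identity and (optional) diagnostic label. Frames
#' are indexed `(t, row, col)` with row = image y increasing downward.
#'
#' @param frames 3D numeric array, `L x H x W` (`L >= 2` frames).
#' @param patient_id Character scalar identifying the patient.
#' @param slice_index Non-negative integer, position of this slice along the
#'   short axis.
#' @param label One of `"MINF"`, `"DCM"`, `"HCM"`, `"RV"`, `"N"` or
#'   `"unknown"`.
#' @param pixel_spacing Optional numeric length-2 vector (mm) carried as
#'   metadata only.
#' @param frame_indices Integer vector of original (0-based) frame indices
#'   retained after any temporal resampling; defaults to `0:(L-1)`.
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, patient_id = "unknown", slice_index = 0L,
                          label = "unknown", pixel_spacing = NULL,
                          frame_indices = NULL) {
  if (length(dim(frames)) != 3L)
    stopf("`frames` must be a 3D array (L x H x W), got %d dims",
          length(dim(frames)))
  d <- dim(frames)
  if (d[1] < 2L) stopf("need at least 2 frames, got %d", d[1])
  if (d[2] < 8L || d[3] < 8L)
    stopf("frames must be at least 8x8 pixels, got %dx%d", d[2], d[3])
  if (!label %in% c(CARDIAC_CLASSES, "unknown"))
    stopf("unknown label '%s'", label)
  if (slice_index < 0L) stopf("slice_index must be >= 0")
  if (is.null(frame_indices)) frame_indices <- seq_len(d[1]) - 1L
  stopifnot(length(frame_indices) == d[1])
  structure(list(frames = frames, patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index), label = label,
                 pixel_spacing = pixel_spacing,
                 frame_indices = as.integer(frame_indices)),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_sequence> patient %s, slice %d, label %s: %d frames of %dx%d px\n",
              x$patient_id, x$slice_index, x$label, d[1], d[2], d[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]; frame indices %s\n",
              min(x$frames), max(x$frames),
              paste(x$frame_indices, collapse = ",")))
  invisible(x)
}

#' @export
dim.cine_sequence <- function(x) dim(x$frames)

seq_frame <- function(seq, t) seq$frames[t, , ]

# Parse an ACDC-style Info.cfg / labels YAML. Accepts either a per-patient
# file with a `Group: DCM` line, or a mapping patient_id -> label. Bare `N`
# must stay a class label, not a YAML boolean, hence the handlers.
parse_label_file <- function(path, patient_id = NULL) {
  keep <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  y <- tryCatch(yaml::read_yaml(path, handlers = keep),
                error = function(e) NULL)
  if (is.null(y)) return("unknown")
  if (!is.null(y$Group)) return(as.character(y$Group))
  if (!is.null(patient_id) && !is.null(y[[patient_id]]))
    return(as.character(y[[patient_id]]))
  "unknown"
}

find_label <- function(nifti_path, patient_id) {
  dir <- dirname(nifti_path)
  for (cand in c(file.path(dir, "Info.cfg"),
                 file.path(dir, "labels.yaml"),
                 file.path(dirname(dir), "labels.yaml"))) {
    if (file.exists(cand)) {
      lab <- parse_label_file(cand, patient_id)
      if (lab != "unknown") return(lab)
    }
  }
  "unknown"
}

#' Read one short-axis slice of a 4D NIfTI cine volume
#'
#' Reads an ACDC-style 4D NIfTI file (dims x, y, slice, time) and extracts a
#' single slice as a [cine_sequence]. The diagnostic label is taken from an
#' `Info.cfg` (`Group: DCM` dialect) or `labels.yaml` file next to the volume
#' when present, else `"unknown"`.
#'
#' @param path Path to a readable `.nii` / `.nii.gz` file.
#' @param slice_index 0-based index along the slice axis.
#' @return A [cine_sequence] with `L` = number of temporal frames, raw
#'   intensities.
#' @export
read_cine_volume <- function(path, slice_index = 0L) {
  if (!file.exists(path)) stopf("cine volume not found: %s", path)
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) != 4L)
    stopf("expected a 4D NIfTI volume, got %dD (dims %s)",
          length(d), paste(d, collapse = "x"))
  if (slice_index < 0L || slice_index >= d[3])
    stopf("slice_index %d out of range [0, %d]", slice_index, d[3] - 1L)
  L <- d[4]
  frames <- array(0, dim = c(L, d[2], d[1]))  # (t, row=y, col=x)
  for (t in seq_len(L)) frames[t, , ] <- t(vol[, , slice_index + 1L, t])
  pid <- sub("\\.nii(\\.gz)?$", "", basename(path))
  pid <- sub("_4d$", "", pid)
  px <- tryCatch(RNifti::pixdim(vol)[1:2], error = function(e) NULL)
  cine_sequence(frames, patient_id = pid, slice_index = slice_index,
                label = find_label(path, pid), pixel_spacing = px)
}

#' Resample a cardiac cycle to a fixed number of frames
#'
#' Selects `target_len` frames at uniformly spaced original indices
#' (`round(linspace)`, ties half-up), always retaining the first and last
#' frame so end-diastole and end-systole are covered. Cycles shorter than
#' `target_len` are extended by nearest-index frame repetition, so the
#' operator is total.
#'
#' @param seq A [cine_sequence].
#' @param target_len Target number of frames (default 13).
#' @return A [cine_sequence] with exactly `target_len` frames;
#'   `frame_indices` records the selection in original-frame coordinates.
#' @export
resample_cycle <- function(seq, target_len = 13L) {
  stopifnot(inherits(seq, "cine_sequence"))
  if (target_len < 2L) stopf("target_len must be >= 2, got %d", target_len)
  L <- dim(seq$frames)[1]
  idx <- round_half_up(seq(0, L - 1, length.out = target_len)) + 1L
  out <- seq
  out$frames <- seq$frames[idx, , , drop = FALSE]
  out$frame_indices <- seq$frame_indices[idx]
  out
}

#' Spatially normalize cine frames to the network input geometry
#'
#' Center-crops each frame to a square (short side), resizes it to
#' `size x size` with bilinear interpolation, and min-max normalizes
#' intensities over the whole sequence to `[0, 1]`. A constant-intensity
#' sequence maps to all zeros.
#'
#' @param seq A [cine_sequence].
#' @param size Output side length in pixels (default 128).
#' @return A [cine_sequence] of shape `L x size x size` with intensities in
#'   `[0, 1]`.
#' @export
preprocess_frames <- function(seq, size = 128L) {
  stopifnot(inherits(seq, "cine_sequence"))
  d <- dim(seq$frames)
  L <- d[1]; H <- d[2]; W <- d[3]
  side <- min(H, W)
  r0 <- (H - side) %/% 2L
  c0 <- (W - side) %/% 2L
  out <- array(0, dim = c(L, size, size))
  for (t in seq_len(L)) {
    f <- seq$frames[t, (r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side)]
    out[t, , ] <- if (side == size) f else resize_bilinear(f, size, size)
  }
  lo <- min(out); hi <- max(out)
  out <- if (hi - lo < 1e-12) array(0, dim(out)) else (out - lo) / (hi - lo)
  res <- seq
  res$frames <- out
  res
}
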