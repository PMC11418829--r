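#' Phantom generation parameters
#'
#' Parameters of the beating-annulus cine phantom. The inner radius follows a
#' single-harmonic cycle `r(t) = r_es + (r_ed - r_es) * (1 + cos(2*pi*t/(n-1))) / 2`
#' so end-diastole (t = 0 and t = n-1) and end-systole (mid-cycle) are
#' analytically known. The wall carries a material-coordinate texture
#' (patient-specific random sinusoid phases) so dense optical flow can recover
#' both radial contraction and rotational twist.
#'
#' @param image_size Frame side length in pixels.
#' @param n_frames Number of temporal frames (>= 3).
#' @param inner_radius_ed,inner_radius_es Inner radius (px) at end-diastole /
#'   end-systole; `inner_radius_es <= inner_radius_ed`.
#' @param wall_thickness Myocardial wall thickness in px (> 0).
#' @param twist_deg_per_frame Cumulative rotation of the wall, degrees/frame.
#' @param akinetic_sector Optional `(start, end)` angles in degrees; within
#'   this sector the wall is frozen at its end-diastolic geometry
#'   (infarct-like regional akinesia).
#' @param second_cavity Logical; add a second, hypokinetic cavity (abnormal
#'   right ventricle signature).
#' @param noise_sd Additive Gaussian intensity noise (image units in [0,1]).
#' @param seed Integer seed; phantoms are bit-reproducible given the seed.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 128L, n_frames = 13L,
                           inner_radius_ed = 30, inner_radius_es = 18,
                           wall_thickness = 10, twist_deg_per_frame = 2,
                           akinetic_sector = NULL, second_cavity = FALSE,
                           noise_sd = 0, seed = 1L) {
  if (n_frames < 3L) stopf("n_frames must be >= 3")
  if (wall_thickness <= 0) stopf("wall_thickness must be > 0")
  if (inner_radius_es > inner_radius_ed)
    stopf("inner_radius_es must be <= inner_radius_ed")
  structure(list(image_size = as.integer(image_size),
                 n_frames = as.integer(n_frames),
                 inner_radius_ed = inner_radius_ed,
                 inner_radius_es = inner_radius_es,
                 wall_thickness = wall_thickness,
                 twist_deg_per_frame = twist_deg_per_frame,
                 akinetic_sector = akinetic_sector,
                 second_cavity = second_cavity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Class presets for the phantom generator
#'
#' Kinematic signatures of the five cardiac conditions, expressed for a
#' 128-px frame and scaled proportionally for other sizes:
#' * `N` - strong contraction, moderate twist;
#' * `MINF` - normal geometry with a 120-degree akinetic sector;
#' * `DCM` - dilated (large radii), contraction amplitude < 25% of normal;
#' * `HCM` - wall at least twice as thick as normal, normal contraction;
#' * `RV` - dilated, hypokinetic, with a second cavity.
#'
#' @param label One of `"MINF"`, `"DCM"`, `"HCM"`, `"RV"`, `"N"`.
#' @param image_size Frame side length in pixels.
#' @param n_frames Number of temporal frames.
#' @param noise_sd Additive Gaussian noise level.
#' @param seed Integer seed.
#' @return A [phantom_params] object.
#' @export
phantom_presets <- function(label, image_size = 128L, n_frames = 13L,
                            noise_sd = 0, seed = 1L) {
  s <- image_size / 128
  base <- switch(label,
    N    = list(ed = 30,  es = 18,   wall = 10, twist = 2,   sector = NULL, cav2 = FALSE),
    MINF = list(ed = 30,  es = 18,   wall = 10, twist = 2,   sector = c(-60, 60), cav2 = FALSE),
    DCM  = list(ed = 42,  es = 39.5, wall = 7,  twist = 0.5, sector = NULL, cav2 = FALSE),
    HCM  = list(ed = 26,  es = 14,   wall = 20, twist = 2,   sector = NULL, cav2 = FALSE),
    RV   = list(ed = 34,  es = 31,   wall = 8,  twist = 0.5, sector = NULL, cav2 = TRUE),
    stopf("unknown phantom label '%s'", label))
  phantom_params(image_size = image_size, n_frames = n_frames,
                 inner_radius_ed = base$ed * s, inner_radius_es = base$es * s,
                 wall_thickness = base$wall * s,
                 twist_deg_per_frame = base$twist,
                 akinetic_sector = base$sector, second_cavity = base$cav2,
                 noise_sd = noise_sd, seed = seed)
}

# Smoothstep on angular distance: 1 outside the akinetic sector, 0 inside,
# smooth over a `trans`-degree transition band.
sector_weight <- function(theta_deg, sector, trans = 8) {
  if (is.null(sector)) return(rep(1, length(theta_deg)))
  # signed angular position relative to sector, wrapped to (-180, 180]
  wrap <- function(a) ((a + 180) %% 360) - 180
  mid <- (sector[1] + sector[2]) / 2
  half <- abs(wrap(sector[2] - sector[1])) / 2
  d <- abs(wrap(theta_deg - mid)) - half   # <0 inside sector
  t <- pmin(pmax(d / trans, 0), 1)
  t * t * (3 - 2 * t)
}

render_annulus <- function(rho, theta, r_in, wall, twist_rad, tex_par,
                           edge = 0.75) {
  s_in <- 1 / (1 + exp(-(rho - r_in) / edge))
  s_out <- 1 / (1 + exp(-(r_in + wall - rho) / edge))
  mask <- s_in * s_out
  depth <- pmin(pmax(rho - r_in, 0), wall)
  th_m <- theta - twist_rad
  tex <- 0.5 +
    0.25 * sin(tex_par$k1 * th_m + tex_par$p1) +
    0.25 * sin(2 * pi * tex_par$k2 * depth / wall + tex_par$p2) *
           cos(tex_par$k3 * th_m + tex_par$p3)
  mask * (0.45 + 0.5 * pmin(pmax(tex, 0), 1))
}

#' Generate a beating-annulus cine phantom
#'
#' Renders a bright textured annulus on a dark background whose inner radius
#' follows a cosine cycle (ED at frame 0, ES at mid-cycle), rotated by a
#' cumulative twist. When `params$akinetic_sector` is set, the sector is
#' frozen at its end-diastolic geometry. Deterministic given `params$seed`.
#'
#' @param label Cardiac class, one of `"MINF"`, `"DCM"`, `"HCM"`, `"RV"`,
#'   `"N"`; defaults for the class come from [phantom_presets] unless
#'   `params` is supplied.
#' @param params A [phantom_params]; defaults to `phantom_presets(label)`.
#' @param patient_id,slice_index Metadata passed to the [cine_sequence].
#' @return A [cine_sequence] with `params$n_frames` frames and the given
#'   label.
#' @export
generate_phantom <- function(label, params = phantom_presets(label),
                             patient_id = paste0("phantom_", label),
                             slice_index = 0L) {
  if (!label %in% CARDIAC_CLASSES) stopf("unknown phantom label '%s'", label)
  stopifnot(inherits(params, "phantom_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  tex_par <- list(k1 = sample(4:9, 1), k2 = runif(1, 1, 2.5),
                  k3 = sample(3:7, 1), p1 = runif(1, 0, 2 * pi),
                  p2 = runif(1, 0, 2 * pi), p3 = runif(1, 0, 2 * pi))
  tex2 <- list(k1 = sample(3:6, 1), k2 = runif(1, 1, 2), k3 = sample(2:5, 1),
               p1 = runif(1, 0, 2 * pi), p2 = runif(1, 0, 2 * pi),
               p3 = runif(1, 0, 2 * pi))
  bg_phase <- runif(2, 0, 2 * pi)

  n <- params$n_frames
  sz <- params$image_size
  cx <- (sz + 1) / 2; cy <- (sz + 1) / 2
  X <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - cx
  Y <- matrix(seq_len(sz), sz, sz) - cy
  rho <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  theta_deg <- theta * 180 / pi
  w_sec <- matrix(sector_weight(as.vector(theta_deg), params$akinetic_sector),
                  sz, sz)
  bg <- 0.08 + 0.02 * sin(rho / 9 + bg_phase[1]) * cos(theta * 2 + bg_phase[2])

  r_ed <- params$inner_radius_ed; r_es <- params$inner_radius_es
  wall <- params$wall_thickness
  frames <- array(0, dim = c(n, sz, sz))
  for (t0 in seq_len(n) - 1L) {
    phase <- (1 + cos(2 * pi * t0 / (n - 1))) / 2
    r_t <- r_es + (r_ed - r_es) * phase
    tw_t <- params$twist_deg_per_frame * t0 * pi / 180
    # akinetic sector stays at ED geometry (r_ed, zero twist)
    r_eff <- w_sec * r_t + (1 - w_sec) * r_ed
    tw_eff <- w_sec * tw_t
    img <- render_annulus(rho, theta, r_eff, wall, tw_eff, tex_par)
    if (params$second_cavity) {
      off <- r_ed + 0.15 * sz
      rho2 <- sqrt((X + off)^2 + Y^2)
      theta2 <- atan2(Y, X + off)
      r2 <- (0.11 * sz) - (0.01 * sz) * (1 - phase)   # mildly contracting
      img2 <- render_annulus(rho2, theta2, r2, 0.05 * sz, tw_t * 0.25, tex2)
      img <- pmax(img, img2)
    }
    img <- bg * (img < 0.1) + pmax(img, bg * (img >= 0.1))
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(sz * sz, 0, params$noise_sd), sz, sz)
    frames[t0 + 1L, , ] <- pmin(pmax(img, 0), 1)
  }
  cine_sequence(frames, patient_id = patient_id, slice_index = slice_index,
                label = label)
}

#' Generate a balanced phantom cohort
#'
#' Draws `n_per_class` phantoms for each of the five cardiac classes with
#' per-patient parameter jitter (uniform +/-10% on radii, contraction
#' amplitude, wall thickness and twist) from seeded substreams, mirroring a
#' balanced multi-condition cohort.
#'
#' @param n_per_class Phantoms per class (>= 1).
#' @param seed Master seed; each phantom gets its own derived substream.
#' @param image_size,n_frames,noise_sd Forwarded to [phantom_presets].
#' @return A list of `5 * n_per_class` [cine_sequence] objects with unique
#'   patient ids and balanced labels.
#' @export
generate_cohort <- function(n_per_class, seed = 1L, image_size = 128L,
                            n_frames = 13L, noise_sd = 0) {
  if (n_per_class < 1L) stopf("n_per_class must be >= 1")
  total <- 5L * n_per_class
  sub <- derive_seeds(seed, 2L * total)
  jit_seeds <- sub[seq_len(total)]
  gen_seeds <- sub[total + seq_len(total)]
  cohort <- vector("list", total)
  k <- 0L
  for (lab in CARDIAC_CLASSES) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      p <- phantom_presets(lab, image_size = image_size, n_frames = n_frames,
                           noise_sd = noise_sd, seed = gen_seeds[k])
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(jit_seeds[k])
      j <- runif(4, 0.9, 1.1)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      amp <- (p$inner_radius_ed - p$inner_radius_es) * j[2]
      p$inner_radius_ed <- p$inner_radius_ed * j[1]
      p$inner_radius_es <- max(p$inner_radius_ed - amp, 1)
      p$wall_thickness <- p$wall_thickness * j[3]
      p$twist_deg_per_frame <- p$twist_deg_per_frame * j[4]
      cohort[[k]] <- generate_phantom(lab, p,
                                      patient_id = sprintf("patient%03d", k))
    }
  }
  cohort
}

#' Write a phantom cohort as an ACDC-style dataset
#'
#' Writes one directory per patient containing a 4D NIfTI volume
#' (`<id>_4d.nii.gz`, dims x, y, slice=1, time) and an `Info.cfg` with a
#' `Group: <label>` line -- exactly the dialect [read_cine_volume] reads.
#'
#' @param cohort List of [cine_sequence] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written NIfTI paths.
#' @export
write_phantom_dataset <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    d <- dim(s$frames)
    pdir <- file.path(dir, s$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    vol <- array(0, dim = c(d[3], d[2], 1L, d[1]))  # (x, y, slice, t)
    for (t in seq_len(d[1])) vol[, , 1L, t] <- t(s$frames[t, , ])
    paths[i] <- file.path(pdir, paste0(s$patient_id, "_4d.nii.gz"))
    RNifti::writeNifti(vol, paths[i])
    writeLines(c(paste0("Group: ", s$label), paste0("NbFrame: ", d[1])),
               file.path(pdir, "Info.cfg"))
  }
  invisible(paths)
}
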