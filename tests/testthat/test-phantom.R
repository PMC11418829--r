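# Beating-annulus phantom generator: cycle geometry, class signatures,
# determinism, cohort structure.

test_that("the cosine cycle returns to end-diastolic geometry at the last frame", {
  p <- phantom_presets("N", noise_sd = 0)
  p$twist_deg_per_frame <- 0                   # isolate the radial cycle
  ph <- generate_phantom("N", p)
  n <- dim(ph$frames)[1]
  expect_equal(ph$frames[1, , ], ph$frames[n, , ], tolerance = 1e-10)
  # mid-cycle (ES) annulus is smaller: fewer bright pixels than at ED
  es <- which.min(sapply(seq_len(n), function(t) sum(ph$frames[t, , ] > 0.3)))
  expect_equal(es, (n + 1) %/% 2)
  expect_lt(sum(ph$frames[es, , ] > 0.3), sum(ph$frames[1, , ] > 0.3))
})

test_that("phantoms are bit-identical given the same parameters and seed", {
  p <- phantom_presets("HCM", noise_sd = 0.02, seed = 9)
  expect_identical(generate_phantom("HCM", p)$frames,
                   generate_phantom("HCM", p)$frames)
  p2 <- phantom_presets("HCM", noise_sd = 0.02, seed = 10)
  expect_false(identical(generate_phantom("HCM", p)$frames,
                         generate_phantom("HCM", p2)$frames))
})

test_that("dilated-weak phantoms move less than normal ones over the wall band", {
  band_change <- function(lab) {
    ph <- generate_phantom(lab, phantom_presets(lab, noise_sd = 0, seed = 4))
    n <- dim(ph$frames)[1]
    # wall band: pixels bright in any frame
    band <- apply(ph$frames, c(2, 3), max) > 0.3
    mean(sapply(seq_len(n - 1), function(t)
      mean(abs(ph$frames[t + 1, , ] - ph$frames[t, , ])[band])))
  }
  expect_lt(band_change("DCM"), band_change("N"))
})

test_that("phantom parameter invariants are enforced", {
  expect_error(phantom_params(inner_radius_ed = 10, inner_radius_es = 12),
               "inner_radius_es")
  expect_error(phantom_params(wall_thickness = 0), "wall_thickness")
  expect_error(phantom_params(n_frames = 2), "n_frames")
  expect_error(generate_phantom("XYZ"), "unknown")
  # preset relations: HCM wall >= 2x normal, DCM amplitude < 25% of normal
  pn <- phantom_presets("N"); ph <- phantom_presets("HCM")
  pd <- phantom_presets("DCM")
  expect_gte(ph$wall_thickness, 2 * pn$wall_thickness)
  expect_lt(pd$inner_radius_ed - pd$inner_radius_es,
            0.25 * (pn$inner_radius_ed - pn$inner_radius_es))
})

test_that("generate_cohort is balanced with unique patients and seed-dependent jitter", {
  co <- generate_cohort(4, seed = 3, image_size = 32)
  expect_length(co, 20)
  labs <- sapply(co, function(s) s$label)
  expect_equal(unname(table(labs)[c("MINF", "DCM", "HCM", "RV", "N")]),
               rep(4L, 5), ignore_attr = TRUE)
  ids <- sapply(co, function(s) s$patient_id)
  expect_length(unique(ids), 20)
  co2 <- generate_cohort(4, seed = 4, image_size = 32)
  expect_false(identical(co[[1]]$frames, co2[[1]]$frames))
  # same seed reproduces the cohort exactly
  co3 <- generate_cohort(4, seed = 3, image_size = 32)
  expect_identical(co[[7]]$frames, co3[[7]]$frames)
})

test_that("wall divergence during contraction is negative for N but near zero in the MINF akinetic sector", {
  # same end-diastolic wall band for both classes: for N the wall contracts
  # away through it, for MINF the akinetic sector's wall stays frozen in it
  p <- phantom_presets("N")
  rmin <- p$inner_radius_ed + 2
  rmax <- p$inner_radius_ed + p$wall_thickness - 2
  div_in_band <- function(lab, th_lim) {
    ph <- generate_phantom(lab, phantom_presets(lab, noise_sd = 0, seed = 2))
    pp <- preprocess_frames(ph, 128)
    sz <- 128; cc <- (sz + 1) / 2
    X <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - cc
    Y <- matrix(seq_len(sz), sz, sz) - cc
    rho <- sqrt(X^2 + Y^2); th <- atan2(Y, X) * 180 / pi
    mask <- rho > rmin & rho < rmax & th > -th_lim & th < th_lim
    mean(sapply(1:5, function(t) {        # contraction phase: ED -> ES
      fl <- estimate_flow_pair(pp$frames[t, , ], pp$frames[t + 1, , ])
      mean(divergence_map(fl)[mask])
    }))
  }
  d_n <- div_in_band("N", 180)            # moving wall, all angles
  d_minf <- div_in_band("MINF", 40)       # frozen akinetic sector interior
  expect_lt(d_n, 0)
  expect_gte(abs(d_n), 3 * abs(d_minf))
})

test_that("phantom datasets round-trip through the ACDC-style reader", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(1, seed = 6, image_size = 32)
  paths <- write_phantom_dataset(co, dir)
  expect_length(paths, 5)
  back <- read_cine_volume(paths[1], 0L)
  expect_equal(back$label, co[[1]]$label)
  expect_equal(back$patient_id, co[[1]]$patient_id)
  expect_equal(dim(back$frames), dim(co[[1]]$frames))
  expect_equal(back$frames, co[[1]]$frames, tolerance = 1e-6)
})
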