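# Kinematic operators: closed forms, oracle equivalence, decomposition,
# linearity, rotation equivariance, and stack assembly.

grid_xy <- function(n) {
  cc <- (n + 1) / 2
  list(x = matrix(seq_len(n), n, n, byrow = TRUE) - cc,
       y = matrix(seq_len(n), n, n) - cc)
}

test_that("divergence and vorticity match closed forms on canonical fields", {
  g <- grid_xy(32)
  # uniform expansion u = 0.1 x, v = 0.1 y -> div 0.2, vor 0 everywhere
  exp_field <- flow_field(0.1 * g$x, 0.1 * g$y)
  expect_equal(divergence_map(exp_field), matrix(0.2, 32, 32),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(vorticity_map(exp_field), matrix(0, 32, 32),
               tolerance = 1e-6, ignore_attr = TRUE)
  # rigid rotation u = -w y, v = w x -> div 0, vor 2w
  w <- 0.05
  rot <- flow_field(-w * g$y, w * g$x)
  expect_equal(divergence_map(rot), matrix(0, 32, 32),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(vorticity_map(rot), matrix(0.10, 32, 32),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("operators equal the brute-force per-pixel oracle exactly on smooth random fields", {
  for (seed in 1:3) {
    u <- smooth_field(16, seed = seed)
    v <- smooth_field(16, seed = seed + 50)
    fl <- flow_field(u, v)
    expect_identical(divergence_map(fl), oracle_div(u, v))
    expect_identical(vorticity_map(fl), oracle_vor(u, v))
  }
})

test_that("divergence and vorticity are linear in the field", {
  u1 <- smooth_field(16, 1); v1 <- smooth_field(16, 2)
  u2 <- smooth_field(16, 3); v2 <- smooth_field(16, 4)
  a <- 1.7; b <- -0.6
  lhs <- divergence_map(flow_field(a * u1 + b * u2, a * v1 + b * v2))
  rhs <- a * divergence_map(flow_field(u1, v1)) +
    b * divergence_map(flow_field(u2, v2))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  lhs_v <- vorticity_map(flow_field(a * u1 + b * u2, a * v1 + b * v2))
  rhs_v <- a * vorticity_map(flow_field(u1, v1)) +
    b * vorticity_map(flow_field(u2, v2))
  expect_equal(lhs_v, rhs_v, tolerance = 1e-12)
})

test_that("a 90-degree grid rotation of the field rotates the divergence map", {
  u <- smooth_field(16, 7); v <- smooth_field(16, 8)
  d0 <- divergence_map(flow_field(u, v))
  # rotate grid 90 deg counterclockwise in (x right, y down) coordinates:
  # position (row, col) -> (n+1-col, row); vector (u, v) -> (v, -u)
  rot_mat <- function(m) t(m)[rev(seq_len(ncol(m))), ]
  d1 <- divergence_map(flow_field(rot_mat(v), -rot_mat(u)))
  inner <- 2:15
  expect_equal(d1[inner, inner], rot_mat(d0)[inner, inner], tolerance = 1e-6)
})

test_that("acceleration decomposition matches closed forms", {
  n <- 8
  cst <- flow_field(matrix(1, n, n), matrix(0, n, n))
  # constant velocity -> zero acceleration
  acc <- acceleration_maps(cst, cst)
  expect_true(all(acc$a_T == 0) && all(acc$a_N == 0))
  # pure speed-up along (1, 0): 1 -> 2 px/frame
  acc <- acceleration_maps(cst, flow_field(matrix(2, n, n), matrix(0, n, n)))
  expect_equal(acc$a_T, matrix(1, n, n), tolerance = 1e-12)
  expect_equal(acc$a_N, matrix(0, n, n), tolerance = 1e-12)
  # constant-speed direction rotation, s = 2, theta = 0.1 rad:
  # a_T = s (cos th - 1), a_N = s |sin th|   [closed form from the definition]
  s <- 2; th <- 0.1
  f0 <- flow_field(matrix(s, n, n), matrix(0, n, n))
  f1 <- flow_field(matrix(s * cos(th), n, n), matrix(s * sin(th), n, n))
  acc <- acceleration_maps(f0, f1)
  expect_equal(acc$a_N, matrix(s * abs(sin(th)), n, n), tolerance = 1e-6)
  expect_equal(acc$a_T, matrix(s * (cos(th) - 1), n, n), tolerance = 1e-6)
})

test_that("a_T^2 + a_N^2 equals |dv/dt|^2 wherever speed >= eps", {
  eps <- 1e-3
  for (seed in 1:3) {
    f0 <- flow_field(smooth_field(16, seed), smooth_field(16, seed + 10))
    f1 <- flow_field(smooth_field(16, seed + 20), smooth_field(16, seed + 30))
    acc <- acceleration_maps(f0, f1, eps)
    sp <- sqrt(f0$u^2 + f0$v^2)
    a2 <- (f1$u - f0$u)^2 + (f1$v - f0$v)^2
    ok <- sp >= eps
    expect_equal((acc$a_T^2 + acc$a_N^2)[ok], a2[ok], tolerance = 1e-9)
    expect_true(all(acc$a_N >= 0))
    expect_true(all(acc$a_T[!ok] == 0) && all(acc$a_N[!ok] == 0))
  }
})

make_flow_seq <- function(Tn, n = 16, seed = 1, zero = FALSE) {
  fields <- lapply(seq_len(Tn), function(t)
    if (zero) flow_field(matrix(0, n, n), matrix(0, n, n))
    else flow_field(smooth_field(n, seed + t), smooth_field(n, seed + 100 + t)))
  structure(list(fields = fields, patient_id = "p", slice_index = 0L,
                 label = "N", config = flow_config()),
            class = "flow_sequence")
}

test_that("kinematic stacks have the requested channels in order, standardized", {
  fs <- make_flow_seq(12)
  st <- build_kinematic_stack(fs, c("a_N", "div", "vor"))
  expect_identical(dim(st$data), c(12L, 16L, 16L, 3L))
  expect_identical(st$channel_names, c("a_N", "div", "vor"))
  for (c in 1:3) {
    expect_equal(mean(st$data[, , , c]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(st$data[, , , c])), 1, tolerance = 1e-10)
  }
  st2 <- build_kinematic_stack(fs, c("u", "v"))
  expect_identical(dim(st2$data), c(12L, 16L, 16L, 2L))
  expect_error(build_kinematic_stack(fs, c("div", "curl")), "unknown channel")
  expect_error(build_kinematic_stack(fs, character(0)), "non-empty")
})

test_that("acceleration channels pair consecutive fields and repeat the last pair", {
  fs <- make_flow_seq(5)
  st <- build_kinematic_stack(fs, "a_N")
  # reconstruct without standardization
  raw <- sapply(1:5, function(t) {
    t0 <- min(t, 4)
    acceleration_maps(fs$fields[[t0]], fs$fields[[t0 + 1]])$a_N
  }, simplify = "array")
  mu <- mean(raw); s <- sd(as.vector(raw))
  for (t in 1:5)
    expect_equal(st$data[t, , , 1], (raw[, , t] - mu) / s, tolerance = 1e-12)
  # last time index equals the second-to-last (repeated pair)
  expect_equal(st$data[5, , , 1], st$data[4, , , 1])
})

test_that("all-zero flow produces an all-zero stack", {
  fs <- make_flow_seq(12, zero = TRUE)
  st <- build_kinematic_stack(fs, c("u", "v", "div", "vor", "a_N", "a_T"))
  expect_true(all(st$data == 0))
})
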