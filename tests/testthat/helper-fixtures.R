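# Fixtures built in code: textured images, analytic flow fields, phantom
# kinematic stacks, and brute-force finite-difference oracles.

textured_image <- function(n = 128, seed = 1, sigma = 3) {
  set.seed(seed)
  img <- matrix(rnorm(n * n), n, n)
  img <- EBImage::gblur(img, sigma)
  (img - min(img)) / (max(img) - min(img))
}

shift_cols <- function(img, k) {
  n <- ncol(img)
  img[, ((seq_len(n) - 1 - k) %% n) + 1]
}

# smooth seeded random flow component
smooth_field <- function(n = 16, seed = 1, sigma = 2, amp = 1) {
  set.seed(seed)
  amp * EBImage::gblur(matrix(rnorm(n * n), n, n), sigma)
}

# Brute-force per-pixel central/one-sided difference oracles, written as
# explicit loops, independent of the vectorized operators under test.
oracle_dx <- function(m) {
  H <- nrow(m); W <- ncol(m)
  g <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    g[i, j] <- if (j == 1) m[i, 2] - m[i, 1]
    else if (j == W) m[i, W] - m[i, W - 1]
    else (m[i, j + 1] - m[i, j - 1]) / 2
  }
  g
}
oracle_dy <- function(m) t(oracle_dx(t(m)))
oracle_div <- function(u, v) oracle_dx(u) + oracle_dy(v)
oracle_vor <- function(u, v) oracle_dx(v) - oracle_dy(u)

# reduced-width network config for fast unit tests
tiny_net <- function(epochs = 3L)
  conv3d_config(epochs = epochs, filters = c(8L, 16L, 32L, 32L, 32L),
                dense_units = c(256L, 256L))

# phantom -> preprocessed -> flow -> single/multi channel stack
phantom_stack <- function(label, seed, channels = "div", size = 32L,
                          pid = sprintf("%s%03d", label, seed)) {
  p <- phantom_presets(label, image_size = size, noise_sd = 0, seed = seed)
  ph <- generate_phantom(label, p, patient_id = pid)
  pp <- preprocess_frames(resample_cycle(ph, 13L), size)
  build_kinematic_stack(estimate_flow_sequence(pp), channels,
                        frames = pp$frames)
}

# memoized separable toy problem shared by several conv3d tests
.toy_cache <- new.env(parent = emptyenv())
toy_problem <- function() {
  if (is.null(.toy_cache$stacks)) {
    .toy_cache$stacks <- c(
      lapply(1:8, function(i) phantom_stack("N", 100 + i)),
      lapply(1:8, function(i) phantom_stack("DCM", 200 + i)))
    .toy_cache$labels <- rep(c("N", "DCM"), each = 8)
  }
  list(stacks = .toy_cache$stacks, labels = .toy_cache$labels)
}

# net trained on the toy problem, shared across assertion blocks
toy_net <- function() {
  if (is.null(.toy_cache$net)) {
    toy <- toy_problem()
    .toy_cache$net <- train_binary(toy$stacks, toy$labels,
                                   tiny_net(epochs = 20L), seed = 0)
  }
  .toy_cache$net
}

# well-separated Gaussian clusters as plain descriptor matrices
gaussian_clusters <- function(n_per = 20, d = 3072, seed = 1, sep = 1,
                              sd = 0.1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, -sep, sd), n_per, d),
             matrix(rnorm(n_per * d, sep, sd), n_per, d))
  list(X = X, labels = rep(c("a", "b"), each = n_per))
}
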