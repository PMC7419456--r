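# Shared fixtures. Heavyweight objects (textures, small rendered datasets)
# are built once per test run and memoized here.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

normalize_vec_test <- function(v) v / sqrt(sum(v^2))
deg2rad_test <- function(d) d * pi / 180
to_gray_test <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# uniformly random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# independent brute-force label computation: full 4x4 change of basis of
# the placenta z direction into camera coordinates
oracle_label <- function(camera_pose, normal_into_cavity) {
  p_z_w <- c(-normal_into_cavity, 0)           # direction, homogeneous
  v <- solve(camera_pose) %*% p_z_w
  c(v[1], v[2])
}

small_texture <- function(seed = 1) memo(paste0("tex", seed), {
  generate_texture(seed, size_px = 256L)
})

# a small rendered dataset shared across dataset/estimator tests
tiny_dataset <- function() memo("tiny_ds", {
  cfg <- render_config(resolution = 100L)
  generate_dataset(list(small_texture(1), small_texture(2)),
                   trajectory_spec("conical", n = 24L), cfg, seed = 42L)
})

toy_network_spec <- function() {
  network_spec(input_px = 100L, conv_channels = c(4L, 8L, 8L, 8L),
               fc_units = c(32L, 16L))
}
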