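# Procedural placenta-like textures. These stand in for ex-vivo placenta
# photographs as surface textures for the synthetic scene generator: a
# reddish chorionic-plate base with low-frequency mottling and branching,
# darker vessel-like curves of decreasing width.

#' Generate a procedural placenta-like texture
#'
#' Deterministic for a fixed seed. The texture is an RGB raster with a
#' reddish mottled base and a branching tree of darker vessel-like curves,
#' emulating the appearance of the chorionic plate. It is synthetic: it
#' reproduces the color statistics and vessel-like structure a fetoscopic
#' view shows, not any real patient anatomy.
#'
#' @param seed integer RNG seed.
#' @param size_px square texture side in pixels (>= 256).
#' @return A `size_px` x `size_px` x 3 array in [0, 1].
#' @export
generate_texture <- function(seed = 1L, size_px = 512L) {
  stopifnot(size_px >= 256L)
  with_preserved_seed(seed, {
    n1 <- octave_noise(size_px, c(6, 12, 24, 48), c(1, 0.6, 0.35, 0.2))
    n2 <- octave_noise(size_px, c(8, 16, 32), c(1, 0.5, 0.3))
    base_r <- clamp01(0.52 + 0.16 * n1)
    base_g <- clamp01(0.17 + 0.08 * n2 + 0.04 * n1)
    base_b <- clamp01(0.14 + 0.06 * n2)
    vess <- vessel_mask(size_px)
    vcol <- c(0.24, 0.05, 0.07)  # dark venous red
    tex <- array(0, c(size_px, size_px, 3))
    tex[, , 1] <- base_r * (1 - vess) + vcol[1] * vess
    tex[, , 2] <- base_g * (1 - vess) + vcol[2] * vess
    tex[, , 3] <- base_b * (1 - vess) + vcol[3] * vess
    # specular-ish sheen spots from amnion: sparse bright mottling
    sheen <- clamp01(octave_noise(size_px, c(40), c(1)) - 1.1) * 2
    for (k in 1:3) tex[, , k] <- clamp01(tex[, , k] + 0.25 * sheen)
    tex
  })
}

# Sum of bilinearly upscaled white-noise grids ("value noise"), roughly
# standardized to sd 1.
octave_noise <- function(size, grids, weights) {
  acc <- matrix(0, size, size)
  for (i in seq_along(grids)) {
    g <- matrix(rnorm(grids[i]^2), grids[i], grids[i])
    acc <- acc + weights[i] * bilinear_upscale(g, size)
  }
  acc / sqrt(sum(weights^2))
}

bilinear_upscale <- function(g, size) {
  n <- nrow(g)
  # sample positions mapped into [1, n]
  p <- seq(1, n, length.out = size)
  i0 <- pmin(floor(p), n - 1L); f <- p - i0
  rows <- g[i0, , drop = FALSE] * (1 - f) + g[i0 + 1L, , drop = FALSE] * f
  rows[, i0, drop = FALSE] * rep(1 - f, each = size) +
    rows[, i0 + 1L, drop = FALSE] * rep(f, each = size)
}

# Branching random-walk vessel tree rendered as a soft coverage mask in
# [0, 1]. Draws each centerline point as a radially feathered disc.
vessel_mask <- function(size) {
  mask <- matrix(0, size, size)
  n_trunks <- sample(5:7, 1)
  queue <- list()
  for (i in seq_len(n_trunks)) {
    side <- sample(4, 1)
    pos <- switch(side,
      c(1, runif(1, 1, size)),
      c(size, runif(1, 1, size)),
      c(runif(1, 1, size), 1),
      c(runif(1, 1, size), size))
    dir <- atan2(size / 2 - pos[2], size / 2 - pos[1]) + runif(1, -0.4, 0.4)
    queue[[length(queue) + 1]] <-
      list(pos = pos, dir = dir, width = runif(1, size / 90, size / 60),
           steps = round(runif(1, 0.5, 0.9) * size / 2), depth = 0)
  }
  while (length(queue) > 0) {
    seg <- queue[[1]]; queue[[1]] <- NULL
    pos <- seg$pos; dir <- seg$dir; w <- seg$width
    for (s in seq_len(seg$steps)) {
      dir <- dir + rnorm(1, 0, 0.09)
      pos <- pos + 2 * c(cos(dir), sin(dir))
      if (any(pos < 1) || any(pos > size)) break
      mask <- stamp_disc(mask, pos, w)
      w <- w * 0.9985
      if (seg$depth < 3 && runif(1) < 0.012 && w > 1.2) {
        queue[[length(queue) + 1]] <-
          list(pos = pos, dir = dir + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1),
               width = w * runif(1, 0.5, 0.7),
               steps = round(seg$steps * 0.6), depth = seg$depth + 1)
      }
    }
  }
  clamp01(mask)
}

stamp_disc <- function(mask, pos, w) {
  size <- nrow(mask)
  r <- ceiling(w + 1)
  xs <- max(1, floor(pos[1] - r)):min(size, ceiling(pos[1] + r))
  ys <- max(1, floor(pos[2] - r)):min(size, ceiling(pos[2] + r))
  d2 <- outer((ys - pos[2])^2, (xs - pos[1])^2, `+`)
  cov <- clamp01(1.4 * (1 - sqrt(d2) / w))
  mask[ys, xs] <- pmax(mask[ys, xs], cov)
  mask
}
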