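# Synthetic fetoscopic scene generator. The scene is a finite textured
# plane (the placenta is locally planar at fetoscopic working distances)
# viewed by a pinhole camera that carries its own light source, as in a
# fetoscope where the illumination fiber is fixed with respect to the
# camera. Shading combines a spotlight cone around the optical axis, a
# Lambertian surface term and inverse-square distance falloff: it is this
# projected-light-cone pattern that carries the orientation information the
# estimator learns to read. Every rendered image is emitted jointly with
# its exact ground-truth inclination label.

#' Placental surface description
#'
#' A finite textured plane with an explicit into-cavity normal and an
#' in-plane coordinate frame (u, v) used for texture mapping and for tip
#' projection coordinates.
#'
#' @param texture RGB array or grayscale matrix mapped over the extent.
#' @param extent_mm physical side length of the textured patch.
#' @param center world position of the patch center (mm).
#' @param normal_into_cavity unit normal pointing into the cavity (towards
#'   the camera side).
#' @return A `placenta_surface` list.
#' @export
placenta_surface <- function(texture, extent_mm = 80,
                             center = c(0, 0, 0),
                             normal_into_cavity = c(0, 0, 1)) {
  n <- normalize_vec(normal_into_cavity)
  a <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- normalize_vec(a - sum(a * n) * n)
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])  # n x u, so (u, v, n) is right-handed
  structure(list(texture = texture, extent_mm = extent_mm, center = center,
                 normal = n, u = u, v = v),
            class = "placenta_surface")
}

#' Illumination model
#'
#' A spotlight carried by the camera (co-located with the camera origin by
#' default), attenuated smoothly towards the cone edge, plus a small ambient
#' floor emulating stray light.
#'
#' @param offset_mm emitter offset in the camera frame.
#' @param cone_half_angle_deg spotlight half-angle, in (0, 90].
#' @param falloff exponent shaping the within-cone attenuation.
#' @param ambient ambient floor as a fraction of full reflectance, in
#'   [0, 0.2].
#' @return A `light_model` list.
#' @export
light_model <- function(offset_mm = c(0, 0, 0), cone_half_angle_deg = 50,
                        falloff = 1.2, ambient = 0.02) {
  stopifnot(cone_half_angle_deg > 0, cone_half_angle_deg <= 90,
            ambient >= 0, ambient <= 0.2)
  structure(list(offset_mm = offset_mm,
                 cone_half_angle_deg = cone_half_angle_deg,
                 falloff = falloff, ambient = ambient),
            class = "light_model")
}

#' Rendering configuration
#'
#' @param resolution square output resolution in pixels (>= 64).
#' @param fov_deg full field of view in degrees.
#' @param d_range camera-to-surface distance range in mm, `c(min, max)`.
#' @param r_max maximum label component magnitude sampled by trajectories.
#' @param exposure radiometric scale; with the default the image saturates
#'   softly at close range and stays visible at the far end of `d_range`.
#' @param channels `"gray"` renders luminance directly; `"rgb"` keeps the
#'   texture's channels.
#' @param noise_sd additive Gaussian sensor noise (0 disables).
#' @param vignetting strength of radial sensor vignetting (0 disables).
#' @param seed seed for the noise model.
#' @return A `render_config` list.
#' @export
render_config <- function(resolution = 200L, fov_deg = 90,
                          d_range = c(10, 50), r_max = 0.6,
                          exposure = 900, channels = c("gray", "rgb"),
                          noise_sd = 0, vignetting = 0, seed = 1L) {
  channels <- match.arg(channels)
  stopifnot(resolution >= 64L, d_range[1] < d_range[2], r_max <= 1)
  structure(list(resolution = as.integer(resolution), fov_deg = fov_deg,
                 d_range = d_range, r_max = r_max, exposure = exposure,
                 channels = channels, noise_sd = noise_sd,
                 vignetting = vignetting, seed = as.integer(seed)),
            class = "render_config")
}

# Bilinear texture lookup. tex: matrix; xs, ys: fractional pixel positions
# (1-based, x = column, y = row); outside positions are clamped.
bilinear_sample <- function(tex, xs, ys) {
  w <- ncol(tex); h <- nrow(tex)
  xs <- pmin(pmax(xs, 1), w); ys <- pmin(pmax(ys, 1), h)
  x0 <- pmin(floor(xs), w - 1); y0 <- pmin(floor(ys), h - 1)
  fx <- xs - x0; fy <- ys - y0
  i00 <- (x0 - 1) * h + y0
  v00 <- tex[i00];       v01 <- tex[i00 + h]
  v10 <- tex[i00 + 1];   v11 <- tex[i00 + h + 1]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Render a fetoscopic view
#'
#' Ray-casts the textured plane under the camera-carried spotlight and
#' returns the shaded image together with the exact inclination label of the
#' viewed geometry. Pixel intensity follows
#' cone attenuation x Lambertian cosine x inverse-square falloff, modulated
#' by the texture reflectance, then soft tone-mapped (x / (1 + x)) and
#' quantized to 8 bits. Pixels beyond the textured extent render dark
#' (ambientless background).
#'
#' @param surface a [placenta_surface()].
#' @param pose 4x4 camera placement `^W T_C`.
#' @param light a [light_model()].
#' @param cfg a [render_config()].
#' @return List with `image` (matrix in [0,1], or HxWx3 array for
#'   `channels = "rgb"`) and `label` (length-2 inclination label).
#' @export
render_view <- function(surface, pose, light = light_model(),
                        cfg = render_config()) {
  stopifnot(inherits(surface, "placenta_surface"))
  label <- label_from_scene(pose, surface$normal)  # errors if facing away

  res <- cfg$resolution
  f <- tan(deg2rad(cfg$fov_deg) / 2)
  cs <- ((seq_len(res)) - (res + 1) / 2) / (res / 2) * f
  dx <- matrix(cs, res, res, byrow = TRUE)   # x right (columns)
  dy <- matrix(cs, res, res)                 # y down (rows)
  inv_norm <- 1 / sqrt(dx^2 + dy^2 + 1)
  dxn <- dx * inv_norm; dyn <- dy * inv_norm; dzn <- inv_norm

  R <- pose[1:3, 1:3]; o <- pose[1:3, 4]
  Dx <- R[1, 1] * dxn + R[1, 2] * dyn + R[1, 3] * dzn
  Dy <- R[2, 1] * dxn + R[2, 2] * dyn + R[2, 3] * dzn
  Dz <- R[3, 1] * dxn + R[3, 2] * dyn + R[3, 3] * dzn

  n <- surface$normal; c0 <- surface$center
  denom <- Dx * n[1] + Dy * n[2] + Dz * n[3]
  tnum <- sum((c0 - o) * n)
  t <- tnum / denom
  valid <- is.finite(t) & t > 0
  if (!any(valid)) stop("no surface visible in the camera frustum")
  t[!valid] <- NA

  hx <- o[1] + t * Dx; hy <- o[2] + t * Dy; hz <- o[3] + t * Dz
  rel_x <- hx - c0[1]; rel_y <- hy - c0[2]; rel_z <- hz - c0[3]
  a <- rel_x * surface$u[1] + rel_y * surface$u[2] + rel_z * surface$u[3]
  b <- rel_x * surface$v[1] + rel_y * surface$v[2] + rel_z * surface$v[3]
  half <- surface$extent_mm / 2
  inside <- valid & abs(a) <= half & abs(b) <= half
  if (!any(inside)) stop("no surface visible in the camera frustum")

  # radiometry (co-located or offset emitter)
  lw <- o + R %*% light$offset_mm
  Lx <- hx - lw[1]; Ly <- hy - lw[2]; Lz <- hz - lw[3]
  r2 <- Lx^2 + Ly^2 + Lz^2
  lambert <- pmax(0, -(Lx * n[1] + Ly * n[2] + Lz * n[3]) / sqrt(r2))
  cos_half <- cos(deg2rad(light$cone_half_angle_deg))
  cone <- pmax(0, (dzn - cos_half) / (1 - cos_half))^light$falloff
  E <- cone * lambert / r2 * cfg$exposure + light$ambient

  tex <- surface$texture
  shade_one <- function(texm) {
    tx <- (a / half + 1) / 2 * (ncol(texm) - 1) + 1
    ty <- (b / half + 1) / 2 * (nrow(texm) - 1) + 1
    refl <- matrix(0, res, res)
    refl[inside] <- bilinear_sample(texm, tx[inside], ty[inside])
    L <- E * refl
    L[!inside] <- 0
    L / (1 + L)
  }

  if (cfg$channels == "gray") {
    img <- shade_one(to_gray(tex))
  } else {
    if (is.matrix(tex)) tex <- array(rep(tex, 3), c(dim(tex), 3))
    img <- array(0, c(res, res, 3))
    for (k in 1:3) img[, , k] <- shade_one(tex[, , k])
  }

  if (cfg$vignetting > 0) {
    rad2 <- (dx^2 + dy^2) / f^2
    vig <- 1 - cfg$vignetting * rad2
    img <- if (is.matrix(img)) img * vig else sweep(img, c(1, 2), vig, `*`)
  }
  if (cfg$noise_sd > 0) {
    img <- with_preserved_seed(cfg$seed, img + rnorm(length(img), 0, cfg$noise_sd))
  }
  img <- clamp01(img)
  img <- round(img * 255) / 255  # 8-bit quantization: on-disk == in-memory
  list(image = img, label = label)
}

#' Trajectory specification for pose sampling
#'
#' @param family `"conical"` sweeps the camera about the surface on an
#'   outward spiral in component space (dense, uniform coverage of the
#'   sampled disc); `"grid"` places labels on a regular grid.
#' @param n number of poses.
#' @param roll `"random"` draws a uniform roll about the optical axis per
#'   pose; `"zero"` keeps the camera un-rolled.
#' @param target_jitter_mm half-width of the uniform jitter of the point the
#'   optical axis targets on the surface (exposes different texture
#'   regions).
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(family = c("conical", "grid"), n = 100L,
                            roll = c("random", "zero"),
                            target_jitter_mm = 24) {
  family <- match.arg(family); roll <- match.arg(roll)
  stopifnot(n >= 1)
  structure(list(family = family, n = as.integer(n), roll = roll,
                 target_jitter_mm = target_jitter_mm),
            class = "trajectory_spec")
}

#' Sample camera poses along a trajectory
#'
#' Produces poses whose labels cover the component disc of radius
#' `cfg$r_max` (the conical family reaches the extremes of both components)
#' with distances drawn within `cfg$d_range`. Deterministic for a fixed
#' seed.
#'
#' @param spec a [trajectory_spec()].
#' @param cfg a [render_config()].
#' @param seed integer seed.
#' @param normal_into_cavity,surface_center scene geometry the poses are
#'   anchored to.
#' @return List of pose records: `pose` (4x4), `label`, `distance_mm`,
#'   `roll_deg`, `target`.
#' @export
sample_poses <- function(spec, cfg = render_config(), seed = 1L,
                         normal_into_cavity = c(0, 0, 1),
                         surface_center = c(0, 0, 0)) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n <- spec$n; r_max <- cfg$r_max
  labels <- if (spec$family == "conical") {
    frac <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
    radius <- r_max * sqrt(frac)
    phi <- (seq_len(n) - 1) * deg2rad(137.50776405)  # golden-angle spiral
    cbind(radius * cos(phi), radius * sin(phi))
  } else {
    m <- 2 * ceiling((sqrt(n) - 1) / 2) + 1  # odd grid side
    g <- as.matrix(expand.grid(x = seq(-r_max, r_max, length.out = m),
                               y = seq(-r_max, r_max, length.out = m)))
    g <- g[sqrt(rowSums(g^2)) <= r_max + 1e-12, , drop = FALSE]
    g[rep_len(seq_len(nrow(g)), n), , drop = FALSE]
  }
  draws <- with_preserved_seed(seed, list(
    d = runif(n, cfg$d_range[1], cfg$d_range[2]),
    roll = if (spec$roll == "random") runif(n, 0, 360) else numeric(n),
    jx = runif(n, -spec$target_jitter_mm, spec$target_jitter_mm),
    jy = runif(n, -spec$target_jitter_mm, spec$target_jitter_mm)))
  nrm <- normalize_vec(normal_into_cavity)
  surf <- placenta_surface(matrix(1, 2, 2), extent_mm = 1,
                           center = surface_center,
                           normal_into_cavity = nrm)
  lapply(seq_len(n), function(i) {
    target <- surface_center + draws$jx[i] * surf$u + draws$jy[i] * surf$v
    pose <- camera_pose_for_label(labels[i, ], draws$d[i],
                                  normal_into_cavity = nrm,
                                  target = target, roll_deg = draws$roll[i])
    list(pose = pose, label = c(x = labels[i, 1], y = labels[i, 2]),
         distance_mm = draws$d[i], roll_deg = draws$roll[i], target = target)
  })
}

#' Generate a labeled synthetic dataset
#'
#' Renders one image per sampled pose, cycling over the provided textures,
#' and returns a manifest joining every image with its exact label and
#' provenance (texture id, pose parameters, seed). Optionally persists the
#' dataset as PNG images plus a `manifest.csv` label table and a
#' `config.json` echo.
#'
#' @param textures list of texture arrays (see [generate_texture()]).
#' @param spec a [trajectory_spec()] (its `n` is the number of samples).
#' @param cfg a [render_config()].
#' @param out_dir output directory, or NULL to keep the dataset in memory.
#' @param seed integer seed controlling poses and any noise.
#' @param light a [light_model()].
#' @param extent_mm physical side of the textured patch.
#' @return A dataset manifest: list with `samples` (data frame), `images`
#'   (list of matrices), `config` (echo of the generation parameters).
#' @export
generate_dataset <- function(textures, spec, cfg = render_config(),
                             out_dir = NULL, seed = 1L,
                             light = light_model(), extent_mm = 80) {
  if (length(textures) < 1) stop("at least one texture is required")
  poses <- sample_poses(spec, cfg, seed = seed)
  n <- length(poses)
  surfaces <- lapply(textures, placenta_surface, extent_mm = extent_mm)
  tex_id <- rep_len(seq_along(textures), n)
  images <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- poses[[i]]
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i  # per-sample noise stream
    rv <- render_view(surfaces[[tex_id[i]]], p$pose, light, cfg_i)
    stopifnot(max(abs(rv$label - p$label)) < 1e-9)
    images[[i]] <- rv$image
    rows[[i]] <- data.frame(
      sample_id = sprintf("s%06d", i),
      image_path = sprintf("img/s%06d.png", i),
      x_component = p$label[1], y_component = p$label[2],
      distance_mm = p$distance_mm, roll_deg = p$roll_deg,
      texture_id = tex_id[i], seed = seed, aug_deg = 0,
      base_id = sprintf("s%06d", i))
  }
  samples <- do.call(rbind, rows)
  config <- list(trajectory = unclass(spec), render = unclass(cfg),
                 light = unclass(light), extent_mm = extent_mm,
                 n_textures = length(textures), seed = seed)
  manifest <- list(samples = samples, images = images, config = config)
  if (!is.null(out_dir)) write_dataset(manifest, out_dir)
  manifest
}

#' Persist / load a dataset manifest
#'
#' Layout: `manifest.csv` (label table), `config.json`, and one grayscale
#' PNG per sample under `img/`.
#'
#' @param manifest a dataset manifest with in-memory images.
#' @param dir dataset directory.
#' @return `write_dataset` returns `dir` invisibly; `load_dataset` the
#'   manifest with images loaded.
#' @export
write_dataset <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgdir <- file.path(dir, "img")
  if (!dir.exists(imgdir)) dir.create(imgdir)
  for (i in seq_len(nrow(manifest$samples))) {
    png::writePNG(manifest$images[[i]],
                  file.path(dir, manifest$samples$image_path[i]))
  }
  utils::write.csv(manifest$samples, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(manifest$config)) {
    jsonlite::write_json(manifest$config, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
load_dataset <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "manifest.csv"),
                             stringsAsFactors = FALSE)
  images <- lapply(samples$image_path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    to_gray(if (length(dim(img)) == 3L) img[, , 1:3, drop = FALSE] else img)
  })
  cfgp <- file.path(dir, "config.json")
  config <- if (file.exists(cfgp)) jsonlite::read_json(cfgp, simplifyVector = TRUE)
  list(samples = samples, images = images, config = config)
}
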