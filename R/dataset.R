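# Dataset assembly: preprocessing to the network input contract, field-of-
# view masking (square chip-on-tip vs circular rod-lens / fiber-bundle),
# rotation augmentation with consistent label transformation, and
# leakage-safe splits.

#' Preprocess an image to the network input contract
#'
#' Single channel (luminance), bilinear down-scaling to `px` x `px`,
#' intensities in [0, 1]. This is the fixed contract all trained models
#' assume.
#'
#' @param image matrix or HxWx3 array, values in [0, 1].
#' @param px output side in pixels (default 200).
#' @return A `px` x `px` matrix in [0, 1].
#' @export
preprocess_image <- function(image, px = 200L) {
  g <- to_gray(image)
  if (min(dim(g)) < 64L) stop("input image smaller than 64 px")
  if (!all(dim(g) == c(px, px))) {
    g <- as.matrix(EBImage::resize(EBImage::as.Image(g), w = px, h = px))
  }
  clamp01(g)
}

#' Apply a field-of-view mask
#'
#' Chip-on-tip sensors deliver a square image (`style = "square"`,
#' identity); rod-lens and fiber-bundle conduits deliver a circular field
#' (`style = "circular"`): pixels outside the inscribed disc are zeroed.
#'
#' @param image square matrix.
#' @param style `"square"` or `"circular"`.
#' @return The masked image.
#' @export
apply_fov_mask <- function(image, style = c("square", "circular")) {
  style <- match.arg(style)
  if (style == "square") return(image)
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  image * (d2 <= (n / 2)^2)
}

# In-plane image rotation about the center, bilinear, out-of-frame filled
# black; positive angle matches rotate_label()'s positive direction (the
# correspondence is pinned by the renderer roll-equivariance tests).
rotate_image <- function(image, theta_deg) {
  if (theta_deg %% 360 == 0) return(image)
  img <- EBImage::as.Image(image)
  # negated angle: with this sign, rotate_image(render(pose), theta) matches
  # the render from the camera rolled by -theta, whose label is
  # rotate_label(label, +theta) -- so image and label share one angle.
  out <- EBImage::rotate(img, angle = -theta_deg, filter = "bilinear",
                         output.dim = dim(image), bg.col = 0)
  as.matrix(out)
}

#' Rotation augmentation with consistent label transformation
#'
#' Each sample yields `360 / increment` samples: the image is rotated about
#' its center in `increment`-degree steps and the label is transformed by
#' [rotate_label()] with the matching angle. This enriches sparsely sampled
#' orientation data without new acquisitions. Source provenance is
#' preserved; the `aug_deg` column records the applied angle and `base_id`
#' the originating sample.
#'
#' @param manifest dataset manifest with in-memory images.
#' @param increment rotation step in degrees; must divide 360.
#' @return The augmented manifest.
#' @export
augment_by_rotation <- function(manifest, increment = 5) {
  if (increment <= 0 || 360 %% increment != 0) {
    stop("rotation increment must divide 360")
  }
  angles <- seq(0, 360 - increment, by = increment)
  n <- nrow(manifest$samples)
  images <- vector("list", n * length(angles))
  rows <- vector("list", n * length(angles))
  k <- 0
  for (i in seq_len(n)) {
    base <- manifest$samples[i, ]
    lab <- c(base$x_component, base$y_component)
    for (a in angles) {
      k <- k + 1
      images[[k]] <- rotate_image(manifest$images[[i]], a)
      row <- base
      rl <- rotate_label(lab, a)
      row$sample_id <- sprintf("%s_r%03d", base$base_id, a)
      row$image_path <- sprintf("img/%s_r%03d.png", base$base_id, a)
      row$x_component <- rl[[1]]
      row$y_component <- rl[[2]]
      row$aug_deg <- a
      rows[[k]] <- row
    }
  }
  list(samples = do.call(rbind, rows), images = images,
       config = c(manifest$config, list(augment_increment = increment)))
}

#' Split specification
#'
#' @param val,test validation and test sizes: counts (>= 1) or fractions
#'   (< 1 interpreted as fractions of the source images).
#' @param seed split seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(val = 0.1, test = 0.2, seed = 1L) {
  structure(list(val = val, test = test, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a dataset without augmentation leakage
#'
#' Randomly assigns *source images* (`base_id`) to train/validation/test so
#' that all rotated copies of one source land in the same split. Counts are
#' in samples and must be reachable exactly by whole source groups (always
#' true for unaugmented data); fractions apply to source images.
#'
#' @param manifest dataset manifest.
#' @param spec a [split_spec()].
#' @return List of three manifests `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  s <- manifest$samples
  base_ids <- unique(s$base_id)
  nb <- length(base_ids)
  group_size <- nrow(s) / nb
  take <- function(x) {
    if (x < 1) round(x * nb)
    else {
      if (x %% group_size != 0) {
        stop(sprintf(
          "count %d not reachable by whole source groups of size %d", x,
          group_size))
      }
      x / group_size
    }
  }
  n_val <- take(spec$val); n_test <- take(spec$test)
  if (n_val + n_test >= nb) stop("infeasible split counts")
  perm <- with_preserved_seed(spec$seed, sample(base_ids))
  ids_val <- perm[seq_len(n_val)]
  ids_test <- perm[n_val + seq_len(n_test)]
  pick <- function(ids) {
    idx <- which(s$base_id %in% ids)
    list(samples = s[idx, , drop = FALSE],
         images = manifest$images[idx],
         config = manifest$config)
  }
  list(train = pick(setdiff(base_ids, c(ids_val, ids_test))),
       val = pick(ids_val), test = pick(ids_test))
}
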