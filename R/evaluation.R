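# Evaluation and reporting: gridded combined-error heatmaps over the
# placental surface, per-episode and pooled RMS/STD summaries, and a
# seeded end-to-end pipeline (generate -> split -> train -> evaluate ->
# control episodes -> summarize).

#' Combined-error heatmap over the placental surface
#'
#' Bins the logged tip-projection coordinates on the surface plane and
#' reports the RMS combined error per bin; shows which surface regions are
#' prone to perpendicularity errors.
#'
#' @param log a `trajectory_log` (or any data frame with `tip_u_mm`,
#'   `tip_v_mm`, `combined_error_deg`).
#' @param bins number of bins per axis (default 25).
#' @param extent_mm c(min, max) of the binned coordinate range; defaults to
#'   the symmetric range covering the data.
#' @return An `error_heatmap`: list with `rms` (bins x bins matrix, NA for
#'   empty bins), `counts`, `u_breaks`, `v_breaks`.
#' @export
error_heatmap <- function(log, bins = 25L, extent_mm = NULL) {
  ok <- is.finite(log$tip_u_mm) & is.finite(log$tip_v_mm)
  if (!any(ok)) stop("log holds no on-surface tip projections")
  u <- log$tip_u_mm[ok]; v <- log$tip_v_mm[ok]
  e <- log$combined_error_deg[ok]
  if (is.null(extent_mm)) {
    m <- max(abs(c(u, v)))
    extent_mm <- c(-m, m) * 1.0001
  }
  br <- seq(extent_mm[1], extent_mm[2], length.out = bins + 1)
  iu <- cut(u, br, include.lowest = TRUE, labels = FALSE)
  iv <- cut(v, br, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(iu) & !is.na(iv)
  rms <- matrix(NA_real_, bins, bins)
  counts <- matrix(0L, bins, bins)
  for (k in which(keep)) {
    counts[iv[k], iu[k]] <- counts[iv[k], iu[k]] + 1L
    s <- rms[iv[k], iu[k]]
    rms[iv[k], iu[k]] <- if (is.na(s)) e[k]^2 else s + e[k]^2
  }
  pop <- counts > 0
  rms[pop] <- sqrt(rms[pop] / counts[pop])
  structure(list(rms = rms, counts = counts, u_breaks = br, v_breaks = br),
            class = "error_heatmap")
}

rms <- function(x) sqrt(mean(x^2))

#' Summarize control episodes
#'
#' Per-episode RMS of the combined error plus the pooled RMS and pooled
#' standard deviation across episodes, per configuration.
#'
#' @param logs a named list of `trajectory_log`s, or a list of such lists
#'   (one per configuration).
#' @return A `control_report` data frame with one row per configuration:
#'   `config`, `episodes`, `rms_per_episode` (list column),
#'   `total_rms_deg`, `total_std_deg`.
#' @export
summarize_episodes <- function(logs) {
  if (inherits(logs, "trajectory_log")) logs <- list(logs)
  if (all(vapply(logs, inherits, TRUE, "trajectory_log"))) {
    logs <- list(episodes = logs)
  }
  rows <- lapply(names(logs), function(cfg) {
    eps <- logs[[cfg]]
    per <- vapply(eps, function(l) rms(l$combined_error_deg), numeric(1))
    pooled <- unlist(lapply(eps, function(l) l$combined_error_deg))
    data.frame(config = cfg, episodes = length(eps),
               rms_per_episode = I(list(per)),
               total_rms_deg = rms(pooled),
               total_std_deg = sd(pooled))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("control_report", class(out))
  out
}

#' Write a heatmap to disk
#'
#' Persists the per-bin RMS grid as CSV and a grayscale PNG rendering
#' (darker = larger error; empty bins black).
#'
#' @param hm an [error_heatmap()].
#' @param path_prefix output path without extension.
#' @return The two file paths, invisibly.
#' @export
write_heatmap <- function(hm, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  pngf <- paste0(path_prefix, ".png")
  utils::write.csv(hm$rms, csv, row.names = FALSE)
  img <- hm$rms
  img[is.na(img)] <- 0
  if (max(img) > 0) img <- img / max(img)
  png::writePNG(img, pngf)
  invisible(c(csv, pngf))
}

#' Run the full pipeline end to end
#'
#' Seeded, declarative pipeline: texture generation, synthetic dataset,
#' split, network training, test evaluation, and control episodes in the
#' straight / fixed-curve / autonomous configurations over the 45-degree
#' scene, summarized into one report. All stages derive their seeds from
#' `config$seed`.
#'
#' @param config list (or path to a YAML file) with optional overrides:
#'   `seed`, `n_samples`, `n_textures`, `val`, `test`, `epochs`,
#'   `patience`, `episode_landmarks`, `resolution`.
#' @param verbose print stage progress.
#' @return A list with `model`, `eval` (test-set report), `control`
#'   (summary data frame), `logs`, `heatmaps`, `config`.
#' @export
reproduce_all <- function(config = list(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, n_samples = 5400L, n_textures = 3L,
                   val = 300L, test = 300L, epochs = 58L, patience = 58L,
                   resolution = 200L, fixed_r2_deg = 30)
  config <- utils::modifyList(defaults, config)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- as.integer(config$seed)

  say("[generate] %d textures, %d samples", config$n_textures, config$n_samples)
  textures <- lapply(seed + seq_len(config$n_textures), generate_texture)
  cfg <- render_config(resolution = config$resolution)
  manifest <- generate_dataset(textures, trajectory_spec("conical",
                                                         n = config$n_samples),
                               cfg, seed = seed)
  say("[split] val %d / test %d", config$val, config$test)
  sp <- split_dataset(manifest, split_spec(val = config$val,
                                           test = config$test,
                                           seed = seed + 100L))
  say("[train] %d epochs max", config$epochs)
  model <- build_network(network_spec(input_px = config$resolution),
                         seed = seed + 200L)
  model <- train_network(model, sp$train, sp$val,
                         training_config(epochs = config$epochs,
                                         patience = config$patience,
                                         seed = seed + 300L),
                         verbose = verbose)
  say("[evaluate]")
  eval_report <- evaluate_model(model, sp$test, dataset_id = "sim-test")

  say("[run-loop] straight / fixed / autonomous on the 45-degree scene")
  scene <- tilted_scene(texture = textures[[1]],
                        resolution_px = config$resolution)
  logs <- list(
    straight = list(run_episode(scene, config = "straight",
                                seed = seed + 400L)),
    fixed = list(run_episode(scene, config = "fixed",
                             fixed_r2_deg = config$fixed_r2_deg,
                             seed = seed + 401L)),
    autonomous = list(run_episode(scene, config = "autonomous",
                                  estimator = model, seed = seed + 402L)))
  control <- summarize_episodes(logs)
  heatmaps <- lapply(logs, function(l) error_heatmap(l[[1]]))
  say("[report] accuracy %.1f%%; RMS straight %.2f / fixed %.2f / auto %.2f deg",
      eval_report$accuracy, control$total_rms_deg[1],
      control$total_rms_deg[2], control$total_rms_deg[3])
  list(model = model, eval = eval_report, control = control, logs = logs,
       heatmaps = heatmaps, config = config)
}
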