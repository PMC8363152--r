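# Figure-level pipeline drivers: landscape export, topograph analysis,
# synthetic benchmark generation and nanodissection reporting. Each run
# writes its resolved configuration next to its outputs so any run can be
# reproduced from the emitted files alone.

utils::globalVariables(c("R_nm", "A_nm2", "E_kBT"))

#' Run configuration
#'
#' Assembles model parameters, morphometry settings, generator settings and
#' seeds into a single serializable configuration. [read_run_config()] /
#' [write_run_config()] round-trip it through YAML (`R_memb: inf` is
#' accepted for a flat membrane).
#'
#' @param params a [model_params()] or a named list overriding single
#'   parameters.
#' @param morphometry named list: `height_thresh` (nm), `sigma` (px),
#'   `rounds`, `flat_tolerance` (deg), `samplings`.
#' @param generator named list: `n`, `T_eff`, `ridge_height`, `r_tip`,
#'   `noise_sd`, `pixel_size`, `n_pixels`, `edge_length`.
#' @param seed integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = model_params(), morphometry = list(),
                       generator = list(), seed = 1) {
  if (!inherits(params, "model_params"))
    params <- do.call(model_params, params)
  mdef <- list(height_thresh = 0.5, sigma = 4, rounds = 2,
               flat_tolerance = 5, samplings = c(1, 0.5, 0.25))
  gdef <- list(n = 10, T_eff = 300, ridge_height = 2, r_tip = 2,
               noise_sd = 0.1, pixel_size = 2, n_pixels = 300,
               edge_length = 18)
  mdef[names(morphometry)] <- morphometry
  gdef[names(generator)] <- generator
  structure(list(params = params, morphometry = mdef, generator = gdef,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- lapply(unclass(x$params), function(v)
    if (is.infinite(v)) "inf" else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  pars <- lapply(x$params, function(v)
    if (identical(v, "inf")) Inf else as.numeric(v))
  run_config(params = do.call(model_params, pars),
             morphometry = x$morphometry, generator = x$generator,
             seed = x$seed)
}

.ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

.save_heatmap <- function(ls, path, title) {
  df <- as.data.frame(ls)
  df <- df[df$valid, ]
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = R_nm, y = A_nm2,
                                         fill = E_kBT)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = title, x = "R (nm)", y = expression(A ~ (nm^2)),
                  fill = "E (kBT)")
  grDevices::png(path, width = 900, height = 700, res = 120)
  print(gp)
  grDevices::dev.off()
}

#' Export the energy landscape: grids, heatmaps, minimizer, critical tension
#'
#' Writes, under `out_dir`: a CSV grid and PNG heatmap for each of the four
#' energy terms and the total, `minimizer.json` (constrained minimum,
#' branch, boundary closed form) and `critical_tension.json` (tension
#' sweep), plus the resolved configuration.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param resolution landscape cells per axis; default 200.
#' @return Invisibly, a list with `minimum`, `critical` and the output
#'   paths.
#' @export
run_landscape <- function(config = run_config(), out_dir, resolution = 200) {
  stopifnot(inherits(config, "run_config"))
  .ensure_dir(out_dir)
  p <- config$params
  terms <- c("memb_bend", "memb_tension", "clath_bend", "clath_poly", "total")
  paths <- character(0)
  for (tm in terms) {
    ls <- energy_landscape(p, resolution = resolution, term = tm)
    csv <- file.path(out_dir, paste0("landscape_", tm, ".csv"))
    utils::write.csv(as.data.frame(ls), csv, row.names = FALSE)
    png <- file.path(out_dir, paste0("landscape_", tm, ".png"))
    .save_heatmap(ls, png, paste("CCP energy landscape:", tm))
    paths <- c(paths, csv, png)
  }
  m <- minimize_energy(p)
  m$R_boundary_closed_form <- boundary_optimal_radius(p)
  jsonlite::write_json(m, file.path(out_dir, "minimizer.json"),
                       auto_unbox = TRUE, digits = NA)
  ct <- critical_tension(p)
  jsonlite::write_json(list(gamma_critical = ct$gamma_critical,
                            bracketed = ct$bracketed),
                       file.path(out_dir, "critical_tension.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(ct$sweep, file.path(out_dir, "tension_sweep.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(minimum = m, critical = ct, paths = paths))
}

#' Generate a seeded synthetic benchmark set
#'
#' Samples a pit population from the energy landscape, builds a lattice on
#' each pit, renders topographs, and writes each truth bundle (topograph
#' TIFF + sidecar, mesh JSON, truth CSV row) under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, the truth data frame (`id`, `R_nm`, `h_nm`, `A_nm2`,
#'   `pentagons`, `seed`).
#' @export
run_generate <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  .ensure_dir(out_dir)
  g <- config$generator
  caps <- sample_population(config$params, g$n, T_eff = g$T_eff,
                            seed = config$seed)
  rows <- list()
  for (i in seq_along(caps)) {
    cap <- caps[[i]]
    frame_nm <- (g$n_pixels - 1) * g$pixel_size
    foot <- if (cap$h < cap$R) sqrt(cap$h * (2 * cap$R - cap$h)) else cap$R
    if (2 * (foot + g$r_tip) > 0.9 * frame_nm) next  # skip oversize pits
    mesh <- build_cap_lattice(cap, edge_length = g$edge_length,
                              seed = config$seed + i)
    truth <- synthetic_truth(cap, mesh, ridge_height = g$ridge_height,
                             r_tip = g$r_tip, noise_sd = g$noise_sd,
                             pixel_size = g$pixel_size,
                             n_pixels = g$n_pixels, seed = config$seed + i)
    topo <- render_topograph(truth)
    write_topograph(topo, file.path(out_dir, sprintf("topo_%03d.tif", i)))
    write_skeleton(mesh, file.path(out_dir, sprintf("mesh_%03d.json", i)))
    rows[[length(rows) + 1L]] <-
      data.frame(id = i, R_nm = cap$R, h_nm = cap$h, A_nm2 = cap$A,
                 pentagons = attr(mesh, "pentagon_count"),
                 seed = config$seed + i)
  }
  truth_df <- do.call(rbind, rows)
  utils::write.csv(truth_df, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(truth_df)
}

#' Analyze topographs: fit pits, skeletonize lattices, angle statistics
#'
#' For each topograph file: level the background, fit every detected pit,
#' detect and skeletonize the clathrin lattice, and compute hub angle
#' statistics. Writes per-image record CSVs and skeleton JSONs, a pooled
#' records table, pooled polygon angle fits, and the angle-sum versus radius
#' binned table.
#'
#' @param config a [run_config()].
#' @param topo_paths character vector of topograph paths (TIFF or CSV, with
#'   sidecars).
#' @param out_dir output directory.
#' @return Invisibly, a list with `records` (pooled data frame), `fits`
#'   (angle fits for 5/6/7-gons), `sums` (anglesum-vs-radius result or
#'   `NULL`), `n_failed` (unreadable/failed images).
#' @export
run_analyze <- function(config = run_config(), topo_paths, out_dir) {
  stopifnot(inherits(config, "run_config"), length(topo_paths) >= 0)
  .ensure_dir(out_dir)
  p <- config$params
  mset <- config$morphometry
  all_records <- list(); skels <- list(); hub_rows <- list()
  n_failed <- 0L
  for (path in topo_paths) {
    topo <- tryCatch(read_topograph(path), error = function(e) NULL)
    if (is.null(topo)) {
      warning("skipping unreadable topograph: ", path)
      n_failed <- n_failed + 1L
      next
    }
    topo <- level_background(topo)
    recs <- detect_ccps(topo, p, height_thresh = mset$height_thresh)
    tab <- records_table(recs)
    base <- tools::file_path_sans_ext(basename(path))
    if (nrow(tab) > 0) tab$image <- base
    utils::write.csv(tab, file.path(out_dir, paste0(base, "_records.csv")),
                     row.names = FALSE)
    mask <- detect_lattice(topo, sigma = mset$sigma, rounds = mset$rounds,
                           samplings = mset$samplings)
    skel <- build_skeleton(mask, topo)
    write_skeleton(skel, file.path(out_dir, paste0(base, "_skeleton.json")))
    skels[[length(skels) + 1L]] <- skel
    ht <- skeleton_hub_table(skel, tolerance = mset$flat_tolerance)
    if (nrow(ht) > 0 && nrow(tab) > 0) {
      ht$R_nm <- tab$R_nm[which.max(tab$A_nm2)]  # dominant pit of the frame
      hub_rows[[length(hub_rows) + 1L]] <- ht
    }
    all_records[[length(all_records) + 1L]] <- tab
  }
  records <- do.call(rbind, all_records)
  if (!is.null(records) && nrow(records) > 0) {
    utils::write.csv(records, file.path(out_dir, "records_all.csv"),
                     row.names = FALSE)
    if (nrow(records) >= 3) {
      ar <- area_radius_distribution(records)
      grDevices::png(file.path(out_dir, "area_vs_radius.png"),
                     width = 900, height = 700, res = 120)
      print(plot(ar))
      grDevices::dev.off()
    }
  }
  fits <- lapply(c(5, 6, 7), function(sz) polygon_angle_histogram(skels, sz))
  names(fits) <- c("pentagon", "hexagon", "heptagon")
  fit_df <- data.frame(polygon = names(fits),
                       size = c(5, 6, 7),
                       n = vapply(fits, `[[`, numeric(1), "n"),
                       mean_deg = vapply(fits, `[[`, numeric(1), "mean"),
                       sd_deg = vapply(fits, `[[`, numeric(1), "sd"))
  utils::write.csv(fit_df, file.path(out_dir, "angle_fits.csv"),
                   row.names = FALSE)
  sums <- NULL
  hubs <- do.call(rbind, hub_rows)
  if (!is.null(hubs) && length(unique(hubs$R_nm)) >= 2) {
    sums <- anglesum_vs_radius(
      data.frame(R_nm = hubs$R_nm, angle_sum_deg = hubs$angle_sum))
    utils::write.csv(sums$bins, file.path(out_dir, "anglesum_vs_radius.csv"),
                     row.names = FALSE)
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(records = records, fits = fits, sums = sums,
                 n_failed = n_failed))
}

#' Simulated nanodissection report
#'
#' Builds a flat elastically loaded lattice, severs a central band of arms
#' to split it, relaxes the fragments at constant area, and writes the
#' before/after trajectory table — the energy-landscape "jump" of a
#' nanodissected lattice toward higher curvature.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param rings honeycomb patch size; default 3.
#' @return Invisibly, the before/after data frame.
#' @export
run_dissect <- function(config = run_config(), out_dir, rings = 3) {
  stopifnot(inherits(config, "run_config"))
  .ensure_dir(out_dir)
  mesh <- hex_patch_mesh(rings = rings,
                         edge = config$generator$edge_length)
  truth <- synthetic_truth(cap = NULL, mesh = mesh,
                           pixel_size = config$generator$pixel_size,
                           n_pixels = config$generator$n_pixels,
                           seed = config$seed)
  # sever every arm crossing a vertical line through the patch (offset off
  # the lattice vertices) to split it in two
  v <- mesh$vertices
  xcut <- 1
  cutters <- which((v[mesh$edges[, 1], 1] - xcut) *
                     (v[mesh$edges[, 2], 1] - xcut) < 0)
  res <- simulate_nanodissection(truth, cutters, config$params)
  utils::write.csv(res, file.path(out_dir, "nanodissection.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(res)
}
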