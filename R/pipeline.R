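# End-to-end orchestration: per-animal WSS/OSI node tables and projection
# maps, group comparisons, PWV and volume tables, written as CSV/JSON
# with a provenance record. Outputs carry units in their column names and
# contain no timestamps, so identical config + seed gives byte-identical
# files.

#' Pipeline configuration
#'
#' Defaults mirror the acquisition and analysis constants of high-field
#' murine 4D flow studies: eta = 0.004 Pa s, 20 frames in WSS mode and
#' 200 in PWV mode, a 0.5 degree x 1 um map grid, 50 flow planes, and a
#' 7 mm analysis extent (3 mm proximal + 4 mm distal of the landmark).
#'
#' @param eta dynamic viscosity (Pa s)
#' @param wss_frames,pwv_frames reconstruction frame counts per mode
#' @param grid_theta_step map angular step (degrees)
#' @param grid_z_step map longitudinal step (mm)
#' @param map_coarsen integer c(z, theta) block sizes applied to maps
#'   before group statistics (1 = full resolution)
#' @param n_planes flow planes for PWV
#' @param prox_mm,dist_mm analysis extent around the landmark (mm)
#' @param alpha significance threshold
#' @param seed integer seed for any stochastic step
#' @param do_pwv run the PWV stage (needs enough frames)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(eta = 0.004, wss_frames = 20L, pwv_frames = 200L,
                            grid_theta_step = 0.5, grid_z_step = 0.001,
                            map_coarsen = c(1L, 1L), n_planes = 50L,
                            prox_mm = 3, dist_mm = 4, alpha = 0.05,
                            seed = 1L, do_pwv = FALSE) {
  stopifnot(eta > 0, grid_theta_step > 0, grid_z_step > 0,
            alpha > 0, alpha < 1, prox_mm > 0, dist_mm > 0)
  structure(list(eta = eta, wss_frames = as.integer(wss_frames),
                 pwv_frames = as.integer(pwv_frames),
                 grid_theta_step = grid_theta_step,
                 grid_z_step = grid_z_step,
                 map_coarsen = as.integer(map_coarsen),
                 n_planes = as.integer(n_planes),
                 prox_mm = prox_mm, dist_mm = dist_mm, alpha = alpha,
                 seed = as.integer(seed), do_pwv = do_pwv),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Analyze one animal: surface, centerline, frames, WSS/OSI, maps
#'
#' @param velocity a [velocity_field()]
#' @param mask a [lumen_mask()]
#' @param config a [pipeline_config()]
#' @param landmark_z landmark arc position (mm); default: centerline
#'   midpoint
#' @param reference theta = 0 reference direction (default +y)
#' @return list: `nodes` (per-node table), `maps` (named list of
#'   `projection_map`s for long_wss, circ_wss, rad_strain, osi),
#'   `volume` (a `volume_series`), `landmark_z`, `centerline`, `mesh`
#' @export
analyze_animal <- function(velocity, mask, config = pipeline_config(),
                           landmark_z = NULL, reference = c(0, 1, 0)) {
  mesh <- extract_surface(mask)
  cl <- orient_by_flow(extract_centerline(mask), velocity, mask)
  if (is.null(landmark_z)) landmark_z <- max(cl$arc) / 2
  ne <- normalize_extent(cl, mesh, landmark_z,
                         prox_mm = config$prox_mm, dist_mm = config$dist_mm)
  frames <- build_wall_frames(ne$mesh, ne$centerline, reference = reference)
  tab <- wall_mechanics_table(velocity, mask, ne$mesh, frames,
                              eta = config$eta)
  zr <- c(0, config$prox_mm + config$dist_mm)
  maps <- list()
  for (metric in c("long_wss", "circ_wss", "rad_strain", "osi")) {
    vals <- tab[[metric]]
    vals[!tab$valid] <- NA_real_
    mp <- project_to_map(vals, frames,
                         theta_step = config$grid_theta_step,
                         z_step = config$grid_z_step, z_range = zr)
    if (any(config$map_coarsen > 1L))
      mp <- coarsen_map(mp, config$map_coarsen[1], config$map_coarsen[2])
    maps[[metric]] <- mp
  }
  cropped <- crop_mask_to_extent(mask, ne$centerline)
  list(nodes = tab, maps = maps, volume = volume_series(cropped),
       landmark_z = landmark_z, centerline = ne$centerline, mesh = ne$mesh)
}

#' Run the full pipeline over a manifest of animals
#'
#' Each manifest row describes one animal: `animal`, `group`, and either
#' file paths (`velocity`, `mask` as NIfTI) or, programmatically,
#' in-memory objects supplied via `objects`. Per-animal failures are
#' caught, flagged in the summary, and excluded from group statistics.
#'
#' @param manifest data.frame with columns `animal`, `group`, and
#'   (unless `objects` is given) `velocity`, `mask` file paths; optional
#'   `landmark_z`
#' @param out_dir output directory (created if missing)
#' @param config a [pipeline_config()]
#' @param objects optional named list: `objects[[animal]]` is a list with
#'   elements `velocity` and `mask`, bypassing file input
#' @return invisibly, a summary list (also written as `summary.json`)
#' @export
run_pipeline <- function(manifest, out_dir, config = pipeline_config(),
                         objects = NULL) {
  stopifnot(all(c("animal", "group") %in% names(manifest)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  results <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    an <- as.character(manifest$animal[i])
    res <- tryCatch({
      if (!is.null(objects)) {
        vel <- objects[[an]]$velocity
        msk <- objects[[an]]$mask
      } else {
        vel <- read_velocity(manifest$velocity[i])
        msk <- read_mask(manifest$mask[i])
      }
      lz <- if ("landmark_z" %in% names(manifest) &&
                is.finite(manifest$landmark_z[i])) manifest$landmark_z[i]
      analyze_animal(vel, msk, config, landmark_z = lz)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[an]] <- conditionMessage(res)
      next
    }
    results[[an]] <- res
    tab <- res$nodes
    tab[] <- lapply(tab, function(col) if (is.numeric(col)) round(col, 6) else col)
    names(tab) <- c("node_id", "z_mm", "theta_deg", "long_wss_pa",
                    "circ_wss_pa", "rad_strain_pa", "osi_pct", "valid")
    utils::write.csv(tab, file.path(out_dir, paste0(an, "_nodes.csv")),
                     row.names = FALSE)
    for (metric in names(res$maps))
      write_map(res$maps[[metric]],
                file.path(out_dir, paste0(an, "_map_", metric, ".csv")))
  }
  if (!length(results)) stop("no animal could be analyzed")

  # volume table
  voltab <- do.call(rbind, lapply(names(results), function(an) {
    v <- results[[an]]$volume
    data.frame(animal = an,
               group = manifest$group[match(an, manifest$animal)],
               mean_mm3 = round(v$mean, 6), max_mm3 = round(v$max, 6),
               min_mm3 = round(v$min, 6),
               max_minus_min_mm3 = round(v$max_minus_min, 6))
  }))
  utils::write.csv(voltab, file.path(out_dir, "volumes.csv"),
                   row.names = FALSE)

  # group comparison on the first two groups with >= 2 analyzed animals
  grp_of <- manifest$group[match(names(results), manifest$animal)]
  tabg <- table(grp_of)
  big <- names(tabg)[tabg >= 2]
  comparisons <- list()
  if (length(big) >= 2) {
    ga <- big[1]; gb <- big[2]
    for (metric in names(results[[1]]$maps)) {
      stack_of <- function(g) map_stack(
        lapply(results[names(results)[grp_of == g]],
               function(r) r$maps[[metric]]), group = g)
      cmp <- pixelwise_compare(stack_of(ga), stack_of(gb),
                               alpha = config$alpha)
      comparisons[[metric]] <- cmp
      base <- file.path(out_dir, paste0("compare_", metric))
      dmap <- structure(list(values = cmp$difference, valid = cmp$valid,
                             grid_z = results[[1]]$maps[[metric]]$grid_z,
                             grid_theta = results[[1]]$maps[[metric]]$grid_theta),
                        class = "projection_map")
      write_map(dmap, paste0(base, "_difference.csv"))
      pmap <- structure(list(values = cmp$p_map, valid = cmp$valid,
                             grid_z = dmap$grid_z,
                             grid_theta = dmap$grid_theta),
                        class = "projection_map")
      write_map(pmap, paste0(base, "_p.csv"))
    }
  }

  # PWV per animal (only meaningful on high-temporal reconstructions)
  pwvtab <- NULL
  if (config$do_pwv) {
    rows <- list()
    for (an in names(results)) {
      r <- results[[an]]
      vel <- if (!is.null(objects)) objects[[an]]$velocity else
        read_velocity(manifest$velocity[match(an, manifest$animal)])
      if (vel$n_frames < 50) {
        failures[[paste0(an, "_pwv")]] <-
          "too few frames for PWV mode; stage skipped"
        next
      }
      msk <- if (!is.null(objects)) objects[[an]]$mask else
        read_mask(manifest$mask[match(an, manifest$animal)])
      fit <- tryCatch({
        pos <- pwv_plane_positions(r$centerline, config$n_planes)
        estimate_pwv(through_plane_flow(vel, msk, r$centerline, pos))
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[paste0(an, "_pwv")]] <- conditionMessage(fit)
      } else {
        rows[[an]] <- data.frame(animal = an, pwv_m_s = round(fit$pwv, 6),
                                 fit_r2 = round(fit$fit_r2, 6))
      }
    }
    if (length(rows)) {
      pwvtab <- do.call(rbind, rows)
      utils::write.csv(pwvtab, file.path(out_dir, "pwv.csv"),
                       row.names = FALSE)
    }
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("archflow")),
    config = unclass(config),
    animals_analyzed = names(results),
    failures = if (length(failures)) failures else NULL,
    groups_compared = if (length(big) >= 2) big[1:2] else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, comparisons = comparisons,
                 volumes = voltab, pwv = pwvtab, failures = failures))
}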