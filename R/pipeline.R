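# End-to-end pipeline driver: a validated run configuration plus a small
# command set (simulate, map, pairs, pathways, hierarchy, report) writing
# CSV/JSON artifacts. Every output directory gets a run.json log with the
# full parameter set and its hash, so runs are auditable and reproducible.

#' Run configuration
#'
#' All tunable parameters of the pipeline with their protocol defaults:
#' 75 ms response window, 4x baseline-SD pixel significance, ~100 um
#' pairing distance, 70% contour fraction for band densities, 10 px disk
#' filter radius. Unknown keys are rejected.
#'
#' @param window_ms Response window, ms.
#' @param threshold_mult Pixel significance multiple of baseline SD.
#' @param pair_dist_um Maximum PV-Pyr soma separation, um.
#' @param contour_fraction Band-density contour fraction.
#' @param filter_radius Disk filter radius, px.
#' @param seed Integer seed for `simulate`.
#' @param ... Simulator overrides forwarded to [scracm_sim_config()]
#'   (unknown names are an error).
#' @return Object of class `run_config`.
#' @export
run_config <- function(window_ms = 75, threshold_mult = 4,
                       pair_dist_um = 100, contour_fraction = 0.70,
                       filter_radius = 10, seed = 1L, ...) {
  sim <- list(...)
  allowed <- setdiff(names(formals(scracm_sim_config)), "seed")
  bad <- setdiff(names(sim), allowed)
  if (length(bad))
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
          "scracmap_config_error")
  structure(list(window_ms = window_ms, threshold_mult = threshold_mult,
                 pair_dist_um = pair_dist_um,
                 contour_fraction = contour_fraction,
                 filter_radius = filter_radius, seed = as.integer(seed),
                 sim = sim),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

write_run_log <- function(config, out_dir, command, outputs) {
  write_json_file(list(command = command, config = unclass(config),
                       config_hash = config_hash(config),
                       outputs = outputs),
                  file.path(out_dir, "run.json"))
}

#' Run a pipeline command
#'
#' Commands:
#' \describe{
#'   \item{simulate}{Generate a synthetic sCRACM dataset plus paired
#'     recordings and write the sweep container to `container`.}
#'   \item{map}{Build per-cell sCRACM maps from the container; one CSV per
#'     cell plus a per-cell summary table.}
#'   \item{pairs}{Pair table: per-pair totals, fold ratios, cohort slope.}
#'   \item{pathways}{Cohort statistics JSON (geometric-mean slope, paired
#'     Wilcoxon PV vs Pyr, time-to-peak t-test).}
#'   \item{hierarchy}{Density-ratio analysis of the density images found
#'     under `images` (stems of CSV+JSON pairs): DR table CSV + ordering
#'     JSON.}
#'   \item{report}{Aggregate every CSV/JSON artifact under `out_dir` into
#'     one summary JSON.}
#' }
#' All commands are deterministic under a fixed seed and log their full
#' parameter set (with hash) to `run.json` in `out_dir`.
#'
#' @param config A [run_config()].
#' @param command One of `simulate`, `map`, `pairs`, `pathways`,
#'   `hierarchy`, `report`.
#' @param container Sweep-container directory (input or output).
#' @param out_dir Output directory for artifacts.
#' @param images For `hierarchy`: data.frame with columns `stem`, `source`,
#'   `target` naming density-image stems.
#' @return Invisible list of the artifacts written.
#' @export
run_pipeline <- function(config, command, container = NULL, out_dir = NULL,
                         images = NULL) {
  stopifnot(inherits(config, "run_config"))
  commands <- c("simulate", "map", "pairs", "pathways", "hierarchy", "report")
  if (!is.character(command) || length(command) != 1L ||
      !command %in% commands)
    abort(sprintf("unknown command; use one of: %s",
                  paste(commands, collapse = ", ")),
          "scracmap_usage_error")
  if (command != "simulate" && is.null(out_dir))
    abort("'out_dir' is required", "scracmap_usage_error")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  out <- switch(command,
    simulate = {
      if (is.null(container))
        abort("'container' is required for simulate", "scracmap_usage_error")
      sim_cfg <- do.call(scracm_sim_config,
                         c(config$sim, list(seed = config$seed)))
      ds <- generate_scracm_dataset(sim_cfg)
      paired <- list(
        conn = generate_paired_recording(TRUE, seed = config$seed),
        unconn = generate_paired_recording(FALSE, seed = config$seed + 1L)
      )
      write_sweep_container(list(dataset = ds, paired = paired), container)
      list(container = container)
    },
    map = {
      ds <- read_sweep_container(container)$dataset
      files <- character(0)
      summ <- list()
      for (id in names(ds$cells)) {
        m <- build_map(ds$cells[[id]], config$threshold_mult,
                       config$window_ms)
        f <- file.path(out_dir, paste0("map_", id, ".csv"))
        data.table::fwrite(data.table::as.data.table(m$values), f)
        files <- c(files, f)
        summ[[id]] <- data.frame(
          cell_id = id, cell_type = m$cell_type, layer = m$layer,
          total_pA = total_input(m),
          responsive_um2 = responsive_area(m),
          epsc_per_um2 = suppressWarnings(mean_epsc_per_area(m)))
      }
      f <- file.path(out_dir, "cells.csv")
      data.table::fwrite(do.call(rbind, summ), f)
      list(maps = files, cells = f)
    },
    pairs = {
      ds <- read_sweep_container(container)$dataset
      tab <- pipeline_pair_table(ds, config)
      f <- file.path(out_dir, "pairs.csv")
      data.table::fwrite(tab, f)
      list(pairs = f)
    },
    pathways = {
      cont <- read_sweep_container(container)
      ds <- cont$dataset
      tab <- pipeline_pair_table(ds, config)
      ok <- !tab$excluded
      res <- list(
        n_pairs = nrow(tab),
        n_excluded = sum(tab$excluded),
        cohort_slope = as.numeric(cohort_slope(tab$fold[ok])),
        cohort_slope_norm = as.numeric(cohort_slope(tab$fold_norm[ok])),
        wilcoxon_pv_vs_pyr = compare_pathways(
          list(tab$pv_total[ok], tab$pyr_total[ok]), "wilcoxon_paired"),
        t_time_to_peak = compare_pathways(
          list(tab$pv_ttp[ok], tab$pyr_ttp[ok]), "t_paired")
      )
      f <- file.path(out_dir, "pathways.json")
      write_json_file(res, f)
      list(pathways = f)
    },
    hierarchy = {
      if (is.null(images))
        abort("'images' is required for hierarchy", "scracmap_usage_error")
      recs <- lapply(seq_len(nrow(images)), function(i) {
        img <- read_density_image(images$stem[i])
        dmap <- optical_density_map(img, config$filter_radius)
        density_ratio(dmap, config$contour_fraction,
                      source = images$source[i], target = images$target[i])
      })
      tab <- dr_table(recs)
      f1 <- file.path(out_dir, "dr_matrix.csv")
      data.table::fwrite(tab, f1)
      ord <- hierarchy_order(tab)
      f2 <- file.path(out_dir, "hierarchy.json")
      write_json_file(list(order = ord$order,
                           mean_dr = as.list(ord$mean_dr),
                           sem = as.list(ord$sem),
                           pairwise_p = ord$pairwise_p,
                           classification = as.list(
                             stats::setNames(classify_pathway(tab$dr),
                                             paste(tab$source, tab$target,
                                                   sep = "->")))),
                      f2)
      list(dr_matrix = f1, hierarchy = f2)
    },
    report = {
      csvs <- list.files(out_dir, "\\.csv$", full.names = TRUE)
      jsons <- setdiff(list.files(out_dir, "\\.json$", full.names = TRUE),
                       file.path(out_dir, c("run.json", "report.json")))
      rep <- list(
        tables = lapply(stats::setNames(csvs, basename(csvs)), function(f) {
          d <- data.table::fread(f)
          list(rows = nrow(d), cols = ncol(d), fields = names(d))
        }),
        reports = lapply(stats::setNames(jsons, basename(jsons)),
                         jsonlite::read_json)
      )
      f <- file.path(out_dir, "report.json")
      write_json_file(rep, f)
      list(report = f)
    }
  )
  if (!is.null(out_dir)) write_run_log(config, out_dir, command, out)
  invisible(out)
}

# Shared by `pairs` and `pathways`: nearest-neighbor pairing within the
# distance threshold (ties by distance then lowest cell id), then per-pair
# totals, folds and times to peak.
pipeline_pair_table <- function(ds, config) {
  cells <- ds$cells
  types <- vapply(cells, `[[`, "", "cell_type")
  pvs <- names(cells)[types == "PV"]
  pyrs <- names(cells)[types == "Pyr"]
  rows <- list()
  for (pv_id in sort(pvs)) {
    pv <- cells[[pv_id]]
    cand <- Filter(function(id) identical(cells[[id]]$layer, pv$layer),
                   sort(pyrs))
    if (length(cand) == 0L) next
    d <- vapply(cand, function(id)
      pv$pixel_pitch_um * sqrt(sum((pv$soma - cells[[id]]$soma)^2)),
      numeric(1))
    d <- d[d <= config$pair_dist_um]
    if (length(d) == 0L) next
    pyr_id <- names(d)[order(d, names(d))][1] # nearest; ties by lowest id
    pc <- withCallingHandlers(
      pair_ratio(pv, cells[[pyr_id]], config$pair_dist_um,
                 config$threshold_mult, config$window_ms),
      scracmap_excluded_pair = function(w) invokeRestart("muffleWarning"))
    rows[[pv_id]] <- data.frame(
      pv_id = pv_id, pyr_id = pyr_id,
      pv_total = pc$pv_total, pyr_total = pc$pyr_total,
      fold = pc$fold, fold_norm = pc$fold_norm,
      distance_um = pc$distance_um, layer = pc$layer,
      excluded = pc$excluded,
      pv_ttp = suppressWarnings(
        time_to_peak(pv, config$threshold_mult, config$window_ms)),
      pyr_ttp = suppressWarnings(
        time_to_peak(cells[[pyr_id]], config$threshold_mult,
                     config$window_ms)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
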