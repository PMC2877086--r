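#' Run one simulation with stop rules and records
#'
#' Initializes the state, then advances in `snapshot_interval` chunks,
#' collecting a [morphometrics_record()] row at MCS 0 and after every chunk,
#' until a stop rule fires or `max_mcs` is exhausted. Stop rules:
#' `"boundary"` (tumor touches a domain face), `"cells:N"` (at least N tumor
#' cells), `"days:N"`. A run that exhausts `max_mcs` without meeting its stop
#' rule is marked censored.
#'
#' @param config a [sim_config()].
#' @param stop stop rule string, e.g. `"boundary"`, `"cells:1000"`,
#'   `"days:30"`.
#' @param out_dir optional directory: writes `config.yaml`, `metrics.csv`,
#'   the final per-cell `census.csv`, a reproducibility `manifest.yaml`, a
#'   plain-text log, and (if `snapshots = TRUE`) a label TIFF per snapshot.
#' @param snapshots write label snapshots per record (needs `out_dir`).
#' @param seed optional seed override.
#' @return An object of class `cpm_run`: list with `records` (data.frame),
#'   `sim`, `config`, `stop_rule`, `stopped_by` (`"rule"` or `"censored"`).
#' @export
run_single <- function(config, stop = "boundary", out_dir = NULL,
                       snapshots = FALSE, seed = NULL) {
  rule <- parse_stop_rule(stop)
  sim <- cpm_sim(config, seed = seed)
  config <- sim$config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  records <- morphometrics_record(sim)
  log_lines <- character(0)
  stopped <- rule_met(rule, records[nrow(records), ], config)
  while (!stopped && sim_mcs(sim) < config$max_mcs) {
    chunk <- min(config$snapshot_interval, config$max_mcs - sim_mcs(sim))
    run_mcs(sim, chunk)
    rec <- morphometrics_record(sim)
    records <- rbind(records, rec)
    log_lines <- c(log_lines, sprintf(
      "MCS %d (day %.2f): %d cells, V = %d, s = %.3f",
      rec$mcs, rec$day, rec$n_cells, rec$tumor_volume, rec$sphericity))
    if (!is.null(out_dir) && snapshots)
      write_snapshot(sim, file.path(out_dir, sprintf("labels_mcs%06d.tiff", rec$mcs)))
    stopped <- rule_met(rule, rec, config)
  }
  sim_audit(sim)
  out <- structure(list(records = records, sim = sim, config = config,
                        stop_rule = stop,
                        stopped_by = if (stopped) "rule" else "censored"),
                   class = "cpm_run")
  if (!is.null(out_dir)) {
    write.csv(records, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(cell_census(sim), file.path(out_dir, "census.csv"), row.names = FALSE)
    manifest <- list(package_version = as.character(utils::packageVersion("tumorcpm")),
                     config_hash = config_hash(config),
                     seed = config$seed, stop_rule = stop,
                     stopped_by = out$stopped_by,
                     final_mcs = sim_mcs(sim))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.cpm_run <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  cat(sprintf("<cpm_run> stop rule '%s' (%s) after %d MCS (day %.1f): %d cells, s = %.3f\n",
              x$stop_rule, x$stopped_by, last$mcs, last$day, last$n_cells,
              last$sphericity))
  invisible(x)
}

parse_stop_rule <- function(stop) {
  if (identical(stop, "boundary")) return(list(type = "boundary"))
  m <- regmatches(stop, regexec("^(cells|days):([0-9.]+)$", stop))[[1]]
  if (length(m) == 3)
    return(list(type = m[2], value = as.numeric(m[3])))
  stop("unknown stop rule: ", stop)
}

rule_met <- function(rule, rec, config) {
  switch(rule$type,
         boundary = isTRUE(rec$touches_boundary),
         cells = rec$n_cells >= rule$value,
         days = rec$day >= rule$value)
}

#' Plan and run a (G, gamma) sweep
#'
#' `sweep_plan()` describes a grid over the diffusion-limitation parameter G
#' and the tumor-TM surface tension gamma (defaults: the study's grid,
#' G in 50..200 and gamma in 6..0 via J(t,t) = 4..16 at J(t,TM) = 8) with
#' replicate seeds derived deterministically from `(base_seed, G, gamma,
#' replicate)`. `run_sweep()` executes every combination and summarises each
#' run: sphericity and mean circularity at the stage cell count and at
#' boundary reach, days to each, and the characteristic time tau, plus
#' across-replicate means and standard deviations. Combinations that never
#' meet a milestone are reported censored (NA), never as zero; individual
#' failures are recorded per cell and the sweep continues.
#'
#' @param G_values,gamma_values numeric grids.
#' @param replicates replicate count per combination.
#' @param base_seed integer; per-run seeds are derived from it.
#' @param config a template [sim_config()] (its L, rates etc. are kept; k and
#'   J_tt are overridden per combination).
#' @param stage cell count defining the fixed-stage metrics.
#' @param stop stop rule passed to [run_single()] (the stage is always also
#'   collected en route).
#' @param out_dir optional root directory; each run writes into
#'   `G<G>_gamma<g>_rep<i>/`.
#' @return `run_sweep`: a list with `runs` (per-run summary data.frame) and
#'   `summary` (per-combination aggregate data.frame).
#' @export
sweep_plan <- function(G_values = c(50, 100, 150, 200),
                       gamma_values = c(6, 4, 2, 0),
                       replicates = 1L,
                       base_seed = 1L,
                       config = sim_config(),
                       stage = 1000L,
                       stop = "boundary") {
  structure(list(G_values = G_values, gamma_values = gamma_values,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 config = config, stage = as.integer(stage), stop = stop),
            class = "cpm_sweep_plan")
}

sweep_seed <- function(base_seed, iG, igamma, rep) {
  as.integer((base_seed + 7919 * iG + 104729 * igamma + 997 * rep) %% 2147483647L)
}

#' @param plan a `sweep_plan()`.
#' @rdname sweep_plan
#' @export
run_sweep <- function(plan, out_dir = NULL) {
  stopifnot(inherits(plan, "cpm_sweep_plan"))
  rows <- list()
  for (iG in seq_along(plan$G_values)) {
    for (ig in seq_along(plan$gamma_values)) {
      for (r in seq_len(plan$replicates)) {
        G <- plan$G_values[iG]; gamma <- plan$gamma_values[ig]
        seed <- sweep_seed(plan$base_seed, iG, ig, r)
        cfg <- modify_config(plan$config, G = G, gamma = gamma, seed = seed)
        dir <- if (is.null(out_dir)) NULL else
          file.path(out_dir, sprintf("G%g_gamma%g_rep%d", G, gamma, r))
        res <- tryCatch(
          summarise_run(run_single(cfg, stop = plan$stop, out_dir = dir),
                        stage = plan$stage),
          error = function(e) data.frame(error = conditionMessage(e)))
        res$G <- G; res$gamma <- gamma; res$replicate <- r; res$seed <- seed
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  runs <- do.call(rbind_fill, rows)
  list(runs = runs, summary = aggregate_sweep(runs))
}

# rebuild a config with a new (G, gamma, seed), keeping everything else
modify_config <- function(cfg, G, gamma, seed) {
  sim_config(L = cfg$L, voxel_size = cfg$voxel_size,
             mcs_per_day = cfg$mcs_per_day,
             gamma = gamma, J_ttm = cfg$J_ttm,
             T_m = cfg$T_m, lambda_V = cfg$lambda_V, lambda_S = cfg$lambda_S,
             V_doubling = cfg$V_doubling, shape_constant = cfg$shape_constant,
             D_c = cfg$D_c, D_m = cfg$D_m, delta = cfg$delta, mu = cfg$mu,
             S_prod = cfg$S_prod, G = G,
             G_mapping_constant = cfg$G_mapping_constant, g = cfg$g,
             quiescence_enabled = cfg$quiescence_enabled,
             necrosis_enabled = cfg$necrosis_enabled,
             c_threshold = cfg$c_threshold, g_necrotic = cfg$g_necrotic,
             divide_on_target = cfg$divide_on_target, seed = seed,
             snapshot_interval = cfg$snapshot_interval, max_mcs = cfg$max_mcs)
}

#' Stage and boundary summary of one run
#'
#' @param run a `cpm_run`.
#' @param stage cell count defining the fixed-stage snapshot.
#' @return One-row data.frame: metrics at the stage crossing, at boundary
#'   reach, and the tau fit (NA where censored).
#' @export
summarise_run <- function(run, stage = 1000L) {
  rec <- run$records
  at_stage <- which(rec$n_cells >= stage)
  st <- if (length(at_stage)) rec[min(at_stage), ] else NULL
  bd <- boundary_reach_time(rec)
  at_bd <- if (!bd$censored) rec[which(rec$touches_boundary)[1], ] else NULL
  fit <- if (sum(is.finite(rec$sphericity)) >= 5)
    fit_characteristic_time(rec$day, rec$sphericity) else NULL
  data.frame(
    s_at_stage = if (!is.null(st)) st$sphericity else NA_real_,
    cbar_at_stage = if (!is.null(st)) st$mean_circularity else NA_real_,
    day_at_stage = if (!is.null(st)) st$day else NA_real_,
    s_at_boundary = if (!is.null(at_bd)) at_bd$sphericity else NA_real_,
    cbar_at_boundary = if (!is.null(at_bd)) at_bd$mean_circularity else NA_real_,
    day_at_boundary = if (bd$censored) NA_real_ else bd$day,
    censored_boundary = bd$censored,
    tau = if (!is.null(fit) && fit$converged) fit$tau else NA_real_,
    final_cells = rec$n_cells[nrow(rec)],
    final_mcs = rec$mcs[nrow(rec)])
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  })
  do.call(rbind, dfs)
}

aggregate_sweep <- function(runs) {
  if (is.null(runs$G)) return(NULL)
  key <- interaction(runs$G, runs$gamma, drop = TRUE)
  agg <- lapply(split(runs, key), function(d) {
    num <- c("s_at_stage", "cbar_at_stage", "day_at_stage", "s_at_boundary",
             "cbar_at_boundary", "day_at_boundary", "tau")
    out <- data.frame(G = d$G[1], gamma = d$gamma[1], n_rep = nrow(d))
    for (cn in num) {
      v <- suppressWarnings(as.numeric(d[[cn]]))
      out[[paste0(cn, "_mean")]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      out[[paste0(cn, "_sd")]] <- if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_
    }
    out$n_censored <- sum(d$censored_boundary %in% TRUE)
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$G, -out$gamma), ]
}
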