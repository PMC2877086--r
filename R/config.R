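#' Simulation configuration
#'
#' Builds the full parameter set of the 3D Cellular Potts tumor model: lattice
#' geometry, contact energies, constraint strengths, field constants, growth
#' law, optional phenotype rules, and run control. Defaults are the published
#' 3D study conditions: a 100^3 lattice of 60 um voxels (6 mm domain), 400 MCS
#' per simulated day, tumor--TM contact energy 8, motility 60, inverse
#' compressibility 20, inverse membrane elasticity 0.4, doubling volume 54
#' voxels, and target-surface scaling \eqn{S_t = 6 V_t^{2/3}} anchored at the
#' initial 3x3x3 cell cube (27 voxels, 54 faces).
#'
#' The diffusion-limitation parameter \eqn{G} is the nondimensional ratio of
#' the maximum tumor substrate-consumption rate to the maximum substrate
#' transport rate; the working form is \eqn{G = \kappa\, k L^2 / D_c} with
#' mapping constant \eqn{\kappa = 1}, so the study's consumption range
#' k = 0.05--0.2 corresponds to G = 50--200 at L = 100, D_c = 10. Exactly one
#' of `k` and `G` may be supplied; the other is derived. Likewise the tumor-TM
#' surface tension \eqn{\gamma = J(t,TM) - J(t,t)/2} may be given either via
#' `gamma` or via `J_tt`; the study varies J(t,t) over 4--16, i.e. gamma over
#' 6--0.
#'
#' @param L voxels per lattice side (cubic domain), at least 8.
#' @param voxel_size physical voxel edge length in micrometers.
#' @param mcs_per_day Monte Carlo Steps per simulated day.
#' @param J_tt tumor-tumor contact energy. Supply this or `gamma`, not both.
#' @param J_ttm tumor-TM contact energy.
#' @param gamma tumor-TM surface tension; sets `J_tt = 2 * (J_ttm - gamma)`.
#' @param T_m cell motility (the Metropolis "temperature").
#' @param lambda_V inverse compressibility (volume-constraint strength).
#' @param lambda_S inverse membrane elasticity (surface-constraint strength).
#' @param V_doubling doubling volume in voxels; mitosis triggers at this size.
#' @param shape_constant constant A in the target-surface law
#'   \eqn{S_t = A V_t^{2/3}}.
#' @param neighbor_order interaction range order (squared lattice distance);
#'   4 gives the 32-site neighborhood used throughout.
#' @param D_c,D_m substrate and MDE diffusion constants (voxel^2/MCS).
#' @param delta TM degradation rate per unit MDE (1/MCS).
#' @param mu MDE production rate per proliferating tumor cell (conc./MCS).
#' @param S_prod substrate production rate per unit TM (conc./MCS).
#' @param k substrate consumption rate per tumor cell (conc./MCS), or NULL if
#'   `G` is given.
#' @param G diffusion-limitation parameter, or NULL if `k` is given.
#' @param G_mapping_constant multiplicative constant of the G <-> k mapping.
#' @param g growth rate: target-volume voxels per MCS per unit substrate.
#' @param quiescence_enabled,necrosis_enabled phenotype rule flags (at most
#'   one may be TRUE; the model studies them separately).
#' @param c_threshold substrate threshold for quiescence/necrosis, in [0, 1].
#' @param g_necrotic negative growth rate of necrotic cells (voxels/MCS).
#' @param divide_on_target if TRUE, trigger mitosis on target volume rather
#'   than actual volume.
#' @param seed RNG seed for the simulation stream.
#' @param snapshot_interval MCS between morphometric records.
#' @param max_mcs hard cap on simulated MCS.
#'
#' @return An object of class `cpm_config` (a validated named list).
#' @examples
#' cfg <- sim_config(L = 50, G = 100, gamma = 2, seed = 1)
#' cfg$k            # consumption rate derived from G
#' surface_tension(cfg$J_ttm, cfg$J_tt)
#' @export
sim_config <- function(L = 100L,
                       voxel_size = 60,
                       mcs_per_day = 400L,
                       J_tt = NULL,
                       J_ttm = 8,
                       gamma = NULL,
                       T_m = 60,
                       lambda_V = 20,
                       lambda_S = 0.4,
                       V_doubling = 54,
                       shape_constant = 6,
                       neighbor_order = 4L,
                       D_c = 10,
                       D_m = 0.01,
                       delta = 0.5,
                       mu = 1,
                       S_prod = 0.1,
                       k = NULL,
                       G = NULL,
                       G_mapping_constant = 1,
                       g = 0.3,
                       quiescence_enabled = FALSE,
                       necrosis_enabled = FALSE,
                       c_threshold = 0.05,
                       g_necrotic = -g / 2,
                       divide_on_target = FALSE,
                       seed = 42L,
                       snapshot_interval = 400L,
                       max_mcs = 40000L) {
  if (!is.null(J_tt) && !is.null(gamma))
    stop("supply either `J_tt` or `gamma`, not both")
  if (is.null(J_tt)) {
    if (is.null(gamma)) gamma <- 6
    J_tt <- 2 * (J_ttm - gamma)
  }
  if (!is.null(k) && !is.null(G))
    stop("supply either `k` or `G`, not both (the other is derived)")
  if (is.null(k)) {
    if (is.null(G)) G <- 50
    k <- k_from_G(G, L = L, D_c = D_c, mapping_constant = G_mapping_constant)
  } else {
    # diffusion-free configurations (D_c = 0) have no finite G
    G <- if (D_c > 0) G_from_k(k, L = L, D_c = D_c,
                               mapping_constant = G_mapping_constant)
         else NA_real_
  }
  cfg <- list(
    L = as.integer(L), voxel_size = voxel_size,
    mcs_per_day = as.integer(mcs_per_day),
    J_tt = J_tt, J_ttm = J_ttm,
    T_m = T_m, lambda_V = lambda_V, lambda_S = lambda_S,
    V_doubling = V_doubling, shape_constant = shape_constant,
    neighbor_order = as.integer(neighbor_order),
    D_c = D_c, D_m = D_m, delta = delta, mu = mu, S_prod = S_prod,
    k = k, G = G, G_mapping_constant = G_mapping_constant, g = g,
    quiescence_enabled = isTRUE(quiescence_enabled),
    necrosis_enabled = isTRUE(necrosis_enabled),
    c_threshold = c_threshold, g_necrotic = g_necrotic,
    divide_on_target = isTRUE(divide_on_target),
    seed = as.integer(seed),
    snapshot_interval = as.integer(snapshot_interval),
    max_mcs = as.integer(max_mcs))
  class(cfg) <- "cpm_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$L >= 3)  # the seeded initial state additionally needs L >= 8
  if (cfg$J_tt <= 0 || cfg$J_ttm <= 0)
    stop("all contact energies must be positive (cells must not dissociate)")
  if (cfg$T_m <= 0) stop("T_m must be positive")
  if (cfg$c_threshold < 0 || cfg$c_threshold > 1)
    stop("c_threshold must lie in [0, 1]")
  if (cfg$quiescence_enabled && cfg$necrosis_enabled)
    stop("quiescence and necrosis rules are studied separately; enable at most one")
  if (cfg$neighbor_order != 4L)
    stop("only the fourth-order (32-neighbor) interaction range is supported")
  invisible(cfg)
}

#' @export
print.cpm_config <- function(x, ...) {
  cat("Cellular Potts tumor-growth configuration\n")
  cat(sprintf("  lattice      : %d^3 voxels (%.1f mm domain), %d MCS/day\n",
              x$L, x$L * x$voxel_size / 1000, x$mcs_per_day))
  cat(sprintf("  adhesion     : J(t,t) = %g, J(t,TM) = %g  ->  gamma = %g\n",
              x$J_tt, x$J_ttm, surface_tension(x$J_ttm, x$J_tt)))
  cat(sprintf("  constraints  : T_m = %g, lambda_V = %g, lambda_S = %g\n",
              x$T_m, x$lambda_V, x$lambda_S))
  cat(sprintf("  fields       : D_c = %g, D_m = %g, delta = %g, mu = %g, S_prod = %g\n",
              x$D_c, x$D_m, x$delta, x$mu, x$S_prod))
  cat(sprintf("  growth       : g = %g, V_doubling = %g, k = %g (G = %g)\n",
              x$g, x$V_doubling, x$k, x$G))
  if (x$quiescence_enabled || x$necrosis_enabled)
    cat(sprintf("  phenotype    : %s below c = %g%s\n",
                if (x$quiescence_enabled) "quiescence" else "necrosis",
                x$c_threshold,
                if (x$necrosis_enabled) sprintf(", g_necrotic = %g", x$g_necrotic) else ""))
  cat(sprintf("  run          : seed %d, snapshot every %d MCS, max %d MCS\n",
              x$seed, x$snapshot_interval, x$max_mcs))
  invisible(x)
}

#' Tumor-TM surface tension
#'
#' \eqn{\gamma = J(t, TM) - J(t, t) / 2}: the effective tension of the
#' tumor--tissue-matrix interface, controlling whether tumor cells cluster
#' (gamma > 0) or disperse.
#'
#' @param J_ttm tumor-TM contact energy.
#' @param J_tt tumor-tumor contact energy.
#' @return The surface tension (same energy units as J).
#' @examples
#' surface_tension(8, 4)   # 6, the study's upper value
#' surface_tension(8, 16)  # 0
#' @export
surface_tension <- function(J_ttm, J_tt) J_ttm - J_tt / 2

#' Diffusion-limitation parameter and consumption rate
#'
#' Working mapping \eqn{G = \kappa\, k L^2 / D_c} between the substrate
#' consumption rate per cell `k` and the nondimensional diffusion-limitation
#' parameter `G` (ratio of maximum tumor-growth rate to maximum substrate
#' transport rate). With the defaults (kappa = 1, L = 100, D_c = 10),
#' k = 0.05 maps to G = 50 and k = 0.2 to G = 200.
#'
#' @param G diffusion-limitation parameter.
#' @param k substrate consumption rate per tumor cell (conc./MCS).
#' @param L lattice size (voxels per side).
#' @param D_c substrate diffusion constant (voxel^2/MCS).
#' @param mapping_constant multiplicative constant kappa of the mapping.
#' @return The derived `k` (for `k_from_G`) or `G` (for `G_from_k`).
#' @examples
#' G_from_k(0.05, L = 100, D_c = 10)  # 50
#' k_from_G(200, L = 100, D_c = 10)   # 0.2
#' @export
k_from_G <- function(G, L = 100, D_c = 10, mapping_constant = 1) {
  stopifnot(G > 0, L > 0, D_c > 0)
  G * D_c / (mapping_constant * L^2)
}

#' @rdname k_from_G
#' @export
G_from_k <- function(k, L = 100, D_c = 10, mapping_constant = 1) {
  stopifnot(k > 0, L > 0, D_c > 0)
  mapping_constant * k * L^2 / D_c
}

#' Forward-Euler substep count for a diffusion constant
#'
#' Smallest integer n such that D/n satisfies the 3D explicit-Euler stability
#' bound (D dt <= safety/6 at dx = 1) with safety factor 0.8.
#'
#' @param D diffusion constant (voxel^2/MCS), non-negative.
#' @return Integer substep count (>= 1).
#' @examples
#' stability_substeps(0)    # 1
#' stability_substeps(10)   # 75
#' @export
stability_substeps <- function(D) {
  stopifnot(D >= 0)
  cpp_stability_substeps(D)
}

#' Read or write a configuration file
#'
#' Flat YAML key-value files mirroring the [sim_config()] field names. `G` and
#' `gamma` are stored for readability but `k` and `J_tt` are authoritative on
#' read (they are re-derived only when absent).
#'
#' @param cfg a `cpm_config` object.
#' @param path file path.
#' @return `read_config` returns a `cpm_config`; `write_config` returns the
#'   path invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cpm_config"))
  x <- unclass(cfg)
  x$gamma <- surface_tension(cfg$J_ttm, cfg$J_tt)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::yaml.load_file(path)
  args <- x[setdiff(names(x), c("G", "gamma"))]
  if (is.null(args$k) && !is.null(x$G)) args$G <- x$G
  if (is.null(args$J_tt) && !is.null(x$gamma)) args$gamma <- x$gamma
  do.call(sim_config, args)
}
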