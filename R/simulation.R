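#' Create a simulation from a configuration
#'
#' Builds the initial state: eight tumor cells, each a 3x3x3 voxel cube,
#' forming a 6x6x6 block at the domain center; every other voxel belongs to
#' the single unconstrained tissue-matrix (TM) Generalized Cell. Fields start
#' uniform: TM density f = 1 (also under the tumor seed; degradation begins at
#' the first MCS), MDE m = 0, substrate c = 1.
#'
#' @param config a [sim_config()] object.
#' @param seed optional RNG seed overriding `config$seed`.
#' @return A `cpm_sim` object (external-pointer handle plus its config).
#' @examples
#' sim <- cpm_sim(sim_config(L = 20, seed = 1))
#' summary(sim)
#' @export
cpm_sim <- function(config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  ptr <- cpp_sim_new(config, config$seed)
  structure(list(ptr = ptr, config = config), class = "cpm_sim")
}

#' Build a simulation around an explicit label lattice
#'
#' Test-oriented constructor: takes an arbitrary L x L x L integer label array
#' (ids >= 1) and a per-id type vector (0 = TM, 1 = tumor), computes the
#' registry (volumes, surfaces, centers of mass) from the array, and sets each
#' cell's targets to its current values so the constraint energy starts at
#' zero.
#'
#' @param sigma 3D integer array of cell ids (>= 1).
#' @param types integer vector, `types[id]` in {0 = TM, 1 = tumor}.
#' @param config a [sim_config()] whose `L` matches `dim(sigma)`.
#' @param seed optional RNG seed.
#' @return A `cpm_sim` object.
#' @export
sim_from_sigma <- function(sigma, types, config, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  ptr <- cpp_sim_from_sigma(sigma, as.integer(types), config, config$seed)
  structure(list(ptr = ptr, config = config), class = "cpm_sim")
}

#' @export
print.cpm_sim <- function(x, ...) {
  cfg <- x$config
  n <- sim_cell_counts(x)
  cat(sprintf(
    "<cpm_sim> %d^3 lattice, MCS %d (day %.2f): %d tumor cell(s) [%d proliferating, %d quiescent, %d necrotic]\n",
    cfg$L, sim_mcs(x), sim_mcs(x) / cfg$mcs_per_day,
    n[["total"]], n[["proliferating"]], n[["quiescent"]], n[["necrotic"]]))
  invisible(x)
}

#' @export
summary.cpm_sim <- function(object, ...) {
  print(object)
  rec <- morphometrics_record(object)
  cat(sprintf("  tumor volume %d voxels, sphericity %.3f, mean circularity %.3f\n",
              rec$tumor_volume, rec$sphericity, rec$mean_circularity))
  cat(sprintf("  3D components: %d; touches boundary: %s\n",
              rec$n_components_3d, rec$touches_boundary))
  invisible(rec)
}

#' Advance a simulation
#'
#' Runs `n_mcs` Monte Carlo Steps. One MCS is L^3 copy attempts (the Metropolis
#' sweep), followed by the field update and the biology update (growth,
#' mitosis, phenotype rules), in that fixed order.
#'
#' @param sim a `cpm_sim` object (modified in place).
#' @param n_mcs number of MCS to run.
#' @return The simulation, invisibly.
#' @export
run_mcs <- function(sim, n_mcs) {
  stopifnot(inherits(sim, "cpm_sim"), n_mcs >= 0)
  if (n_mcs > 0) cpp_sim_run(sim$ptr, as.integer(n_mcs))
  invisible(sim)
}

#' Engine accessors and low-level operations
#'
#' Direct views of the running state and the elementary operations of the
#' Cellular Potts engine, exposed for analysis and testing: the label lattice,
#' the three fields, the cell registry, total energies, the local energy
#' difference of a candidate copy, single Metropolis attempts, forced cell
#' division, and the state audit (recomputes every ledger from the lattice and
#' stops on any mismatch).
#'
#' @param sim a `cpm_sim` object.
#' @param which field name: `"f"` (TM density), `"m"` (MDE), `"c"` (substrate).
#' @param value replacement 3D array (for `sim_set_field`).
#' @param x integer site coordinates (0-based, length 3).
#' @param id_new candidate cell id to copy into `x`.
#' @param id cell id.
#' @param axis optional unit 3-vector: forced division plane normal.
#' @param n number of attempts.
#' @name engine
#' @return See each function; arrays are `L x L x L`.
NULL

#' @rdname engine
#' @export
sim_sigma <- function(sim) cpp_sim_sigma(sim$ptr)

#' @rdname engine
#' @export
sim_field <- function(sim, which = c("c", "m", "f")) {
  cpp_sim_field(sim$ptr, match.arg(which))
}

#' @rdname engine
#' @export
sim_set_field <- function(sim, which, value) {
  cpp_sim_set_field(sim$ptr, match.arg(which, c("c", "m", "f")), value)
  invisible(sim)
}

#' @rdname engine
#' @export
sim_cells <- function(sim) {
  df <- cpp_sim_cells(sim$ptr)
  df$type <- c("TM", "tumor")[df$type + 1L]
  df$state <- c("proliferating", "quiescent", "necrotic")[df$state + 1L]
  df
}

#' @rdname engine
#' @export
sim_mcs <- function(sim) as.integer(cpp_sim_mcs(sim$ptr))

#' @rdname engine
#' @export
sim_cell_counts <- function(sim) {
  df <- cpp_sim_cells(sim$ptr)
  tum <- df$type == 1L & df$V > 0L
  c(total = sum(tum),
    proliferating = sum(tum & df$state == 0L),
    quiescent = sum(tum & df$state == 1L),
    necrotic = sum(tum & df$state == 2L))
}

#' @rdname engine
#' @export
tumor_mask <- function(sim) {
  df <- cpp_sim_cells(sim$ptr)
  tumor_ids <- df$id[df$type == 1L]
  sig <- cpp_sim_sigma(sim$ptr)
  array(sig %in% tumor_ids, dim = dim(sig))
}

#' @rdname engine
#' @export
contact_energy_total <- function(sim) cpp_sim_contact_energy(sim$ptr)

#' @rdname engine
#' @export
effective_energy <- function(sim) cpp_sim_effective_energy(sim$ptr)

#' @rdname engine
#' @export
delta_H <- function(sim, x, id_new) {
  cpp_sim_delta_h(sim$ptr, as.integer(x), as.integer(id_new))
}

#' @rdname engine
#' @export
apply_copy <- function(sim, x, id_new) {
  cpp_sim_apply_copy(sim$ptr, as.integer(x), as.integer(id_new))
  invisible(sim)
}

#' @rdname engine
#' @export
metropolis_attempt <- function(sim) as.logical(cpp_sim_attempt(sim$ptr))

#' @rdname engine
#' @export
metropolis_sweep <- function(sim) cpp_sim_sweep(sim$ptr)

#' @rdname engine
#' @export
sim_audit <- function(sim) cpp_sim_audit(sim$ptr)

#' @rdname engine
#' @export
sim_touches_boundary <- function(sim) cpp_sim_touches_boundary(sim$ptr)

#' @rdname engine
#' @export
divide_cell <- function(sim, id, axis = NULL) {
  if (!is.null(axis)) axis <- as.numeric(axis)
  cpp_sim_mitose(sim$ptr, as.integer(id), axis)
}

#' @rdname engine
#' @export
update_fields <- function(sim) {
  cpp_sim_update_fields(sim$ptr)
  invisible(sim)
}

#' @rdname engine
#' @export
biology_step <- function(sim, grow = TRUE, divide = TRUE, phenotype = TRUE) {
  cpp_sim_biology_step(sim$ptr, grow, divide, phenotype)
  invisible(sim)
}

#' @rdname engine
#' @export
set_cell <- function(sim, id, V_t = NULL, S_t = NULL,
                     state = c(NA, "proliferating", "quiescent", "necrotic")[1]) {
  st <- NULL
  if (!is.na(state) && !is.null(state)) {
    st <- match(match.arg(state, c("proliferating", "quiescent", "necrotic")),
                c("proliferating", "quiescent", "necrotic")) - 1L
  }
  cpp_sim_set_cell(sim$ptr, as.integer(id), V_t, S_t, st)
  invisible(sim)
}

#' Fourth-order neighborhood offsets
#'
#' Integer offsets of the interaction neighborhood: all lattice vectors with
#' squared length between 1 and `order`. Order 4 gives the 32-site
#' neighborhood (shells 6 + 12 + 8 + 6) used for contact energies and copy
#' attempts.
#'
#' @param order maximum squared distance (interaction range order).
#' @return Integer matrix with 3 columns (dx, dy, dz).
#' @examples
#' nrow(neighbor_offsets(4))  # 32
#' @export
neighbor_offsets <- function(order = 4L) cpp_neighbor_offsets(as.integer(order))

#' Target surface area for a target volume
#'
#' \eqn{S_t = A V_t^{2/3}} with A fixed by the initial cubic cell
#' (V_t = 27 voxels, S_t = 54 faces, so A = 6): the nondimensional
#' surface-to-volume ratio stays constant as cells grow, keeping them roughly
#' spherical. Non-positive target volumes (necrotic shrink-out) give S_t = 0.
#'
#' @param V_t target volume (voxels).
#' @param shape_constant the constant A.
#' @return Target surface area.
#' @examples
#' update_target_surface(27)  # 54
#' @export
update_target_surface <- function(V_t, shape_constant = 6) {
  ifelse(V_t > 0, shape_constant * V_t^(2 / 3), 0)
}
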