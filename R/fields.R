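#' Standalone field operators
#'
#' The elementary pieces of the per-MCS field update, operating on plain 3D
#' arrays with the same stencils as the engine. The full update (inside
#' [run_mcs()] / [update_fields()]) is, per MCS: forward-Euler substeps of
#' substrate diffusion plus saturating production `S_prod * f * (1 - c)`
#' (clamped to [0, 1]), with TM degradation `f <- f * (1 - delta * m * dt)`
#' sharing the substrate substep; MDE diffusion at its own substep count; then
#' once per MCS the point coupling at each proliferating tumor cell's
#' center-of-mass voxel (deposit `mu` of MDE capped at 1, consume `k` of
#' substrate floored at 0).
#'
#' @param field,f,m 3D numeric arrays (equal dims).
#' @param D diffusion constant (voxel^2 per MCS).
#' @param dt Euler substep length (MCS).
#' @param nsteps number of substeps to apply.
#' @param delta TM degradation rate per unit MDE.
#' @param clamp01 clamp values into [0, 1] after each substep.
#' @name field-operators
NULL

#' @describeIn field-operators 7-point no-flux (mirrored-boundary) Laplacian;
#'   a linear operator returning the array of second differences.
#' @export
laplacian_noflux <- function(field) cpp_laplacian_noflux(field)

#' @describeIn field-operators `nsteps` forward-Euler diffusion substeps
#'   `v <- v + dt * D * laplacian(v)`.
#' @export
diffuse_field <- function(field, D, dt = 1, nsteps = 1, clamp01 = FALSE) {
  cpp_diffuse(field, D, dt, as.integer(nsteps), clamp01)
}

#' @describeIn field-operators TM degradation by MDE,
#'   `f <- f * (1 - delta * m * dt)` clamped at 0, applied `nsteps` times
#'   with `m` held fixed. Degradation does not consume MDE, and f never
#'   increases.
#' @export
degrade_tm <- function(f, m, delta, dt = 1, nsteps = 1) {
  stopifnot(delta >= 0, all(dim(f) == dim(m)))
  cpp_degrade_tm(f, m, delta, dt, as.integer(nsteps))
}
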