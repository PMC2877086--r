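#' Snapshot input/output
#'
#' Label lattices are written as multi-page 16-bit TIFF (one z-slice per
#' page) with a YAML sidecar recording MCS, day, lattice size and the config
#' hash; fields as multi-page 32-bit TIFF (values are already in [0, 1]).
#' Label round trips are exact for up to 65535 cells.
#'
#' @param sim a `cpm_sim` object.
#' @param path output TIFF path (the sidecar gets the extension `.meta.yaml`).
#' @param which field name (`"c"`, `"m"`, `"f"`) for field snapshots.
#' @return `write_snapshot`/`write_field_snapshot` return `path` invisibly;
#'   `read_snapshot` returns a list with `sigma` (3D integer array) and
#'   `meta`.
#' @export
write_snapshot <- function(sim, path) {
  sig <- sim_sigma(sim)
  L <- dim(sig)[1]
  if (max(sig) > 65535L) stop("more than 65535 cells; 16-bit labels overflow")
  pages <- lapply(seq_len(dim(sig)[3]), function(z) sig[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(mcs = sim_mcs(sim),
               day = sim_mcs(sim) / sim$config$mcs_per_day,
               L = L,
               config_hash = config_hash(sim$config))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  L <- nrow(pages[[1]])
  sig <- array(0L, dim = c(L, ncol(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) sig[, , z] <- as.integer(round(pages[[z]] * 65535))
  meta_file <- sidecar_path(path)
  meta <- if (file.exists(meta_file)) yaml::yaml.load_file(meta_file) else NULL
  list(sigma = sig, meta = meta)
}

#' @rdname write_snapshot
#' @export
write_field_snapshot <- function(sim, which, path) {
  fld <- sim_field(sim, which)
  pages <- lapply(seq_len(dim(fld)[3]), function(z) fld[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", "", path, ignore.case = TRUE) |>
  paste0(".meta.yaml")

# polynomial rolling hash of the YAML-serialized config (stable across
# sessions; avoids an external digest dependency)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(cfg), precision = 15))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Per-cell census
#'
#' One row per Generalized Cell: id, type, phenotypic state, volume, target
#' volume, surface, target surface, center of mass, and the substrate
#' concentration at the center-of-mass voxel.
#'
#' @param sim a `cpm_sim` object.
#' @return A data.frame.
#' @export
cell_census <- function(sim) {
  df <- sim_cells(sim)
  cfld <- sim_field(sim, "c")
  L <- sim$config$L
  com_voxel <- function(x) pmin(pmax(ceiling(x - 0.5), 0L), L - 1L)
  c_com <- rep(NA_real_, nrow(df))
  ok <- df$V > 0
  if (any(ok)) {
    ix <- com_voxel(df$com_x[ok]); iy <- com_voxel(df$com_y[ok]); iz <- com_voxel(df$com_z[ok])
    c_com[ok] <- cfld[cbind(ix + 1L, iy + 1L, iz + 1L)]
  }
  df$c_com <- c_com
  df
}

#' Export a mid-plane section as a PNG image
#'
#' Writes the tumor occupancy of one mid-plane section (XY, XZ or YZ) as a
#' black-and-white PNG, for visual comparison of section morphologies.
#'
#' @param sim a `cpm_sim` object.
#' @param plane `"xy"`, `"xz"` or `"yz"` (section at plane index
#'   `floor(L/2)`, 0-based).
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
write_section_png <- function(sim, plane = c("xy", "xz", "yz"), path) {
  plane <- match.arg(plane)
  mask <- tumor_mask(sim)
  mid <- floor(dim(mask) / 2) + 1L
  sec <- switch(plane,
                xy = mask[, , mid[3]],
                xz = mask[, mid[2], ],
                yz = mask[mid[1], , ])
  png::writePNG(t(sec * 1), path)
  invisible(path)
}
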