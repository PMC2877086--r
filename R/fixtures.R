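#' Digitized test shapes
#'
#' Deterministic rasterized shapes with known continuum volume, area,
#' sphericity and circularity, used to calibrate the morphometric estimators:
#' balls, cubes, (rotated) ellipsoids, two disjoint balls, and a U-shaped
#' tube whose mid-plane section is disconnected although the 3D object is
#' connected -- the geometric artifact that makes 2D sections of connected 3D
#' tumors look fragmented.
#'
#' @param kind one of `"ball"`, `"cube"`, `"ellipsoid"`, `"two_balls"`,
#'   `"u_tube"`, `"from_run"`.
#' @param L lattice side (voxels); the shape is centered.
#' @param r ball radius / tube radius (voxels).
#' @param a,b,c cube side / ellipsoid semi-axes (voxels).
#' @param rot optional 3x3 rotation matrix (ellipsoid).
#' @param separation center-to-center distance of the two balls.
#' @param sim a `cpm_sim` (for `kind = "from_run"`).
#' @return A 3D logical array (`L^3`).
#' @examples
#' sum(make_fixture("cube", a = 10, L = 32))  # exactly 1000
#' @export
make_fixture <- function(kind = c("ball", "cube", "ellipsoid", "two_balls",
                                  "u_tube", "from_run"),
                         L = 64, r = 12, a = 10, b = 8, c = 6, rot = NULL,
                         separation = NULL, sim = NULL) {
  kind <- match.arg(kind)
  ctr <- (L - 1) / 2
  gx <- array(rep(seq_len(L) - 1 - ctr, times = L * L), dim = c(L, L, L))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  switch(kind,
    ball = {
      if (2 * r + 2 > L) stop("ball does not fit the lattice")
      gx^2 + gy^2 + gz^2 <= r^2
    },
    cube = {
      if (a > L) stop("cube does not fit the lattice")
      rasterize_cube(gx, gy, gz, a)
    },
    ellipsoid = {
      if (is.null(rot)) rot <- diag(3)
      p <- rbind(as.vector(gx), as.vector(gy), as.vector(gz))
      q <- crossprod(rot, p)  # rotate coordinates into the ellipsoid frame
      ok <- (q[1, ] / a)^2 + (q[2, ] / b)^2 + (q[3, ] / c)^2 <= 1
      array(ok, dim = c(L, L, L))
    },
    two_balls = {
      if (is.null(separation)) separation <- 3 * r
      if (separation <= 2 * r) stop("two_balls must be disjoint")
      d <- separation / 2
      ((gx - d)^2 + gy^2 + gz^2 <= r^2) | ((gx + d)^2 + gy^2 + gz^2 <= r^2)
    },
    u_tube = {
      # two vertical arms joined by a bottom bar; the mid-height section
      # cuts only the arms: 3D-connected, 2D-disconnected
      arm_off <- max(2 * r + 2, floor(L / 4))
      zlow <- -floor(L / 4)
      arms <- ((gx - arm_off)^2 + gy^2 <= r^2 | (gx + arm_off)^2 + gy^2 <= r^2) &
        gz >= zlow
      bar <- abs(gx) <= arm_off & gy^2 + (gz - zlow)^2 <= r^2
      arms | bar
    },
    from_run = {
      stopifnot(inherits(sim, "cpm_sim"))
      tumor_mask(sim)
    })
}

# axis-aligned cube of side a (voxel count exactly a^3 for integer a)
rasterize_cube <- function(gx, gy, gz, a) {
  lo <- -a / 2 + 0.5 - 1e-9
  hi <- a / 2 - 0.5 + 1e-9
  gx >= lo & gx <= hi & gy >= lo & gy <= hi & gz >= lo & gz <= hi
}

#' Random 3D rotation matrix
#'
#' Uniform random rotation (QR of a Gaussian matrix, determinant corrected),
#' used to orient ellipsoid fixtures.
#'
#' @param seed integer seed.
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
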