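# Shared test utilities: small random multi-cell lattices and R-side
# brute-force oracles, independent of the C++ energy code paths.

# Random label lattice: n_cells tumor blobs grown by seeded accretion in a
# TM background (id 1). Returns list(sigma, types).
random_lattice <- function(L = 6, n_cells = 3, seed = 1) {
  set.seed(seed)
  sigma <- array(1L, dim = c(L, L, L))
  centers <- matrix(sample(seq_len(L), 3 * n_cells, replace = TRUE), ncol = 3)
  for (i in seq_len(n_cells)) {
    id <- i + 1L
    cur <- matrix(centers[i, ], ncol = 3)
    sigma[cur] <- id
    for (step in seq_len(8)) {
      pick <- cur[sample(nrow(cur), 1), ]
      dir <- diag(3)[sample(3, 1), ] * sample(c(-1L, 1L), 1)
      nxt <- pmin(pmax(pick + dir, 1L), L)
      sigma[matrix(nxt, ncol = 3)] <- id
      cur <- rbind(cur, nxt)
    }
  }
  list(sigma = sigma, types = c(0L, rep(1L, n_cells)))
}

# Brute-force contact energy: enumerate all unordered voxel pairs within the
# fourth-order range directly in R.
brute_contact_energy <- function(sigma, types, J_tt, J_ttm) {
  L <- dim(sigma)[1]
  off <- neighbor_offsets(4)
  E <- 0
  for (x in seq_len(L)) for (y in seq_len(L)) for (z in seq_len(L)) {
    a <- sigma[x, y, z]
    for (r in seq_len(nrow(off))) {
      nx <- x + off[r, 1]; ny <- y + off[r, 2]; nz <- z + off[r, 3]
      if (nx < 1 || nx > L || ny < 1 || ny > L || nz < 1 || nz > L) next
      b <- sigma[nx, ny, nz]
      if (a == b) next
      ta <- types[a]; tb <- types[b]
      E <- E + if (ta == 1 && tb == 1) J_tt else J_ttm
    }
  }
  E / 2  # every pair visited from both ends
}

# Config for tiny test lattices: fields inert unless a test enables them
quiet_config <- function(L, seed = 1, ...) {
  sim_config(L = L, seed = seed, D_c = 0, D_m = 0, delta = 0, mu = 0,
             S_prod = 0, k = 1e-9, g = 0, snapshot_interval = 100,
             max_mcs = 10000, ...)
}

# total heterotypic (tumor-TM) boundary faces = surface S of the TM cell
tm_boundary_area <- function(sim) {
  df <- sim_cells(sim)
  df$S[df$type == "TM"][1]
}
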