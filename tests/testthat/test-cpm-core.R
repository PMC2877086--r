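test_that("fourth-order neighborhood has 32 symmetric offsets in shells 6+12+8+6", {
  off <- neighbor_offsets(4)
  expect_equal(nrow(off), 32L)
  r2 <- rowSums(off^2)
  expect_equal(as.integer(table(r2)), c(6L, 12L, 8L, 6L))
  # symmetric under negation
  key <- apply(off, 1, paste, collapse = ",")
  neg <- apply(-off, 1, paste, collapse = ",")
  expect_setequal(key, neg)
  # first-order range: the 6 face neighbors
  expect_equal(nrow(neighbor_offsets(1)), 6L)
})

test_that("surface tension is J(t,TM) - J(t,t)/2", {
  expect_equal(surface_tension(8, 4), 6)
  expect_equal(surface_tension(8, 16), 0)
  # symmetry point: J_tt = 2 J_ttm gives zero tension for any J_ttm
  for (J in c(2, 8, 11.5)) expect_equal(surface_tension(J, 2 * J), 0)
})

test_that("initial state is a centered 2x2x2 block of 3x3x3 tumor cells in TM", {
  sim <- cpm_sim(quiet_config(L = 20))
  sig <- sim_sigma(sim)
  expect_equal(sum(sig >= 2), 8 * 27)        # 216 tumor voxels
  expect_equal(sum(sig == 1), 20^3 - 216)    # the rest is the single TM cell
  df <- sim_cells(sim)
  expect_equal(sum(df$type == "tumor"), 8L)
  expect_true(all(df$V[df$type == "tumor"] == 27L))
  expect_true(all(df$S[df$type == "tumor"] == 54L))
  expect_true(all(df$V_t[df$type == "tumor"] == 27))
  expect_true(sim_audit(sim))

  # smallest legal domain: seed occupies voxels 1..6 on each axis (0-based)
  sim8 <- cpm_sim(quiet_config(L = 8))
  sig8 <- sim_sigma(sim8)
  expect_true(all(sig8[2:7, 2:7, 2:7] >= 2))
  expect_true(all(sig8[1, , ] == 1) && all(sig8[8, , ] == 1))
  expect_error(cpm_sim(quiet_config(L = 7)), "too small")
  expect_error(quiet_config(L = 2))
})

test_that("contact energy matches brute-force pair enumeration and is linear in J", {
  for (seed in 1:3) {
    rl <- random_lattice(L = 6, n_cells = 3, seed = seed)
    cfg <- quiet_config(L = 6, J_tt = 16, J_ttm = 8)
    sim <- sim_from_sigma(rl$sigma, rl$types, cfg)
    expect_equal(contact_energy_total(sim),
                 brute_contact_energy(rl$sigma, rl$types, 16, 8))
    # doubling all J doubles the total
    sim2 <- sim_from_sigma(rl$sigma, rl$types, quiet_config(L = 6, J_tt = 32, J_ttm = 16))
    expect_equal(contact_energy_total(sim2), 2 * contact_energy_total(sim))
  }
  # single cell filling the lattice: no heterotypic pairs
  sig1 <- array(2L, dim = c(6, 6, 6))
  sim1 <- sim_from_sigma(sig1, c(0L, 1L), quiet_config(L = 6))
  expect_equal(contact_energy_total(sim1), 0)
})

test_that("volume and surface penalties enter the effective energy quadratically", {
  rl <- random_lattice(L = 6, n_cells = 1, seed = 4)
  cfg <- quiet_config(L = 6)  # lambda_V = 20, lambda_S = 0.4
  sim <- sim_from_sigma(rl$sigma, rl$types, cfg)
  base <- effective_energy(sim)  # targets equal current values: contact only
  expect_equal(base, contact_energy_total(sim))
  df <- sim_cells(sim)
  tumor <- df[df$type == "tumor", ]
  # V - V_t = 1 at lambda_V = 20 adds exactly 20
  set_cell(sim, tumor$id, V_t = tumor$V - 1)
  expect_equal(effective_energy(sim), base + 20)
  # S - S_t = 2 at lambda_S = 0.4 adds another 0.4 * 4 = 1.6
  set_cell(sim, tumor$id, S_t = tumor$S - 2)
  expect_equal(effective_energy(sim), base + 20 + 1.6)
  # the TM cell is unconstrained: distorting its targets changes nothing
  tm <- df[df$type == "TM", ]
  set_cell(sim, tm$id, V_t = 1, S_t = 1)
  expect_equal(effective_energy(sim), base + 20 + 1.6)
})

test_that("local delta-H equals the global energy difference (oracle)", {
  n_checked <- 0
  for (seed in 1:3) {
    L <- if (seed %% 2) 6L else 8L
    rl <- random_lattice(L = L, n_cells = 4, seed = seed)
    cfg <- quiet_config(L = L, J_tt = 16, J_ttm = 8)
    sim <- sim_from_sigma(rl$sigma, rl$types, cfg)
    # give cells non-trivial targets so all three energy terms are active
    for (id in which(rl$types == 1)) {  # types are indexed by id
      set_cell(sim, id, V_t = 27, S_t = 54)
    }
    set.seed(seed + 100)
    for (i in 1:150) {
      x <- sample.int(L, 3, replace = TRUE) - 1L
      cur <- sim_sigma(sim)[x[1] + 1, x[2] + 1, x[3] + 1]
      cand <- sample(setdiff(seq_len(max(rl$sigma)), cur), 1)
      dH <- delta_H(sim, x, cand)
      before <- effective_energy(sim)
      apply_copy(sim, x, cand)
      after <- effective_energy(sim)
      expect_lt(abs(dH - (after - before)), 1e-9)
      # reversibility: undoing the copy gives exactly -dH
      dH_back <- delta_H(sim, x, cur)
      expect_lt(abs(dH_back + dH), 1e-9)
      apply_copy(sim, x, cur)
      n_checked <- n_checked + 1
    }
    expect_true(sim_audit(sim))
  }
  expect_gte(n_checked, 450)
})

test_that("Metropolis acceptance follows min(1, exp(-dH/T_m))", {
  # dH = T_m = 60: acceptance probability exactly exp(-1)
  n <- 1e5
  acc <- tumorcpm:::cpp_accept_count(60, 60, n, seed = 7)
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(acc / n - p), 3 * se)
  # dH <= 0 always accepted; infinite barrier never
  expect_equal(tumorcpm:::cpp_accept_count(0, 60, 1000, 1), 1000L)
  expect_equal(tumorcpm:::cpp_accept_count(-5, 60, 1000, 1), 1000L)
  expect_equal(tumorcpm:::cpp_accept_count(Inf, 60, 1000, 1), 0L)
})

test_that("volume ledger is conserved and trajectories are seed-deterministic", {
  cfg <- quiet_config(L = 16, seed = 11)
  sim <- cpm_sim(cfg)
  run_mcs(sim, 0)
  expect_equal(sim_mcs(sim), 0L)          # n_mcs = 0 leaves state untouched
  run_mcs(sim, 10)
  expect_true(sim_audit(sim))
  df <- sim_cells(sim)
  expect_equal(sum(df$V), 16L^3)          # exact integer conservation
  # same seed: bit-identical sigma; different seed: different trajectory
  sim_b <- cpm_sim(cfg)
  run_mcs(sim_b, 10)
  expect_identical(sim_sigma(sim), sim_sigma(sim_b))
  sim_c <- cpm_sim(quiet_config(L = 16, seed = 12))
  run_mcs(sim_c, 10)
  expect_false(identical(sim_sigma(sim), sim_sigma(sim_c)))
})

test_that("positive surface tension makes fragmented tumor cells round up", {
  # two tumor cells, each seeded as two disjoint 2x2x2 blocks in TM;
  # with gamma = 6 the tumor-TM boundary area should shrink in trend
  drops <- vapply(1:5, function(seed) {
    L <- 14L
    sigma <- array(1L, dim = c(L, L, L))
    blocks <- list(c(3, 3, 3), c(9, 9, 9), c(3, 9, 6), c(9, 3, 6))
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      id <- if (i <= 2) 2L else 3L
      sigma[b[1]:(b[1]+1), b[2]:(b[2]+1), b[3]:(b[3]+1)] <- id
    }
    cfg <- quiet_config(L = L, seed = seed, J_tt = 4, J_ttm = 8)  # gamma 6
    sim <- sim_from_sigma(sigma, c(0L, 1L, 1L), cfg)
    for (id in 2:3) set_cell(sim, id, V_t = 16, S_t = update_target_surface(16))
    a0 <- tm_boundary_area(sim)
    run_mcs(sim, 1000)
    a0 - tm_boundary_area(sim)
  }, numeric(1))
  expect_gt(mean(drops), 0)
  expect_true(mean(drops > 0) >= 0.8)  # at least 4 of 5 seeds shrink
})

test_that("energy depends on types only, not on id labels", {
  rl <- random_lattice(L = 6, n_cells = 3, seed = 9)
  cfg <- quiet_config(L = 6, J_tt = 16, J_ttm = 8)
  sim <- sim_from_sigma(rl$sigma, rl$types, cfg)
  # permute the tumor ids (2,3,4) -> (4,2,3)
  perm <- c(1L, 4L, 2L, 3L)
  sig2 <- array(perm[rl$sigma], dim = dim(rl$sigma))
  sim2 <- sim_from_sigma(sig2, rl$types, cfg)
  expect_equal(contact_energy_total(sim2), contact_energy_total(sim))
})
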