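test_that("G <-> k mapping reproduces the study correspondence and round-trips", {
  expect_equal(G_from_k(0.05, L = 100, D_c = 10), 50)
  expect_equal(G_from_k(0.2, L = 100, D_c = 10), 200)
  expect_equal(k_from_G(50, L = 100, D_c = 10), 0.05)
  for (k in c(0.01, 0.05, 0.44))
    expect_equal(k_from_G(G_from_k(k, L = 72, D_c = 3), L = 72, D_c = 3), k)
  # the mapping constant rescales G linearly
  expect_equal(G_from_k(0.05, 100, 10, mapping_constant = 2), 100)
  # a config accepts exactly one of k and G and derives the other
  cfg <- sim_config(L = 100, G = 200)
  expect_equal(cfg$k, 0.2)
  expect_error(sim_config(k = 0.1, G = 100), "either")
})

test_that("target surface scales as the 2/3 power anchored at the initial cube", {
  expect_equal(update_target_surface(27), 54)
  expect_equal(update_target_surface(54), 6 * 54^(2 / 3))
  # 2/3-power homogeneity: volume x8 -> surface x4
  for (v in c(10, 27, 100)) {
    expect_equal(update_target_surface(8 * v), 4 * update_target_surface(v))
  }
  # necrotic shrink-out
  expect_equal(update_target_surface(0), 0)
  expect_equal(update_target_surface(-3), 0)
})

test_that("target volume grows by g * c(COM) per MCS, by state", {
  L <- 9
  sigma <- array(1L, dim = c(L, L, L)); sigma[5, 5, 5] <- 2L
  cfg <- sim_config(L = L, seed = 1, D_c = 0, D_m = 0, delta = 0, mu = 0,
                    S_prod = 0, k = 1e-12, g = 0.3, g_necrotic = -0.1)
  mk <- function(cval, state = "proliferating") {
    sim <- sim_from_sigma(sigma, c(0L, 1L), cfg)
    set_cell(sim, 2, V_t = 27, S_t = 54, state = state)
    sim_set_field(sim, "c", array(cval, dim = c(L, L, L)))
    sim
  }
  # c = 1: V_t increases by exactly n * g (no division below V_doubling)
  sim <- mk(1)
  for (n in 1:5) biology_step(sim, grow = TRUE, divide = FALSE, phenotype = FALSE)
  expect_equal(sim_cells(sim)$V_t[2], 27 + 5 * 0.3, tolerance = 1e-6)
  expect_equal(sim_cells(sim)$S_t[2], update_target_surface(27 + 1.5), tolerance = 1e-6)
  # c = 0: no growth (the model's implicit quiescence)
  sim0 <- mk(0)
  biology_step(sim0, grow = TRUE, divide = FALSE, phenotype = FALSE)
  expect_equal(sim_cells(sim0)$V_t[2], 27)
  # quiescent cells do not grow even at c = 1
  simq <- mk(1, "quiescent")
  biology_step(simq, grow = TRUE, divide = FALSE, phenotype = FALSE)
  expect_equal(sim_cells(simq)$V_t[2], 27)
  # necrotic cells shrink at g_necrotic, with V_t floored at 0
  simn <- mk(1, "necrotic")
  for (i in 1:5) biology_step(simn, grow = TRUE, divide = FALSE, phenotype = FALSE)
  expect_equal(sim_cells(simn)$V_t[2], 27 - 0.5, tolerance = 1e-6)
  for (i in 1:500) biology_step(simn, grow = TRUE, divide = FALSE, phenotype = FALSE)
  expect_equal(sim_cells(simn)$V_t[2], 0)
})

test_that("mitosis splits along the requested plane and conserves volume", {
  L <- 12
  sigma <- array(1L, dim = c(L, L, L))
  sigma[5:7, 5:7, 4:9] <- 2L  # 3 x 3 x 6 box, 54 voxels
  cfg <- quiet_config(L = L)
  sim <- sim_from_sigma(sigma, c(0L, 1L), cfg)
  set_cell(sim, 2, V_t = 54, S_t = update_target_surface(54))
  new_id <- divide_cell(sim, 2, axis = c(0, 0, 1))  # plane normal = long axis
  expect_equal(new_id, 3L)
  df <- sim_cells(sim)
  expect_equal(df$V[df$id %in% c(2, 3)], c(27L, 27L))
  expect_equal(df$V_t[df$id %in% c(2, 3)], c(27, 27))       # half the parent's V_t
  expect_equal(df$S_t[df$id %in% c(2, 3)], c(54, 54))
  expect_equal(df$S[df$id %in% c(2, 3)], c(54L, 54L))       # two 3x3x3 cubes
  expect_true(sim_audit(sim))

  # random-axis division of irregular blobs conserves volume exactly
  for (seed in 1:5) {
    rl <- random_lattice(L = 8, n_cells = 1, seed = seed + 20)
    s2 <- sim_from_sigma(rl$sigma, rl$types, quiet_config(L = 8, seed = seed))
    v_parent <- sim_cells(s2)$V[2]
    nid <- divide_cell(s2, 2)
    df2 <- sim_cells(s2)
    expect_equal(df2$V[2] + df2$V[nid], v_parent)
    expect_true(all(df2$V[c(2, nid)] > 0))
    expect_true(sim_audit(s2))
  }
})

test_that("random division planes through the COM halve the volume on average", {
  # Monte-Carlo property of the plane chooser on assorted blobs
  fracs <- c()
  for (seed in 1:4) {
    mask <- make_fixture(if (seed %% 2) "ball" else "ellipsoid",
                         r = 7, a = 8, b = 6, c = 5, L = 20)
    fr <- tumorcpm:::cpp_random_split_fractions(
      array(as.integer(mask), dim(mask)), n = 300, seed = seed)
    fracs <- c(fracs, fr)
  }
  expect_gte(length(fracs), 1000)
  expect_lt(abs(mean(fracs) - 0.5), 0.02)
})

test_that("quiescence is reversible, necrosis is not, and both are threshold-driven", {
  L <- 9
  sigma <- array(1L, dim = c(L, L, L)); sigma[5, 5, 5] <- 2L
  base <- list(L = L, seed = 1, D_c = 0, D_m = 0, delta = 0, mu = 0,
               S_prod = 0, k = 1e-12, g = 0, c_threshold = 0.05)
  # quiescence: below threshold -> quiescent; recovery -> proliferating again
  cfgq <- do.call(sim_config, c(base, quiescence_enabled = TRUE))
  simq <- sim_from_sigma(sigma, c(0L, 1L), cfgq)
  sim_set_field(simq, "c", array(0.01, dim = c(L, L, L)))
  biology_step(simq, grow = FALSE, divide = FALSE, phenotype = TRUE)
  expect_equal(sim_cells(simq)$state[2], "quiescent")
  sim_set_field(simq, "c", array(0.5, dim = c(L, L, L)))
  biology_step(simq, grow = FALSE, divide = FALSE, phenotype = TRUE)
  expect_equal(sim_cells(simq)$state[2], "proliferating")
  # at or above threshold nothing changes
  biology_step(simq, grow = FALSE, divide = FALSE, phenotype = TRUE)
  expect_equal(sim_cells(simq)$state[2], "proliferating")
  # necrosis: irreversible even if substrate recovers
  cfgn <- do.call(sim_config, c(base, necrosis_enabled = TRUE))
  simn <- sim_from_sigma(sigma, c(0L, 1L), cfgn)
  sim_set_field(simn, "c", array(0.01, dim = c(L, L, L)))
  biology_step(simn, grow = FALSE, divide = FALSE, phenotype = TRUE)
  expect_equal(sim_cells(simn)$state[2], "necrotic")
  sim_set_field(simn, "c", array(1, dim = c(L, L, L)))
  biology_step(simn, grow = FALSE, divide = FALSE, phenotype = TRUE)
  expect_equal(sim_cells(simn)$state[2], "necrotic")
  # enabling both rules at once is a configuration error
  expect_error(do.call(sim_config, c(base, quiescence_enabled = TRUE,
                                     necrosis_enabled = TRUE)), "separately")
})

test_that("phenotype counts partition the tumor-cell census", {
  cfg <- sim_config(L = 20, seed = 3, G = 50, g = 0.3, quiescence_enabled = TRUE,
                    c_threshold = 0.3, snapshot_interval = 50)
  sim <- cpm_sim(cfg)
  run_mcs(sim, 60)
  n <- sim_cell_counts(sim)
  expect_equal(n[["total"]],
               n[["proliferating"]] + n[["quiescent"]] + n[["necrotic"]])
  expect_true(sim_audit(sim))
})

test_that("at saturating substrate the population doubles at a stable cadence", {
  # k ~ 0 keeps c = 1 everywhere: V_t grows at g per MCS, cells divide at 54
  mcs_to_32 <- vapply(1:3, function(seed) {
    cfg <- sim_config(L = 24, seed = seed, D_c = 0, D_m = 0, delta = 0,
                      mu = 0, S_prod = 0, k = 1e-12, g = 0.3, gamma = 6,
                      snapshot_interval = 30, max_mcs = 2000)
    sim <- cpm_sim(cfg)
    n <- 0
    while (sim_cell_counts(sim)[["total"]] < 32 && n < 2000) {
      run_mcs(sim, 10); n <- n + 10
    }
    n
  }, numeric(1))
  expect_true(all(mcs_to_32 < 2000))
  # 8 -> 32 cells is two doublings; spread across seeds within 10% of the mean
  expect_lt(max(abs(mcs_to_32 - mean(mcs_to_32))) / mean(mcs_to_32), 0.10)
})

test_that("cohesive tumors stay 26-connected at every snapshot", {
  # gamma = 6: the tumor should remain one 26-connected body as it grows
  cfg <- sim_config(L = 30, seed = 8, k = 0.05, gamma = 6, g = 0.3,
                    snapshot_interval = 100, max_mcs = 1000)
  sim <- cpm_sim(cfg)
  for (i in 1:6) {
    run_mcs(sim, 100)
    expect_equal(connected_components(tumor_mask(sim))$n, 1L)
  }
})
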