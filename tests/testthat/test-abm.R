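test_that("init_world places the configured agents in an empty world", {
  cfg <- tiny_config()
  set.seed(42)
  w <- init_world(cfg)
  expect_equal(length(w$energy), init_total(cfg))
  expect_equal(sum(w$species == 0), cfg$init_yeast)
  expect_equal(sum(w$species == 1 & w$strain == 0), cfg$init_wt_bacteria)
  expect_equal(sum(w$strain == 1), cfg$init_mutant_bacteria)
  expect_true(all(w$energy == cfg$energy_init))
  expect_true(all(w$amino_acid == 0) && all(w$vitamin == 0))
  expect_true(all(w$row >= 0 & w$row < cfg$grid_height))
  expect_true(all(w$col >= 0 & w$col < cfg$grid_width))
  expect_equal(w$tick, 0L)
})

test_that("init_world is deterministic under a fixed seed and honours zero counts", {
  cfg <- tiny_config(rng_seed = 7L)
  expect_identical(init_world(cfg), init_world(cfg))
  w0 <- init_world(tiny_config(init_mutant_bacteria = 0L, rng_seed = 1L))
  expect_equal(sum(w0$strain == 1), 0)
})

test_that("invalid configurations are rejected by name", {
  expect_error(tiny_config(mixing = 1.5), "mixing")
  expect_error(tiny_config(diffusion_rate = -0.1), "diffusion_rate")
  expect_error(tiny_config(division_threshold = 5, energy_init = 10),
               "division_threshold")
  expect_error(tiny_config(init_yeast = -1), "init_yeast")
  expect_warning(tiny_config(bact_conversion_efficiency = 3), "calibration")
})

test_that("diffuse spreads over the 8-neighbour torus and conserves mass", {
  g <- matrix(0, 3, 3); g[2, 2] <- 8
  out <- diffuse(g, 0.5)
  expect_equal(out[2, 2], 4)
  expect_equal(unname(out[-5]), rep(0.5, 8))
  # identity at rate 0
  expect_equal(diffuse(g, 0), g)
  # conservation for random grids and rates
  set.seed(11)
  for (i in 1:20) {
    h <- matrix(runif(32 * 32, 0, 5), 32, 32)
    rate <- runif(1)
    out <- diffuse(h, rate)
    expect_equal(sum(out), sum(h), tolerance = 1e-9)
    expect_true(all(out >= 0))
  }
  expect_error(diffuse(g, 1.2), "rate")
})

test_that("diffusion wraps across the torus edges", {
  g <- matrix(0, 4, 4); g[1, 1] <- 16
  out <- diffuse(g, 1)   # everything leaves the focal patch
  expect_equal(out[1, 1], 0)
  expect_equal(out[4, 4], 2)  # wrapped diagonal neighbour
  expect_equal(sum(out), 16, tolerance = 1e-12)
})

test_that("a wild bacterium on a saturated patch nets exactly one energy unit", {
  cfg <- tiny_config(mixing = 0, wander_prob = 0)
  w <- init_world(tiny_config(init_yeast = 0L, init_wt_bacteria = 1L,
                              init_mutant_bacteria = 0L, rng_seed = 3L,
                              mixing = 0, wander_prob = 0))
  w$amino_acid[] <- 10  # uniform, so diffusion cannot drain the focal patch
  e0 <- w$energy[1]
  w1 <- abm_tick(w, cfg)
  expect_equal(w1$energy[1] - e0, 1, tolerance = 1e-12)
})

test_that("an agent that cannot pay its secretion cost dies of it", {
  cfg <- tiny_config(mixing = 0, wander_prob = 0)
  w <- init_world(tiny_config(init_yeast = 1L, init_wt_bacteria = 0L,
                              init_mutant_bacteria = 0L, rng_seed = 5L,
                              mixing = 0, wander_prob = 0))
  w$energy[1] <- cfg$yeast_secretion_cost * cfg$yeast_secretion_rate / 2
  w1 <- abm_tick(w, cfg)    # no vitamin anywhere: secretion drives energy <= 0
  expect_equal(length(w1$energy), 0)
})

test_that("division splits the parent's energy between two daughters", {
  cfg <- tiny_config(mixing = 0, wander_prob = 0)
  w <- init_world(tiny_config(init_yeast = 1L, init_wt_bacteria = 0L,
                              init_mutant_bacteria = 0L, rng_seed = 5L,
                              mixing = 0, wander_prob = 0))
  # energy after the unavoidable secretion cost lands exactly on the threshold
  w$energy[1] <- cfg$division_threshold +
    cfg$yeast_secretion_cost * cfg$yeast_secretion_rate
  w1 <- abm_tick(w, cfg)
  expect_equal(length(w1$energy), 2)
  expect_equal(w1$energy, rep(cfg$division_threshold / 2, 2))
  expect_equal(w1$row[1], w1$row[2])
  expect_equal(w1$col[1], w1$col[2])
})

test_that("a lone saturated bacterium divides at the closed-form tick count", {
  cfg <- tiny_config(mixing = 0, wander_prob = 0)
  w <- init_world(tiny_config(init_yeast = 0L, init_wt_bacteria = 1L,
                              init_mutant_bacteria = 0L, rng_seed = 9L,
                              mixing = 0, wander_prob = 0))
  net <- cfg$bact_conversion_efficiency * cfg$bact_uptake_max -
    cfg$bact_secretion_cost * cfg$bact_secretion_rate
  expected_ticks <- ceiling((cfg$division_threshold - cfg$energy_init) / net)
  for (i in seq_len(expected_ticks - 1)) {
    w$amino_acid[] <- 10
    w <- abm_tick(w, cfg)
    expect_equal(length(w$energy), 1)
  }
  w$amino_acid[] <- 10
  w <- abm_tick(w, cfg)
  expect_equal(length(w$energy), 2)
})

test_that("per-tick metabolite change equals secretion minus consumption", {
  cfg <- tiny_config(mixing = 0.3, division_threshold = 1e6,
                     energy_init = 1e3)
  set.seed(21)
  for (rep in 1:5) {
    w <- init_world(cfg)
    w$amino_acid[] <- runif(64, 0, 2)
    w$vitamin[] <- runif(64, 0, 2)
    before_aa <- sum(w$amino_acid); before_vit <- sum(w$vitamin)
    e_before <- w$energy
    w1 <- abm_tick(w, cfg)
    # no deaths or divisions at these energies, so agents map 1:1
    expect_equal(length(w1$energy), length(w$energy))
    d_e <- w1$energy - e_before
    yeast <- w1$species == 0
    mut <- w1$strain == 1
    sec_b <- cfg$bact_secretion_rate *
      ifelse(mut[!yeast], cfg$mutant_secretion_fold, 1)
    consumed_vit <- (d_e[yeast] + cfg$yeast_secretion_cost * cfg$yeast_secretion_rate) /
      cfg$yeast_conversion_efficiency
    consumed_aa <- (d_e[!yeast] + cfg$bact_secretion_cost * sec_b) /
      cfg$bact_conversion_efficiency
    secreted_aa <- sum(yeast) * cfg$yeast_secretion_rate
    secreted_vit <- sum(sec_b)
    expect_equal(sum(w1$amino_acid) - before_aa,
                 secreted_aa - sum(consumed_aa), tolerance = 1e-9)
    expect_equal(sum(w1$vitamin) - before_vit,
                 secreted_vit - sum(consumed_vit), tolerance = 1e-9)
  }
})

test_that("obligate mutualism: either species alone goes extinct quickly", {
  # bacteria without yeast have no amino-acid source; the secretion cost
  # drains energy_init in energy_init/(cost*rate) ticks
  cfg_b <- tiny_config(init_yeast = 0L, init_wt_bacteria = 20L,
                       init_mutant_bacteria = 0L, rng_seed = 2L)
  bound_b <- ceiling(cfg_b$energy_init /
    (cfg_b$bact_secretion_cost * cfg_b$bact_secretion_rate)) + 1
  r <- run_transfer_cycle(init_world(cfg_b), cfg_b)
  expect_equal(r$outcome, "extinct")
  expect_lte(nrow(r$records), bound_b)

  cfg_y <- tiny_config(init_yeast = 20L, init_wt_bacteria = 0L,
                       init_mutant_bacteria = 0L, rng_seed = 2L)
  bound_y <- ceiling(cfg_y$energy_init /
    (cfg_y$yeast_secretion_cost * cfg_y$yeast_secretion_rate)) + 1
  r <- run_transfer_cycle(init_world(cfg_y), cfg_y)
  expect_equal(r$outcome, "extinct")
  expect_lte(nrow(r$records), bound_y)
})

test_that("run_transfer_cycle stops at the doubling threshold or reports why not", {
  cfg <- tiny_config(rng_seed = 31L)
  expect_equal(transfer_threshold(cfg), init_total(cfg) * 2^cfg$doublings_per_transfer)
  # the default community does five doublings: a 32-fold census expansion
  full <- sim_config()
  expect_equal(transfer_threshold(full), init_total(full) * 32)

  w <- init_world(cfg)
  r <- run_transfer_cycle(w, cfg)
  expect_true(r$outcome %in% c("reached_threshold", "extinct", "timed_out"))
  if (r$outcome == "reached_threshold")
    expect_gte(length(r$world$energy), transfer_threshold(cfg))
  # empty world: immediately extinct
  w0 <- init_world(tiny_config(init_yeast = 0L, init_wt_bacteria = 0L,
                               init_mutant_bacteria = 0L, rng_seed = 1L))
  r0 <- run_transfer_cycle(w0, cfg)
  expect_equal(r0$outcome, "extinct")
  expect_equal(nrow(r0$records), 0)
})

test_that("transfer cycles are deterministic under a fixed seed", {
  cfg <- tiny_config()
  set.seed(123); r1 <- run_transfer_cycle(init_world(cfg), cfg)
  set.seed(123); r2 <- run_transfer_cycle(init_world(cfg), cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$world, r2$world)
})

test_that("apply_transfer dilutes to the inoculum size into a fresh world", {
  cfg <- tiny_config(rng_seed = 17L)
  w <- init_world(cfg)
  r <- run_transfer_cycle(w, cfg)
  if (r$outcome == "reached_threshold") {
    w2 <- apply_transfer(r$world, cfg)
    expect_equal(length(w2$energy), init_total(cfg))
    expect_true(all(w2$amino_acid == 0) && all(w2$vitamin == 0))
    expect_equal(w2$tick, 0L)
    # energies preserved: transferred energies are a sub-multiset
    expect_true(all(w2$energy %in% r$world$energy))
  }
  # fewer agents than the inoculum: all retained
  small <- init_world(tiny_config(init_yeast = 2L, init_wt_bacteria = 3L,
                                  init_mutant_bacteria = 0L, rng_seed = 4L))
  w3 <- apply_transfer(small, cfg)
  expect_equal(length(w3$energy), 5)
  # empty world is an error
  empty <- init_world(tiny_config(init_yeast = 0L, init_wt_bacteria = 0L,
                                  init_mutant_bacteria = 0L, rng_seed = 4L))
  expect_error(apply_transfer(empty, cfg), "empty")
})

test_that("transfer sampling is label-blind (binomial oracle)", {
  # a 50/50 mutant/wild world sampled down many times: the mean post-transfer
  # mutant fraction matches the pre-transfer fraction within binomial error
  cfg <- tiny_config(init_yeast = 0L, init_wt_bacteria = 45L,
                     init_mutant_bacteria = 45L)
  set.seed(99)
  w <- init_world(cfg)
  big <- w
  idx <- rep(seq_along(w$energy), each = 8)   # blow up to 720 agents
  for (f in c("species", "strain", "energy", "row", "col")) big[[f]] <- w[[f]][idx]
  fracs <- replicate(200, {
    w2 <- apply_transfer(big, cfg)
    mean(w2$strain == 1)
  })
  se <- sqrt(0.25 / length(big$energy) + 0.25 / 90) / sqrt(200)
  expect_lt(abs(mean(fracs) - 0.5), 4 * se + 0.01)
})

test_that("population records have the exported CSV layout", {
  cfg <- tiny_config(rng_seed = 13L)
  r <- run_transfer_cycle(init_world(cfg), cfg)
  expect_named(r$records, c("transfer", "tick", "n_yeast", "n_wt", "n_mutant",
                            "total_aa", "total_vit"))
  f <- tempfile(fileext = ".csv")
  write_population_csv(r$records, f)
  back <- read.csv(f)
  expect_equal(back, r$records, tolerance = 1e-12)
  expect_equal(readLines(f, n = 1),
               "transfer,tick,n_yeast,n_wt,n_mutant,total_aa,total_vit")
})
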