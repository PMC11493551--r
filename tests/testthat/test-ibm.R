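test_that("introductions add exactly n adults at the entry cell with the stated sex ratio and sizes", {
  land <- tiny_packed()
  ep <- land$entry_points[["site1"]]
  p <- ibm_params()
  state <- new_sim_state()
  set.seed(1)
  state <- introduce(state, 10, ep, land, p)
  expect_identical(estabsim:::n_toads(state), 10L)
  expect_true(all(state$toads$cell == ep))
  expect_true(all(state$toads$stage == 3L))

  set.seed(2)
  big <- introduce(new_sim_state(), 10000, ep, land, p)
  male_frac <- mean(big$toads$sex == 1L)
  expect_lt(abs(male_frac - 0.5), 3 * sqrt(0.25 / 10000))
  svl <- big$toads$svl
  expect_true(all(svl >= 70 & svl <= 110))
  # truncation is symmetric about 90, so the truncated mean is still 90
  expect_lt(abs(mean(svl) - 90), 3 * sd(svl) / sqrt(10000))
})

test_that("introduction on a water cell is rejected", {
  land <- tiny_packed()
  wc <- which(land$is_water)[1]
  expect_error(introduce(new_sim_state(), 5, wc, land), "ocean/water")
})

test_that("hydric state is a monotone step function of water loss", {
  p <- ibm_params()
  loss <- seq(0, 1, by = 0.01)
  st <- hydric_state(loss, p)
  lev <- c(hydrated = 0, dehydrated = 1, extremely_dehydrated = 2, desiccated = 3)
  expect_true(all(diff(lev[st]) >= 0))
  expect_identical(unname(st[loss == 0]), "hydrated")
  expect_identical(unname(st[which(loss >= 0.10)[1]]), "dehydrated")
  expect_identical(unname(st[which(loss >= 0.40)[1]]), "desiccated")
})

test_that("behavioural rules honour stage, season, sex and hydration", {
  p <- ibm_params()
  # juveniles never breed, even in the wet season
  expect_false(any(decide_behaviour(rep(2L, 50), rep(1L, 50), rep(FALSE, 50),
                                    rep(0, 50), "wet", TRUE, p) == "breeding"))
  # an adult female that has spawned is excluded until the season resets
  expect_identical(decide_behaviour(3L, 2L, TRUE, 0, "wet", TRUE, p), "foraging")
  expect_identical(decide_behaviour(3L, 2L, FALSE, 0, "wet", TRUE, p), "breeding")
  # dehydration dominates everything, including inactivity draws
  expect_identical(decide_behaviour(3L, 1L, FALSE, 0.15, "dry", FALSE, p), "rehydrating")
  expect_identical(decide_behaviour(3L, 1L, FALSE, 0.15, "wet", TRUE, p), "rehydrating")
  # active, hydrated, non-breeding toads forage
  expect_identical(decide_behaviour(1L, 1L, FALSE, 0, "dry", TRUE, p), "foraging")
  expect_identical(decide_behaviour(1L, 1L, FALSE, 0, "dry", FALSE, p), "inactive")
})

test_that("daily displacements never exceed the 1000 m ceiling", {
  land <- tiny_packed()
  p <- ibm_params(move_scale_wet_m = 5000) # push the kernel against the cap
  n <- 10000
  interior <- cell_index(land$grid, rep(60L, n), rep(69L, n))
  toads <- list(cell = interior, heading = runif(n, -pi, pi),
                activity = rep("foraging", n))
  set.seed(4)
  mv <- disperse_toads(toads, land, "wet", FALSE, p)
  d <- cell_distance(land$grid, toads$cell, mv$cell)
  expect_true(all(d <= 1000))
  expect_gt(max(d), 500) # the cap is actually being exercised
})

test_that("a zero-scale kernel leaves every toad in place", {
  land <- tiny_packed()
  p <- ibm_params(move_scale_wet_m = 0, move_scale_dry_m = 0)
  toads <- list(cell = rep(land$entry_points[["site1"]], 20),
                heading = rep(0, 20), activity = rep("foraging", 20))
  set.seed(5)
  mv <- disperse_toads(toads, land, "wet", FALSE, p)
  expect_identical(mv$cell, toads$cell)
})

test_that("rehydrating toads close in on water (BFS-distance oracle)", {
  land <- tiny_packed()
  targets <- which(land$is_rehydration)
  dist0 <- bfs_dist_oracle(land$grid, targets)
  # start well away from the cluster
  cells <- cell_index(land$grid, rep(5:14, 10), rep(5:14, each = 10))
  cells <- cells[dist0[cells] > 10]
  toads <- list(cell = cells, heading = rep(0, length(cells)),
                activity = rep("rehydrating", length(cells)))
  set.seed(6)
  mv <- disperse_toads(toads, land, "dry", FALSE, ibm_params())
  expect_lt(mean(dist0[mv$cell]), mean(dist0[toads$cell]))
})

test_that("clutch size maps SVL linearly onto the fecundity range", {
  p <- ibm_params()
  expect_identical(estabsim:::clutch_size_from_svl(70, p), 7675L)
  expect_identical(estabsim:::clutch_size_from_svl(110, p), 14288L)
  mid <- estabsim:::clutch_size_from_svl(90, p)
  expect_identical(mid, as.integer(round((7675 + 14288) / 2)))
  sizes <- estabsim:::clutch_size_from_svl(seq(50, 130, by = 5), p)
  expect_true(all(sizes >= 7675L & sizes <= 14288L))
})

test_that("spawning avoids tadpole-occupied ponds and fails without perceptible water", {
  land <- tiny_packed()
  wc <- which(land$is_breeding)
  ep <- land$entry_points[["site1"]]
  d <- cell_distance(land$grid, rep(ep, length(wc)), wc)
  near <- wc[d <= 300]
  expect_gt(length(near), 1)
  counts <- stats::setNames(rep(0, length(near)), near)
  counts[1] <- 500
  pick <- spawn_clutch(90, ep, land, counts, ibm_params())
  expect_false(pick$cell == near[1])
  # no water within perception: a cell in the far corner
  far <- cell_index(land$grid, 2L, 2L)
  expect_null(spawn_clutch(90, far, land, numeric(), ibm_params()))
})

test_that("mortality follows the binomial law and tadpoles suppress co-located eggs", {
  p <- ibm_params(mort_adult = 0.3)
  land <- tiny_packed()
  ep <- land$entry_points[["site1"]]
  set.seed(7)
  state <- introduce(new_sim_state(), 10000, ep, land, p)
  state <- apply_mortality(state, p)
  dead <- attr(state, "deaths")[["adult"]]
  expect_lt(abs(dead - 10000 * 0.3), 3 * sqrt(10000 * 0.3 * 0.7))

  # same seed schedule, with vs without resident tadpoles
  wc <- which(tiny_packed()$is_water)[1]
  base <- add_clutch(new_sim_state(), wc, 5000, age = 1L)
  with_tad <- add_clutch(base, wc, 3000, age = 10L, stage = 2L)
  set.seed(8); a <- apply_mortality(base, ibm_params())
  set.seed(8); b <- apply_mortality(with_tad, ibm_params())
  surv_alone <- a$clutches$n[1] / 5000
  surv_with <- b$clutches$n[b$clutches$age == 1L] / 5000
  if (length(surv_with) == 0) surv_with <- 0
  expect_lt(surv_with, surv_alone)
})

test_that("mortality of one everywhere empties the population in a single day", {
  p <- ibm_params(mort_egg = 1, mort_tadpole = 1, mort_metamorph = 1,
                  mort_juvenile = 1, mort_adult = 1)
  land <- tiny_packed()
  state <- introduce(new_sim_state(), 50, land$entry_points[["site1"]], land, p)
  state <- add_clutch(state, which(land$is_water)[1], 1000)
  state <- apply_mortality(state, p)
  expect_identical(estabsim:::n_toads(state), 0L)
  expect_length(state$clutches$n, 0)
})

test_that("clutches hatch at 3 days and desiccated toads are removed", {
  land <- tiny_packed()
  rain <- tiny_rain()
  p <- frozen_params()
  state <- add_clutch(new_sim_state(day = 150L), which(land$is_water)[1], 100,
                      age = 3L)
  state <- sim_step(state, land, rain, p)
  expect_true(all(state$clutches$stage == 2L))

  # a toad pushed past the desiccation threshold dies that day
  p2 <- frozen_params(daily_water_loss_frac = 0.45, inactive_loss_mult = 1)
  dry_day <- 170L # mid-dry season; ensure no rain that day
  rain$rain_mm[dry_day] <- 0
  far <- cell_index(land$grid, 3L, 3L)
  st <- new_sim_state(day = dry_day)
  set.seed(9)
  st <- introduce(st, 5, far, land, p2)
  st <- sim_step(st, land, rain, p2)
  expect_identical(estabsim:::n_toads(st), 0L)
})

test_that("a frozen population is a fixed point of the daily step", {
  land <- tiny_packed()
  rain <- generate_rainfall(400, seed = 3, p_rain_wet = 0, p_rain_dry = 0)
  p <- frozen_params(p_active_wet = 0, p_active_dry = 0, growth_cv = 0,
                     growth_mm_day = 0)
  set.seed(10)
  state <- introduce(new_sim_state(day = 160L), 30, tiny_packed()$entry_points[["site1"]], land, p)
  before <- state$toads
  for (i in 1:20) state <- sim_step(state, land, rain, p)
  expect_identical(state$toads$id, before$id)
  expect_identical(state$toads$stage, before$stage)
  expect_identical(state$toads$cell, before$cell)
  expect_identical(state$toads$svl, before$svl)
  check_ledger(state$ledger)
})

test_that("mean age at adulthood calibrates near 243 days", {
  land <- tiny_packed()
  rain <- generate_rainfall(600, seed = 3, p_rain_wet = 1, p_rain_dry = 1)
  p <- frozen_params() # no mortality so every recruit is observed
  state <- new_sim_state(day = 1L)
  wc <- which(land$is_water)[1]
  set.seed(11)
  for (i in 1:30) state <- add_clutch(state, wc, 20, age = 0L,
                                      meta_age = sample(34:55, 1))
  ages <- c()
  seen <- integer()
  for (d in 1:400) {
    state <- sim_step(state, land, rain, p)
    ad <- state$toads$stage == 3L
    new <- setdiff(state$toads$id[ad], seen)
    if (length(new)) {
      ages <- c(ages, state$toads$age[match(new, state$toads$id)])
      seen <- c(seen, new)
    }
    if (length(seen) == 600) break
  }
  expect_gte(length(ages), 500)
  expect_lt(abs(mean(ages) - 243) / 243, 0.15)
})

test_that("identical seeds replay bit-identical trajectories", {
  land <- tiny_packed()
  rain <- tiny_rain()
  sp <- scenario_params(6, 1, "site1", 290)
  a <- run_scenario(sp, land, rain, max_years = 1, seed = 99, keep_ledger = TRUE)
  b <- run_scenario(sp, land, rain, max_years = 1, seed = 99, keep_ledger = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$established, b$established)
})
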