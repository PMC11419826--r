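ded_fixture <- function(n = 30, horizon = 3000, seed = 1,
                        with_expression = FALSE, cf = FALSE) {
  p_cf <- if (cf) 0.05 else 0
  m <- mk_model(seed + 500,
                p = c(BD = .95 - p_cf, MD = .01, CD = .04, CF = p_cf))
  params <- fate_sim_params(n_progenitors = n, horizon = horizon, seed = seed)
  ded <- simulate_population(m, params)
  if (with_expression) {
    src <- suppressWarnings(backpropagate_expression(make_synthetic_lineage_db(
      fixture_spec(n_lineages = 20, horizon = horizon + 1000,
                   seed = seed + 900, meanlog = log(1300), sdlog = 0.12))))
    el <- build_expression_list(src)
    ded <- assign_expression(ded, el, src, params)
    attr(ded, "v_max") <- el$v_max
  }
  ded
}

test_that("placement stays inside the sphere and empty worlds are empty", {
  p <- tme_params(seed = 5)
  w <- place_agents(c(suppressive = 0, permissive = 0, lethal = 0), 0, p)
  expect_identical(nrow(w$micro), 0L)
  expect_identical(nrow(w$cancer), 0L)

  w <- place_agents(c(suppressive = 300, permissive = 300, lethal = 400),
                    200, p)
  r <- sqrt(w$micro$x^2 + w$micro$y^2 + w$micro$z^2)
  expect_true(all(r <= 50))
  expect_true(all(sqrt(rowSums(w$cancer[c("x", "y", "z")]^2)) <= 50))
  expect_identical(as.vector(table(w$micro$category)[
    c("suppressive", "permissive", "lethal")]), c(300L, 300L, 400L))
})

test_that("nearest-neighbor selection sorts by distance with id ties", {
  micro <- data.frame(id = 1:3, category = "lethal",
                      x = c(2, 4, 5), y = 0, z = 0)
  nb <- neighbors_within(c(0, 0, 0), micro, radius = 6)
  expect_identical(nb$id, c(1L, 2L))
  expect_equal(nb$distance, c(2, 4))

  expect_identical(nrow(neighbors_within(c(30, 0, 0), micro, radius = 6)), 0L)

  tie <- data.frame(id = c(9L, 4L), category = "lethal",
                    x = c(3, -3), y = 0, z = 0)
  nb <- neighbors_within(c(0, 0, 0), tie, radius = 6)
  expect_identical(nb$id, c(4L, 9L))
})

test_that("nearest-neighbor selection matches an exhaustive sort oracle", {
  set.seed(10)
  for (i in 1:30) {
    micro <- data.frame(id = sample.int(100, 25),
                        category = sample(c("suppressive", "permissive",
                                            "lethal"), 25, TRUE),
                        x = runif(25, -12, 12), y = runif(25, -12, 12),
                        z = runif(25, -12, 12))
    pos <- runif(3, -6, 6)
    nb <- neighbors_within(pos, micro, radius = 6)
    expect_identical(nb$id, oracle_nearest(pos, micro, radius = 6))
  }
})

test_that("the distance-weighted strength offset reproduces its casework", {
  expect_equal(adjusted_suppressive_strength(50, 50, 3, 6), 25)
  expect_equal(adjusted_suppressive_strength(50, 50, 4, 4), 0)
  expect_equal(adjusted_suppressive_strength(50, 0, 3, 6), 50)
  expect_equal(adjusted_suppressive_strength(10, 80, 5, 6), 0)  # clamped
  expect_error(adjusted_suppressive_strength(50, 50, 0, 6), "positive")
})

test_that("resistance maps expression linearly onto effect probability", {
  expect_equal(effect_probability(1000, 1000, 5), 0.2)
  expect_equal(effect_probability(0, 1000, 5), 1.0)
  expect_equal(effect_probability(NA, 1000, 5), 1.0)
  expect_equal(effect_probability(500, 1000, 1), 1.0)
  expect_equal(effect_probability(500, 1000, 5), 1 / 3)
  expect_error(effect_probability(1, 1, 0.5), ">= 1")
})

test_that("suppressive prolongation rescales the cell and its subtree", {
  db <- mk_db(rec(1, 0, birth = 0, fate_t = 1500, fate = "BD"),
              rec(1, 1, p1 = 0, birth = 1500, fate_t = 3000, fate = "BD"),
              rec(1, 2, p1 = 0, birth = 1500, fate_t = 2900, fate = "CD"),
              rec(1, 3, p1 = 1, birth = 3000, fate_t = 4000,
                  fate = "ALIVE_END"),
              rec(1, 4, p1 = 1, birth = 3000, fate_t = 4400,
                  fate = "ALIVE_END"),
              observation_end = 4400)
  # a 25 h doubling time under strength 10 becomes 27.5 h
  got <- apply_suppressive(db, 1, 0, strength = 10, time = 0)
  expect_equal(got$fate_time[got$cell_id == 0], 1650)
  # descendants: durations scaled, births follow the parent
  expect_equal(got$birth_time[got$cell_id == 1], 1650)
  expect_equal(got$fate_time[got$cell_id == 1], 1650 + 1500 * 1.1)
  expect_equal(got$fate_time[got$cell_id == 2], 1650 + 1400 * 1.1)
  expect_equal(got$fate_time[got$cell_id == 3],
               1650 + 1500 * 1.1 + 1000 * 1.1)
  # strength 0 is the identity
  same <- apply_suppressive(db, 1, 0, strength = 0, time = 0)
  expect_equal(as.data.frame(same), as.data.frame(db))
})

test_that("subtree rescaling equals brute-force per-record multiplication", {
  db <- ded_fixture(n = 5, seed = 3)
  roots <- db[is.na(db$parent1), ]
  for (i in seq_len(nrow(roots))) {
    lin <- roots$lineage_id[i]
    got <- apply_suppressive(db, lin, 0, strength = 20, time = 0)
    sub <- got$lineage_id == lin
    # oracle: scale every duration in the lineage, rebuild births top-down
    expect_equal((got$fate_time - got$birth_time)[sub],
                 (db$fate_time - db$birth_time)[sub] * 1.2)
    expect_equal(got$birth_time[sub & is.na(got$parent1)], 0)
    key <- paste(got$lineage_id, got$cell_id)
    p1 <- match(paste(got$lineage_id, got$parent1), key)
    kids <- which(sub & !is.na(p1))
    expect_equal(got$birth_time[kids], got$fate_time[p1[kids]])
    # other lineages untouched
    expect_equal(as.data.frame(got[!sub, ]), as.data.frame(db[!sub, ]))
  }
})

test_that("permissive shortening is floored at the minimum doubling time", {
  db <- mk_db(rec(1, 0, birth = 0, fate_t = 1500, fate = "BD"),
              rec(1, 1, p1 = 0, birth = 1500, fate_t = 2760, fate = "BD"),
              rec(1, 2, p1 = 0, birth = 1500, fate_t = 3000,
                  fate = "ALIVE_END"),
              rec(1, 3, p1 = 1, birth = 2760, fate_t = 3000,
                  fate = "ALIVE_END"),
              rec(1, 4, p1 = 1, birth = 2760, fate_t = 3000,
                  fate = "ALIVE_END"),
              observation_end = 3000)
  # 25 h at strength 10, floor 20 h -> 22.5 h
  got <- apply_permissive(db, 1, 0, strength = 10, min_doubling = 1200,
                          time = 0)
  expect_equal(got$fate_time[got$cell_id == 0], 1350)
  # 21 h at strength 10, floor 20 h -> floored at 20 h
  expect_equal(got$fate_time[got$cell_id == 1] -
                 got$birth_time[got$cell_id == 1], 1200)
  same <- apply_permissive(db, 1, 0, strength = 0, min_doubling = 1200,
                           time = 0)
  expect_equal(as.data.frame(same), as.data.frame(db))
  expect_error(apply_permissive(db, 1, 0, strength = 100,
                                min_doubling = 0), "< 100")
})

test_that("lethal removal prunes exactly the subtree", {
  db <- toy_bd7()
  leaf <- apply_lethal(db, 1, 3, time = 1300)
  expect_identical(nrow(leaf), 7L)  # leaf becomes CD, nothing else removed
  expect_identical(leaf$fate[leaf$cell_id == 3], "CD")

  # killing the root of a complete binary tree leaves only the root (as CD)
  m <- deterministic_bd_model(1000)
  ded <- simulate_population(m, fate_sim_params(n_progenitors = 1,
                                                horizon = 3500, seed = 2))
  expect_identical(nrow(ded) %% 2L, 1L)  # 2^(g+1) - 1 records
  root_killed <- apply_lethal(ded, 1, 0, time = 100)
  expect_identical(nrow(root_killed), 1L)
  expect_identical(root_killed$fate, "CD")

  # random kills equal the complement-of-subtree oracle
  db <- ded_fixture(n = 8, seed = 11, cf = TRUE)
  set.seed(40)
  for (i in sample.int(nrow(db), 10)) {
    lin <- db$lineage_id[i]; id <- db$cell_id[i]
    got <- apply_lethal(db, lin, id, time = db$birth_time[i] + 1)
    removed <- setdiff(oracle_subtree_bfs(db, lin, id), id)
    expect_identical(nrow(got), nrow(db) - length(removed))
    expect_false(any(got$lineage_id == lin & got$cell_id %in% removed))
  }
})

test_that("empty worlds and zero strengths reproduce the control exactly", {
  ded <- ded_fixture(n = 20, seed = 7, cf = TRUE)
  params <- tme_params(seed = 9, horizon = 3000)
  empty <- place_agents(c(suppressive = 0, permissive = 0, lethal = 0), 20,
                        params)
  res <- run_simulation(ded, empty, params)
  control <- population_curve(ded)
  expect_identical(res$trace$n, control$n)
  expect_identical(nrow(res$effect_log), 0L)

  zero <- tme_params(seed = 9, horizon = 3000, s_sup = 0, s_perm = 0,
                     s_lethal = 0)
  w <- place_agents(c(suppressive = 150, permissive = 150, lethal = 150),
                    20, zero)
  res <- run_simulation(ded, w, zero)
  expect_identical(res$trace$n, control$n)
})

test_that("a coincident lethal agent with full strength kills everything", {
  ded <- ded_fixture(n = 10, seed = 13)
  world <- mk_world(
    micro = data.frame(id = 1L, category = "lethal", x = 0, y = 0, z = 0),
    cancer = data.frame(id = 1:10, x = 0, y = 0, z = 0))
  params <- tme_params(seed = 2, horizon = 3000, s_lethal = 100,
                       resistance_max = 1)
  res <- run_simulation(ded, world, params)
  expect_identical(res$final_population, 0)
  expect_true(all(res$effect_log$success))
  expect_identical(nrow(res$db_final), 10L)  # only the dead progenitors
})

test_that("each cell receives at most one suppressive/permissive effect", {
  ded <- ded_fixture(n = 25, seed = 17)
  params <- tme_params(seed = 5, horizon = 3000, s_sup = 30, s_perm = 30,
                       s_lethal = 0)
  w <- place_agents(c(suppressive = 250, permissive = 250, lethal = 0), 25,
                    params)
  res <- run_simulation(ded, w, params)
  mods <- res$effect_log[res$effect_log$effect %in%
                           c("suppressive", "permissive"), ]
  expect_gt(nrow(mods), 0)
  expect_false(any(duplicated(mods[c("lineage_id", "cell_id")])))
})

test_that("final population is conserved against removed subtrees", {
  ded <- ded_fixture(n = 30, seed = 23)  # no fusion events
  params <- tme_params(seed = 6, horizon = 3000, s_sup = 0, s_perm = 0,
                       s_lethal = 100, resistance_max = 1)
  w <- place_agents(c(suppressive = 0, permissive = 0, lethal = 120), 30,
                    params)
  res <- run_simulation(ded, w, params)
  control <- population_curve(ded)$n[length(population_curve(ded)$n)]
  kills <- res$effect_log[res$effect_log$effect == "lethal" &
                            res$effect_log$success, ]
  removed_alive <- 0L
  for (i in seq_len(nrow(kills))) {
    ids <- subtree(ded, kills$lineage_id[i], kills$cell_id[i])
    sub <- ded[ded$lineage_id == kills$lineage_id[i] &
                 ded$cell_id %in% ids, ]
    removed_alive <- removed_alive + sum(sub$fate == "ALIVE_END")
  }
  expect_equal(res$final_population, control - removed_alive)
})

test_that("static anchors keep a cell's nearest-agent set constant", {
  ded <- ded_fixture(n = 15, seed = 29)
  params <- tme_params(seed = 8, horizon = 3000, s_sup = 10, s_perm = 10,
                       s_lethal = 50, resistance_max = 2)
  w <- place_agents(c(suppressive = 100, permissive = 100, lethal = 100),
                    15, params)
  res <- run_simulation(ded, w, params)
  # recompute every logged encounter from the stored anchors
  for (i in seq_len(min(nrow(res$effect_log), 40))) {
    le <- res$effect_log[i, ]
    pos <- res$positions[res$positions$lineage_id == le$lineage_id &
                           res$positions$cell_id == le$cell_id, ]
    nb <- neighbors_within(c(pos$x, pos$y, pos$z), w$micro,
                           params$search_radius)
    expect_identical(nb$id[1], le$agent_id)
  }
})

test_that("simulations are bit-identical under an equal seed", {
  ded <- ded_fixture(n = 15, seed = 31, with_expression = TRUE)
  params <- tme_params(seed = 12, horizon = 3000, s_sup = 20, s_perm = 20,
                       s_lethal = 60, resistance_max = 3,
                       v_max = attr(ded, "v_max"))
  w <- place_agents(c(suppressive = 80, permissive = 80, lethal = 80), 15,
                    params)
  a <- run_simulation(ded, w, params)
  b <- run_simulation(ded, w, params)
  expect_identical(a$trace, b$trace)
  expect_identical(a$effect_log, b$effect_log)
  expect_identical(as.data.frame(a$db_final), as.data.frame(b$db_final))
})

test_that("sweep grids enumerate the Cartesian ratio product", {
  expect_identical(nrow(sweep_grid(c(0, 1), c(0, 1), c(0, 1), 0.1)), 1331L)
  expect_identical(nrow(sweep_grid(c(0.5, 0.5), c(0.2, 0.2), c(0, 0), 0.1)),
                   1L)
  expect_identical(nrow(sweep_grid(c(0, 1), c(0, 1), c(0, 1), 0.5)), 27L)
  g <- sweep_grid(c(0, 1), c(0, 1), c(0, 1), 0.5, base_seed = 3)
  expect_identical(anyDuplicated(g[c("suppressive", "permissive", "lethal")]),
                   0L)
  expect_identical(anyDuplicated(g$seed), 0L)
  expect_error(sweep_grid(increment = 0), "positive")
})

test_that("sweep runs derive counts and stay order-independent", {
  ded <- ded_fixture(n = 10, seed = 37)
  grid <- sweep_grid(c(0, 0.5), c(0, 0), c(0, 0.5), increment = 0.5,
                     base_seed = 2)
  params <- tme_params(seed = 2, horizon = 2000, s_sup = 20, s_perm = 20,
                       s_lethal = 100)
  out <- run_sweep(ded, grid, params)
  expect_identical(nrow(out$summary), 4L)
  # re-running a single row in isolation reproduces the sweep's result
  single <- run_sweep(ded, grid[4, ], params)
  expect_identical(single$summary$final_population,
                   out$summary$final_population[4])
})
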