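# Gillespie loop-extrusion engine: event semantics, conservation laws,
# determinism, and agreement with closed-form expectations.

test_that("init_state builds an empty seeded state and rejects bad input", {
  s <- init_state(chromosome_config(), loop_params(seed = 1))
  expect_s3_class(s, "muk_state")
  expect_equal(s$time, 0)
  expect_equal(nrow(s$complexes), 0L)
  expect_equal(s$n_free, 110L)
  expect_error(loop_params(k_bind = -1), "rates")
  expect_error(loop_params(t_end = 0), "t_end")
  expect_error(chromosome_config(ter_interval = c(5, 5)), "ter_interval")
})

test_that("zero-copy and zero-rate edge cases behave as the model dictates", {
  cfg <- chromosome_config()
  s <- run_sim(cfg, loop_params(n_total = 0L, seed = 3))
  expect_equal(nrow(s$complexes), 0L)
  expect_equal(s$counters[["binds"]], 0)
  expect_equal(s$time, 500)

  s <- run_sim(cfg, loop_params(k_bind = 0, seed = 3))
  expect_equal(nrow(s$complexes), 0L)

  s <- run_sim(cfg, loop_params(k_move = 0, seed = 3))
  expect_true(nrow(s$complexes) > 0)
  expect_true(all(loop_spans(s) == 2L))
})

test_that("a single step on an empty chromosome is a bind creating span 2", {
  s0 <- init_state(chromosome_config(matp_active = FALSE), loop_params(seed = 7))
  s1 <- step_sim(s0)
  expect_equal(nrow(s1$complexes), 1L)
  expect_equal(loop_spans(s1), 2L)
  expect_equal(s1$n_free, 109L)
  expect_equal((s1$complexes$right - s1$complexes$left) %% 4641, 1)
})

test_that("head-on collided dimers stall while outer dimers keep extruding", {
  # two complexes side by side: inner dimers (segments 10 and 11) face each
  # other and can never move; only the outer dimers advance
  st <- toy_loop_state(data.frame(left = c(9, 11), right = c(10, 12)),
                       n_segments = 200L)
  st$params <- loop_params(k_bind = 0, k_unbind = 0, k_move = 1,
                           n_total = 2L, t_end = 1e4)
  set.seed(5)
  for (i in 1:60) st <- step_sim(st)
  expect_true(any(st$complexes$right == 10)) # inner dimers unmoved
  expect_true(any(st$complexes$left == 11))
  expect_true(st$counters[["moves"]] == 60)
  # outer dimers advanced away (left dimer may wrap around the origin)
  outer_left <- st$complexes$left[st$complexes$right == 10]
  outer_right <- st$complexes$right[st$complexes$left == 11]
  expect_true(outer_left != 9 && outer_right != 12)
})

test_that("moving into an active ter interval destroys complex and loop", {
  cfg <- chromosome_config(n_segments = 100L, ter_interval = c(20L, 40L),
                           matp_active = TRUE)
  st <- toy_loop_state(data.frame(left = 17, right = 18), n_segments = 100L,
                       matp_active = TRUE, ter_interval = c(20L, 40L))
  st$params <- loop_params(k_bind = 0, k_unbind = 0, k_move = 1,
                           n_total = 1L, t_end = 1e5)
  set.seed(9)
  # right dimer at 18 reaches 19 then 20 (ter): at most a handful of moves
  for (i in 1:10) {
    st <- step_sim(st)
    if (nrow(st$complexes) == 0L) break
  }
  expect_equal(nrow(st$complexes), 0L)
  expect_equal(st$n_free, 1L)
  expect_gte(st$counters[["displacements"]], 1)
  expect_equal(st$counters[["unbinds"]], 0)
})

test_that("binding into active ter is an instant displacement, never residency", {
  # near-all-ter chromosome: every adjacent pair touches [0, 49), so every
  # binding event is displaced instantly and nothing ever stays bound
  cfg <- chromosome_config(n_segments = 50L, ter_interval = c(0L, 49L),
                           matp_active = TRUE)
  s <- run_sim(cfg, loop_params(k_bind = 0.01, n_total = 5L, t_end = 100,
                                seed = 2))
  expect_equal(nrow(s$complexes), 0L)
  expect_equal(s$n_free, 5L)
  expect_gt(s$counters[["displacements"]], 0)
  expect_equal(s$counters[["unbinds"]], 0)
  expect_equal(s$counters[["binds"]], 0) # displaced binds never count as bound
})

test_that("conservation and occupancy invariants hold along trajectories", {
  cfg <- chromosome_config(n_segments = 300L, ter_interval = c(100L, 160L))
  st <- init_state(cfg, loop_params(n_total = 20L, k_bind = 1e-3, seed = 11))
  for (i in 1:300) {
    st <- step_sim(st, t_end = Inf) # step_sim revalidates every event
    occ <- c(st$complexes$left, st$complexes$right)
    expect_equal(st$n_free + nrow(st$complexes), 20L)
    expect_false(anyDuplicated(occ) > 0)
  }
  expect_gt(st$counters[["binds"]], 0)
})

test_that("runs are deterministic given the seed", {
  a <- run_sim(chromosome_config(), loop_params(seed = 42))
  b <- run_sim(chromosome_config(), loop_params(seed = 42))
  expect_identical(a$complexes, b$complexes)
  expect_identical(a$counters, b$counters)
  r1 <- run_replicas(n_replicas = 2L, base_seed = 7L,
                     params = loop_params(t_end = 50))
  r2 <- run_replicas(n_replicas = 2L, base_seed = 7L,
                     params = loop_params(t_end = 50))
  expect_identical(lapply(r1, `[[`, "complexes"), lapply(r2, `[[`, "complexes"))
  # replica 2 of a pair equals a solo run at base_seed + 1
  solo <- run_sim(chromosome_config(), loop_params(t_end = 50, seed = 8L))
  expect_identical(r1[[2]]$complexes, solo$complexes)
})

test_that("closed-form expected loop sizes match the kinetic rates", {
  expect_equal(analytic_mean_loop(loop_params()), 2 + 2 * 0.6 / 0.0154,
               tolerance = 1e-12)
  expect_equal(analytic_mean_loop(loop_params(directionality = "unidirectional")),
               2 + 0.6 / 0.0154, tolerance = 1e-12)
  expect_equal(analytic_mean_loop(loop_params(k_move = 0)), 2)
  expect_error(analytic_mean_loop(loop_params(k_unbind = 0)), "diverge")
})

test_that("isolated-complex simulation matches closed form and exponential law", {
  p <- loop_params(seed = 123)
  ev <- simulate_unbind_events(10000L, p)
  expect_equal(mean(ev$span_kbp), analytic_mean_loop(p), tolerance = 0.02)
  ks <- suppressWarnings(ks.test(ev$lifetime_s, pexp, rate = p$k_unbind))
  expect_gt(ks$p.value, 0.01)
  # unidirectional variant
  pu <- loop_params(directionality = "unidirectional", seed = 124)
  evu <- simulate_unbind_events(10000L, pu)
  expect_equal(mean(evu$span_kbp), analytic_mean_loop(pu), tolerance = 0.02)
})

test_that("null-model bound fraction obeys the birth-death balance", {
  # no extrusion, no displacement: B / (N - B) = k_bind * n_pairs / k_unbind
  cfg <- chromosome_config(matp_active = FALSE)
  p <- loop_params(k_move = 0)
  snaps <- run_replicas(cfg, p, n_replicas = 150L, base_seed = 300L)
  B <- mean(vapply(snaps, function(s) nrow(s$complexes), numeric(1)))
  mean_pairs <- mean(vapply(snaps, function(s) {
    free <- rep(TRUE, cfg$n_segments)
    free[c(s$complexes$left, s$complexes$right) + 1L] <- FALSE
    sum(free & free[c(2:cfg$n_segments, 1L)])
  }, numeric(1)))
  lhs <- B / (p$n_total - B)
  rhs <- p$k_bind * mean_pairs / p$k_unbind
  expect_equal(lhs, rhs, tolerance = 0.03)
})

test_that("looped fraction rises and loop size falls with copy number", {
  sweep <- occupancy_sweep(c(30L, 110L, 330L), n_replicas = 30L,
                           base_seed = 500L)
  expect_true(all(diff(sweep$mean_looped_fraction) > 0))
  expect_true(all(diff(sweep$mean_loop_kbp) < 0))
  expect_true(all(diff(sweep$mean_bound) > 0))
})

test_that("snapshot states are read out exactly at t_end", {
  s <- run_sim(chromosome_config(), loop_params(t_end = 123.5, seed = 6))
  expect_equal(s$time, 123.5)
})
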