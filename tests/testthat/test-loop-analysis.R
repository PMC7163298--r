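# Loop-state analytics vs hand-computable fixtures and brute-force oracles.

test_that("looped fraction on simple and nested fixtures", {
  empty <- toy_loop_state(data.frame(left = integer(0), right = integer(0)),
                          n_segments = 100L)
  expect_equal(looped_fraction(empty), 0)

  one <- toy_loop_state(data.frame(left = 5, right = 14), n_segments = 100L)
  expect_equal(looped_fraction(one), 0.10)
  expect_equal(loop_sizes(one), 10)

  nested <- toy_loop_state(data.frame(left = c(5, 7), right = c(14, 9)),
                           n_segments = 100L)
  expect_equal(looped_fraction(nested), oracle_looped_fraction(nested))
  expect_equal(looped_fraction(nested), 0.10) # nested counted once
  expect_equal(sort(loop_sizes(nested)), c(3, 10)) # reported independently

  # wrap-around loop
  wrap <- toy_loop_state(data.frame(left = 95, right = 4), n_segments = 100L)
  expect_equal(looped_fraction(wrap), 0.10)
})

test_that("freshly bound complex has a 2-segment (2 kbp) loop", {
  st <- toy_loop_state(data.frame(left = 0, right = 1), n_segments = 20L)
  expect_equal(loop_sizes(st), 2)
})

test_that("cluster rule: separation, collision, nesting", {
  # two complexes separated by unlooped DNA -> two clusters
  apart <- toy_loop_state(data.frame(left = c(0, 10), right = c(3, 13)),
                          n_segments = 30L)
  expect_length(find_clusters(apart), 2L)

  # head-on collision (adjacent occupied segments) -> one cluster
  collided <- toy_loop_state(data.frame(left = c(0, 6), right = c(5, 11)),
                             n_segments = 30L)
  cl <- find_clusters(collided)
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$dna_kbp, 12) # union of both spans
  expect_equal(cl[[1L]]$member_ids, c(1L, 2L))

  # nested loop not touching the parent stem -> its own cluster
  nested_free <- toy_loop_state(data.frame(left = c(0, 3), right = c(9, 6)),
                                n_segments = 30L)
  expect_length(find_clusters(nested_free), 2L)

  # nested loop collided with the parent dimer on one side -> parent cluster
  nested_hit <- toy_loop_state(data.frame(left = c(0, 1), right = c(9, 4)),
                               n_segments = 30L)
  cl <- find_clusters(nested_hit)
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$member_ids, c(1L, 2L))

  # chain of three collided complexes: union DNA via the oracle
  chain <- toy_loop_state(data.frame(left = c(0, 4, 8), right = c(3, 7, 11)),
                          n_segments = 40L)
  expect_equal(largest_cluster_dna(chain), oracle_largest_cluster_dna(chain))
  expect_equal(largest_cluster_dna(chain), 12)
})

test_that("largest cluster of a single complex is its own span; empty is 0", {
  one <- toy_loop_state(data.frame(left = 2, right = 11), n_segments = 50L)
  expect_equal(largest_cluster_dna(one), 10)
  empty <- toy_loop_state(data.frame(left = integer(0), right = integer(0)),
                          n_segments = 50L)
  expect_equal(largest_cluster_dna(empty), 0)
})

test_that("locus distances: inside cluster, plain arc, and shortcut paths", {
  # single complex; locus inside the cluster footprint -> 0
  st <- toy_loop_state(data.frame(left = 10, right = 19), n_segments = 100L)
  expect_equal(locus_distance(st, 10), 0)
  # arc distance with no other loops: locus at segment 0, nearest dimer at 10
  expect_equal(locus_distance(st, 0), 10)
  # a second loop between locus and cluster acts as a shortcut, but the
  # largest cluster is the 10-segment one
  st2 <- toy_loop_state(data.frame(left = c(10, 2), right = c(19, 7)),
                        n_segments = 100L)
  expect_equal(locus_distance(st2, 0), 2 + 0 + 3) # 0->2, shortcut, 7->10
  expect_error(locus_distance(toy_loop_state(
    data.frame(left = integer(0), right = integer(0)), n_segments = 10L), 0),
    "undefined")
})

test_that("analytics match brute-force oracles on random small states", {
  for (seed in 1:100) {
    st <- random_toy_state(n_segments = 20L, max_complexes = 4L, seed = seed)
    expect_equal(looped_fraction(st), oracle_looped_fraction(st),
                 info = paste("seed", seed))
    cl <- find_clusters(st)
    or <- oracle_clusters(st)
    key <- function(cls) sort(vapply(cls, function(c)
      paste(c$member_ids, collapse = ","), character(1)))
    expect_equal(key(cl), key(or), info = paste("seed", seed))
    expect_equal(largest_cluster_dna(st), oracle_largest_cluster_dna(st),
                 info = paste("seed", seed))
    locus <- (seed * 7) %% 20
    expect_equal(locus_distance(st, locus), oracle_locus_distance(st, locus),
                 info = paste("seed", seed))
  }
})

test_that("locus distance never exceeds the arc bound and loops only shorten it", {
  st <- random_toy_state(n_segments = 20L, max_complexes = 3L, seed = 7)
  for (locus in 0:19) {
    d <- locus_distance(st, locus)
    expect_lte(d, 10) # n_segments/2 * 1 kbp
  }
  # adding a shortcut edge never increases any pairwise graph distance
  g0 <- loop_graph(st)
  st_more <- st
  st_more$complexes <- rbind(st_more$complexes,
                             data.frame(id = 99L, left = 14L, right = 2L,
                                        anchor = 14L, moving_side = "both"))
  g1 <- loop_graph(st_more)
  d0 <- igraph::distances(g0)
  d1 <- igraph::distances(g1)
  expect_true(all(d1 <= d0 + 1e-12))
})

test_that("distance profile is 0-width for duplicated snapshots and finds ter", {
  st <- toy_loop_state(data.frame(left = 10, right = 19), n_segments = 100L)
  prof <- distance_profile(list(st, st), loci_kb = c(0, 30, 60), n_boot = 50L)
  expect_equal(prof$ci_lo, prof$mean_kbp)
  expect_equal(prof$ci_hi, prof$mean_kbp)
  expect_equal(nrow(prof), 3L)
})

test_that("random-link chromosomes are reproducible and well-formed", {
  a <- random_link_chromosome(52L, seed = 5)
  b <- random_link_chromosome(52L, seed = 5)
  expect_identical(a$complexes, b$complexes)
  expect_equal(nrow(a$complexes), 52L)
  expect_true(all(a$complexes$left != a$complexes$right))
  bare <- random_link_chromosome(0L, seed = 1)
  expect_equal(nrow(bare$complexes), 0L)
  g <- loop_graph(bare)
  expect_equal(igraph::ecount(g), 4641)
})

test_that("force-directed layout is deterministic and circular for a bare ring", {
  bare <- random_link_chromosome(0L, n_segments = 200L, seed = 1)
  xy1 <- chromosome_layout(bare, seed = 3, niter = 300L)
  xy2 <- chromosome_layout(bare, seed = 3, niter = 300L)
  expect_identical(xy1, xy2)
  # ring adjacency is preserved: neighbours sit far closer than random pairs
  edge_len <- sqrt(rowSums((xy1 - xy1[c(2:200, 1), ])^2))
  set.seed(1)
  rnd <- cbind(sample(200), sample(200))
  rnd_len <- sqrt(rowSums((xy1[rnd[, 1], ] - xy1[rnd[, 2], ])^2))
  expect_lt(mean(edge_len), 0.25 * mean(rnd_len))
})

test_that("copy-number calibration hits a target bound count", {
  N <- calibrate_copy_number(53, n_pilot = 20L, base_seed = 9L)
  snaps <- run_replicas(params = loop_params(n_total = N),
                        n_replicas = 40L, base_seed = 900L)
  B <- mean(vapply(snaps, function(s) nrow(s$complexes), numeric(1)))
  expect_equal(B, 53, tolerance = 0.08)
})
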