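# Analytics on simulated loop states: looped fraction, loop sizes, clusters,
# locus-to-cluster distances (loops as shortcuts), sweeps, null models, layout.

#' Genomic landmark coordinates (kb)
#'
#' Replication origin \emph{oriC} (~3926 kb) and the \emph{ter3} marker
#' (1644 kb) on the E. coli MG1655 chromosome, used to orient distance
#' profiles.
#' @export
ECOLI_ORIC_KB <- 3926

#' @rdname ECOLI_ORIC_KB
#' @export
ECOLI_TER3_KB <- 1644

state_n <- function(state) state$config$n_segments

#' Per-complex loop spans in segments
#'
#' The loop span of a complex is the number of segments from its left to its
#' right dimer inclusive, measured along the arc that grew out of the anchor
#' (so a freshly bound complex has span 2).
#'
#' @param state a \code{muk_state} (or \code{toy_loop_state}).
#' @return integer vector, one span per bound complex.
#' @export
loop_spans <- function(state) {
  cx <- state$complexes
  n <- state_n(state)
  as.integer(((cx$right - cx$left) %% n) + 1L)
}

#' Boolean mask of segments lying within at least one loop
#'
#' @param state a \code{muk_state}.
#' @return logical vector of length \code{n_segments} (index 1 = segment 0).
#' @export
loop_mask <- function(state) {
  n <- state_n(state)
  m <- logical(n)
  cx <- state$complexes
  if (nrow(cx)) {
    sp <- loop_spans(state)
    for (k in seq_len(nrow(cx)))
      m[((cx$left[k] + 0:(sp[k] - 1L)) %% n) + 1L] <- TRUE
  }
  m
}

#' Fraction of the chromosome within a loop
#'
#' Segments inside nested loops are counted once (the statistic is the size of
#' the union of loop spans over the chromosome length).
#'
#' @param state a \code{muk_state}.
#' @return fraction in [0, 1].
#' @export
looped_fraction <- function(state) mean(loop_mask(state))

#' Loop size of each bound complex, in kbp
#'
#' Nested loops are reported independently (one entry per complex).
#'
#' @param state a \code{muk_state}.
#' @return numeric vector of loop sizes (kbp), one per bound complex.
#' @export
loop_sizes <- function(state) loop_spans(state) * state$config$segment_bp / 1000

# positions (0-based) occupied by each complex: 2-column matrix
occupied_segments <- function(state) {
  cbind(state$complexes$left, state$complexes$right)
}

# is complex C (row c) strictly nested inside complex A (row a)?
nested_in <- function(state, spans) {
  cx <- state$complexes
  n <- state_n(state)
  nb <- nrow(cx)
  # rel[i, j] = position of complex j's dimer relative to complex i's left end
  relL <- outer(cx$left, cx$left, function(a, p) (p - a) %% n)
  relR <- outer(cx$left, cx$right, function(a, p) (p - a) %% n)
  inside <- (relL >= 1 & relL <= spans - 2) & (relR >= 1 & relR <= spans - 2)
  diag(inside) <- FALSE
  t(inside) # [c, a] TRUE if c nested in a
}

#' Partition bound complexes into MukBEF clusters
#'
#' A cluster is a set of complexes with no unlooped DNA segments between
#' them. Operationally, two complexes are joined when (a) their occupied
#' segments are immediately adjacent on the chromosome (a head-on collision),
#' or (b) neither is nested inside the other and the DNA between their
#' footprints is entirely within loops or occupied, i.e. their footprints lie
#' in the same maximal run of loop-covered segments. A loop nested inside
#' another contributes to the parent's cluster only through rule (a) - it must
#' have reached the stem of the enclosing loop from at least one side.
#' Membership is transitive.
#'
#' @param state a \code{muk_state}.
#' @return list of clusters, each a list with \code{member_ids} (complex ids)
#'   and \code{dna_kbp} (union of member loop spans, kbp), ordered by
#'   decreasing DNA content then by lowest member id.
#' @export
find_clusters <- function(state) {
  cx <- state$complexes
  nb <- nrow(cx)
  if (nb == 0L) return(list())
  n <- state_n(state)
  spans <- loop_spans(state)
  covered <- loop_mask(state)

  owner <- integer(n) # segment (1-based) -> complex row, 0 if free
  owner[cx$left + 1L] <- seq_len(nb)
  owner[cx$right + 1L] <- seq_len(nb)

  edges <- matrix(integer(0), ncol = 2)
  # (a) collisions: adjacent occupied segments held by different complexes
  occ_idx <- which(owner > 0L)
  nxt <- (occ_idx %% n) + 1L
  hit <- owner[nxt] > 0L & owner[nxt] != owner[occ_idx]
  if (any(hit))
    edges <- rbind(edges, cbind(owner[occ_idx[hit]], owner[nxt[hit]]))

  # (b) same covered run, neither nested in the other
  run <- integer(n)
  if (all(covered)) {
    run[] <- 1L
  } else {
    r <- rle(covered)
    run_id <- cumsum(r$values) * as.integer(r$values)
    run <- inverse.rle(list(lengths = r$lengths, values = run_id))
    # circular wrap: first and last runs merge if both covered
    if (covered[1L] && covered[n]) run[run == run[n]] <- run[1L]
  }
  cx_run <- run[cx$left + 1L]
  nest <- nested_in(state, spans)
  for (rid in unique(cx_run)) {
    members <- which(cx_run == rid)
    if (length(members) < 2L) next
    pr <- t(utils::combn(members, 2L))
    ok <- !nest[cbind(pr[, 1], pr[, 2])] & !nest[cbind(pr[, 2], pr[, 1])]
    if (any(ok)) edges <- rbind(edges, pr[ok, , drop = FALSE])
  }

  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_len(nb), seq_len(nb))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_len(nb)]

  clusters <- lapply(split(seq_len(nb), comp), function(members) {
    m <- logical(n)
    for (k in members)
      m[((cx$left[k] + 0:(spans[k] - 1L)) %% n) + 1L] <- TRUE
    list(member_ids = sort(cx$id[members]),
         dna_kbp = sum(m) * state$config$segment_bp / 1000)
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "dna_kbp"),
               vapply(clusters, function(cl) min(cl$member_ids), numeric(1)))
  unname(clusters[ord])
}

#' DNA content of the largest MukBEF cluster
#'
#' @param state a \code{muk_state}.
#' @return kbp of DNA in the largest cluster (ties broken by lowest member
#'   id); 0 if no complex is bound.
#' @export
largest_cluster_dna <- function(state) {
  cl <- find_clusters(state)
  if (!length(cl)) return(0)
  cl[[1L]]$dna_kbp
}

#' Segment graph of a loop state, with loops as shortcuts
#'
#' Nodes are DNA segments; edges are chromosome adjacency (weight one
#' segment, in kbp) plus one shortcut edge per bound complex between its two
#' dimer segments (default weight 0: traversing a loop stem is free).
#'
#' @param state a \code{muk_state} or random-link structure.
#' @param shortcut_weight_kbp weight of a loop-stem edge (0 or the kbp of one
#'   segment are the sensible choices).
#' @return an igraph graph with \code{n_segments} vertices (vertex i =
#'   segment i-1).
#' @export
loop_graph <- function(state, shortcut_weight_kbp = 0) {
  n <- state_n(state)
  kbp <- state$config$segment_bp / 1000
  ring <- rbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  if (!state$config$circular) ring <- ring[, -n, drop = FALSE]
  w <- rep(kbp, ncol(ring))
  cx <- state$complexes
  if (nrow(cx)) {
    ring <- cbind(ring, rbind(cx$left + 1L, cx$right + 1L))
    w <- c(w, rep(shortcut_weight_kbp, nrow(cx)))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(ring))
  igraph::E(g)$weight <- w
  g
}

locus_to_segment <- function(locus_kb, config) {
  (as.integer(floor(locus_kb * 1000 / config$segment_bp)) %% config$n_segments)
}

#' Shortest distance from a locus to the largest MukBEF cluster
#'
#' Distance is measured along the chromosome in the segment graph where each
#' bound complex contributes a zero-weight shortcut between its two dimer
#' segments, to the nearest segment occupied by a member of the largest
#' cluster.
#'
#' @param state a \code{muk_state} with at least one bound complex.
#' @param locus_kb genomic coordinate(s) of the locus, kb.
#' @param shortcut_weight_kbp see \code{\link{loop_graph}}.
#' @return distance(s) in kbp.
#' @export
locus_distance <- function(state, locus_kb, shortcut_weight_kbp = 0) {
  cl <- find_clusters(state)
  if (!length(cl)) stop("no bound complexes: locus distance undefined")
  cx <- state$complexes
  members <- which(cx$id %in% cl[[1L]]$member_ids)
  targets <- unique(c(cx$left[members], cx$right[members])) + 1L
  g <- loop_graph(state, shortcut_weight_kbp)
  src <- locus_to_segment(locus_kb, state$config) + 1L
  d <- igraph::distances(g, v = unique(src), to = targets)
  dm <- apply(d, 1L, min)
  as.numeric(dm[match(src, unique(src))])
}

#' Mean locus-to-largest-cluster distance profile across replicas
#'
#' @param snapshots list of \code{muk_state} replicas (at least 2).
#' @param loci_kb genomic coordinate grid, kb (default: every 50 kb).
#' @param n_boot bootstrap resamples for the 95 percent CI of the mean.
#' @param seed seed for the bootstrap resampling.
#' @param shortcut_weight_kbp see \code{\link{loop_graph}}.
#' @return data.frame with columns \code{locus_kb}, \code{mean_kbp},
#'   \code{ci_lo}, \code{ci_hi}.
#' @export
distance_profile <- function(snapshots, loci_kb = NULL, n_boot = 1000L,
                             seed = 1L, shortcut_weight_kbp = 0) {
  stopifnot(length(snapshots) >= 2L)
  cfg <- snapshots[[1L]]$config
  if (is.null(loci_kb))
    loci_kb <- seq(0, cfg$n_segments * cfg$segment_bp / 1000 - 1, by = 50)
  d <- vapply(snapshots, locus_distance, numeric(length(loci_kb)),
              locus_kb = loci_kb, shortcut_weight_kbp = shortcut_weight_kbp)
  d <- matrix(d, nrow = length(loci_kb))
  mean_kbp <- rowMeans(d)
  set.seed(seed)
  R <- ncol(d)
  boots <- vapply(seq_len(n_boot), function(b) {
    rowMeans(d[, sample.int(R, R, replace = TRUE), drop = FALSE])
  }, numeric(length(loci_kb)))
  boots <- matrix(boots, nrow = length(loci_kb))
  data.frame(locus_kb = loci_kb, mean_kbp = mean_kbp,
             ci_lo = apply(boots, 1L, quantile, 0.025),
             ci_hi = apply(boots, 1L, quantile, 0.975))
}

#' Summary statistics of a simulated ensemble
#'
#' @param snapshots list of \code{muk_state} replicas.
#' @return data.frame with one row per replica: \code{n_bound},
#'   \code{looped_fraction}, \code{mean_loop_kbp},
#'   \code{largest_cluster_kbp}.
#' @export
summarize_ensemble <- function(snapshots) {
  do.call(rbind, lapply(snapshots, function(s) {
    sz <- loop_sizes(s)
    data.frame(n_bound = nrow(s$complexes),
               looped_fraction = looped_fraction(s),
               mean_loop_kbp = if (length(sz)) mean(sz) else NA_real_,
               largest_cluster_kbp = largest_cluster_dna(s))
  }))
}

#' Loop statistics as a function of MukBEF copy number
#'
#' Runs replica ensembles over a grid of total copy numbers and summarizes
#' mean bound count, looped chromosome fraction, per-complex loop size and
#' largest-cluster DNA, optionally for both extrusion modes.
#'
#' @param copy_numbers integer vector of total copy numbers.
#' @param config a \code{\link{chromosome_config}}.
#' @param params a \code{\link{loop_params}} template.
#' @param n_replicas replicas per copy number.
#' @param base_seed first replica seed (advanced between conditions).
#' @param directionality character vector of extrusion modes to sweep.
#' @return data.frame with one row per copy number and mode.
#' @export
occupancy_sweep <- function(copy_numbers, config = chromosome_config(),
                            params = loop_params(), n_replicas = 100L,
                            base_seed = 1L,
                            directionality = "bidirectional") {
  stopifnot(length(copy_numbers) >= 1L)
  rows <- list()
  seed <- base_seed
  for (dir in directionality) for (N in copy_numbers) {
    p <- params
    p$n_total <- as.integer(N)
    p$directionality <- dir
    if (N == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        n_total = 0L, directionality = dir, mean_bound = 0,
        mean_looped_fraction = 0, mean_loop_kbp = 0, mean_largest_cluster_kbp = 0)
    } else {
      snaps <- run_replicas(config, p, n_replicas, seed)
      s <- summarize_ensemble(snaps)
      rows[[length(rows) + 1L]] <- data.frame(
        n_total = as.integer(N), directionality = dir,
        mean_bound = mean(s$n_bound),
        mean_looped_fraction = mean(s$looped_fraction),
        mean_loop_kbp = mean(unlist(lapply(snaps, loop_sizes))),
        mean_largest_cluster_kbp = mean(s$largest_cluster_kbp))
    }
    seed <- seed + n_replicas
  }
  do.call(rbind, rows)
}

#' Calibrate total copy number to a target mean bound count
#'
#' The experimental reference conditions are stated as numbers of
#' chromosome-bound complexes (about 53 in wild type, about 175 with
#' increased occupancy). This helper finds the total copy number whose
#' steady-state ensemble mean bound count matches a target, by a short pilot
#' ensemble and one proportional correction step.
#'
#' @param target_bound desired mean number of bound complexes.
#' @param config a \code{\link{chromosome_config}}.
#' @param params a \code{\link{loop_params}} template.
#' @param n_pilot pilot replicas per evaluation.
#' @param base_seed pilot seed.
#' @return integer total copy number.
#' @export
calibrate_copy_number <- function(target_bound, config = chromosome_config(),
                                  params = loop_params(), n_pilot = 40L,
                                  base_seed = 1L) {
  mean_bound <- function(N) {
    p <- params
    p$n_total <- as.integer(round(N))
    mean(vapply(run_replicas(config, p, n_pilot, base_seed),
                function(s) nrow(s$complexes), numeric(1)))
  }
  N0 <- max(1, round(target_bound / 0.45)) # rough prior: ~45-50% bound
  b0 <- mean_bound(N0)
  N1 <- round(N0 * target_bound / max(b0, 1e-9))
  b1 <- mean_bound(N1)
  # one secant refinement if still off by more than 2%
  if (abs(b1 - target_bound) / target_bound > 0.02 && abs(b1 - b0) > 1e-9) {
    N2 <- round(N1 + (target_bound - b1) * (N1 - N0) / (b1 - b0))
    return(as.integer(max(1, N2)))
  }
  as.integer(max(1, N1))
}

#' Random-link null chromosome
#'
#' Generates \code{n_links} connections between uniformly random pairs of DNA
#' segments, as a loop-state-like structure consumable by
#' \code{\link{loop_graph}}, \code{\link{chromosome_layout}} and the distance
#' operations. With 52 links this is the wild-type-occupancy random null.
#'
#' @param n_links number of random connections.
#' @param n_segments chromosome size in segments.
#' @param seed RNG seed.
#' @param segment_bp basepairs per segment.
#' @return a \code{muk_state}-shaped object (class \code{random_link_state}).
#' @export
random_link_chromosome <- function(n_links = 52L, n_segments = 4641L, seed = 1L,
                                   segment_bp = 1000L) {
  stopifnot(n_links >= 0L)
  set.seed(seed)
  cx <- empty_complexes()
  if (n_links > 0L) {
    a <- sample.int(n_segments, n_links, replace = TRUE) - 1L
    b <- sample.int(n_segments, n_links, replace = TRUE) - 1L
    while (any(a == b)) {
      i <- a == b
      b[i] <- sample.int(n_segments, sum(i), replace = TRUE) - 1L
    }
    cx <- data.frame(id = seq_len(n_links), left = pmin(a, b), right = pmax(a, b),
                     anchor = pmin(a, b), moving_side = "both",
                     stringsAsFactors = FALSE)
  }
  structure(list(time = NA_real_,
                 config = chromosome_config(n_segments, segment_bp,
                                            matp_active = FALSE),
                 params = NULL, complexes = cx,
                 n_free = 0L, next_id = n_links + 1L,
                 counters = c(binds = 0, unbinds = 0, moves = 0, displacements = 0)),
            class = c("random_link_state", "muk_state"))
}

#' Force-directed 2-D layout of a loop state
#'
#' Embeds the segment graph (chromosome adjacency plus loop edges) with the
#' Fruchterman-Reingold algorithm; visualization only.
#'
#' @param state a \code{muk_state} or random-link structure.
#' @param seed layout seed (the embedding is deterministic given the seed).
#' @param niter iterations of the layout algorithm.
#' @return a matrix with one (x, y) row per segment.
#' @export
chromosome_layout <- function(state, seed = 1L, niter = 500L) {
  g <- loop_graph(state, shortcut_weight_kbp = state$config$segment_bp / 1000)
  set.seed(seed)
  igraph::layout_with_fr(g, niter = niter, weights = NA)
}
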