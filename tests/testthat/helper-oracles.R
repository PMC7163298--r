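# Brute-force oracles, written independently of the package implementation:
# explicit per-segment loops, naive BFS flood fill, O(V^2) Dijkstra.

oracle_span_segs <- function(state, k) {
  n <- state$config$n_segments
  cx <- state$complexes
  len <- ((cx$right[k] - cx$left[k]) %% n) + 1L
  (cx$left[k] + 0:(len - 1L)) %% n
}

oracle_looped_fraction <- function(state) {
  n <- state$config$n_segments
  inloop <- rep(FALSE, n)
  for (k in seq_len(nrow(state$complexes)))
    for (s in oracle_span_segs(state, k)) inloop[s + 1L] <- TRUE
  sum(inloop) / n
}

# cluster rule, evaluated pairwise with explicit arc walks:
#  (a) occupied segments of two complexes adjacent on the ring, or
#  (b) neither nested in the other and some arc between occupied segments of
#      the two is entirely covered (occupied or within a loop span)
oracle_clusters <- function(state) {
  n <- state$config$n_segments
  cx <- state$complexes
  nb <- nrow(cx)
  if (nb == 0L) return(list())
  covered <- rep(FALSE, n)
  for (k in seq_len(nb)) for (s in oracle_span_segs(state, k)) covered[s + 1L] <- TRUE
  feet <- lapply(seq_len(nb), function(k) c(cx$left[k], cx$right[k]))
  interior <- lapply(seq_len(nb), function(k)
    setdiff(oracle_span_segs(state, k), feet[[k]]))
  nested <- function(a, b) all(feet[[a]] %in% interior[[b]])
  arc_covered <- function(s, t) {
    # walk forward from s to t; TRUE if all strictly-between segments covered
    cur <- (s + 1L) %% n
    while (cur != t) {
      if (!covered[cur + 1L]) return(FALSE)
      cur <- (cur + 1L) %% n
    }
    TRUE
  }
  linked <- matrix(FALSE, nb, nb)
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    if (a >= b) next
    hit <- FALSE
    for (s in feet[[a]]) for (t in feet[[b]])
      if ((s - t) %% n == 1L || (t - s) %% n == 1L) hit <- TRUE
    if (!hit && !nested(a, b) && !nested(b, a)) {
      for (s in feet[[a]]) for (t in feet[[b]])
        if (arc_covered(s, t) || arc_covered(t, s)) hit <- TRUE
    }
    linked[a, b] <- linked[b, a] <- hit
  }
  # BFS flood fill over the link matrix
  comp <- rep(0L, nb); nc <- 0L
  for (a in seq_len(nb)) {
    if (comp[a] > 0L) next
    nc <- nc + 1L
    queue <- a
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- nc
      queue <- c(queue, which(linked[v, ] & comp == 0L))
    }
  }
  lapply(seq_len(nc), function(cid) {
    members <- which(comp == cid)
    segs <- rep(FALSE, n)
    for (k in members) for (s in oracle_span_segs(state, k)) segs[s + 1L] <- TRUE
    list(member_ids = sort(cx$id[members]),
         dna_kbp = sum(segs) * state$config$segment_bp / 1000)
  })
}

oracle_largest_cluster_dna <- function(state) {
  cl <- oracle_clusters(state)
  if (!length(cl)) return(0)
  max(vapply(cl, `[[`, numeric(1), "dna_kbp"))
}

# plain O(V^2) Dijkstra on the explicit segment graph
oracle_locus_distance <- function(state, locus_kb) {
  n <- state$config$n_segments
  kbp <- state$config$segment_bp / 1000
  cx <- state$complexes
  adj <- vector("list", n)
  add_edge <- function(u, v, w) {
    adj[[u + 1L]] <<- rbind(adj[[u + 1L]], c(v, w))
    adj[[v + 1L]] <<- rbind(adj[[v + 1L]], c(u, w))
  }
  for (i in 0:(n - 1L)) add_edge(i, (i + 1L) %% n, kbp)
  for (k in seq_len(nrow(cx))) add_edge(cx$left[k], cx$right[k], 0)
  src <- floor(locus_kb * 1000 / state$config$segment_bp) %% n
  dist <- rep(Inf, n); dist[src + 1L] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1L] + 1L; w <- adj[[u]][r, 2L]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  cl <- oracle_clusters(state)
  best <- cl[[which.max(vapply(cl, `[[`, numeric(1), "dna_kbp"))]]
  members <- which(cx$id %in% best$member_ids)
  min(dist[c(cx$left[members], cx$right[members]) + 1L])
}

# random small loop states with non-overlapping dimer placements; may contain
# nested and collided configurations
random_toy_state <- function(n_segments = 20L, max_complexes = 4L, seed = 1L) {
  set.seed(seed)
  nb <- sample.int(max_complexes, 1L)
  taken <- rep(FALSE, n_segments)
  rows <- list()
  for (k in seq_len(nb)) {
    for (try in 1:50) {
      left <- sample.int(n_segments, 1L) - 1L
      span <- sample(2:max(2L, n_segments %/% 2L), 1L)
      right <- (left + span - 1L) %% n_segments
      if (left == right) next
      if (!taken[left + 1L] && !taken[right + 1L]) {
        taken[c(left, right) + 1L] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(left = left, right = right)
        break
      }
    }
  }
  toy_loop_state(do.call(rbind, rows), n_segments = n_segments)
}

# brute-force optimal frame-to-frame assignment: enumerate every injective
# mapping of detections to open tracks within the radius; maximize link
# count, then minimize summed distance
oracle_assignment <- function(dist_mat, radius) {
  nr <- nrow(dist_mat); nc <- ncol(dist_mat)
  best <- list(n = -1L, s = Inf, asg = rep(NA_integer_, nr))
  asg <- rep(NA_integer_, nr)
  recurse <- function(i) {
    if (i > nr) {
      nlink <- sum(!is.na(asg))
      ssum <- sum(dist_mat[cbind(which(!is.na(asg)), asg[!is.na(asg)])])
      if (nlink > best$n || (nlink == best$n && ssum < best$s))
        best <<- list(n = nlink, s = ssum, asg = asg)
      return(invisible())
    }
    for (j in seq_len(nc)) {
      if (j %in% asg || dist_mat[i, j] > radius) next
      asg[i] <<- j; recurse(i + 1L); asg[i] <<- NA_integer_
    }
    recurse(i + 1L)
  }
  recurse(1L)
  best$asg
}

# maximum-likelihood fit of a two-component exponential mixture to raw
# durations (cross-check oracle for the survival-curve fit)
oracle_mixture_mle <- function(durations) {
  nll <- function(p) {
    w <- plogis(p[1L]); t1 <- exp(p[2L]); t2 <- exp(p[3L])
    -sum(log(w * dexp(durations, 1 / t1) + (1 - w) * dexp(durations, 1 / t2)))
  }
  fit <- optim(c(0, log(mean(durations) / 4), log(mean(durations) * 2)), nll,
               control = list(maxit = 2000))
  taus <- sort(exp(fit$par[2:3]))
  list(tau_fast = taus[1L], tau_slow = taus[2L])
}

# exhaustive-search Otsu threshold over 256 bins
oracle_otsu <- function(img) {
  v <- as.vector(img)
  rng <- range(v)
  brks <- seq(rng[1], rng[2], length.out = 257L)
  h <- hist(v, breaks = brks, plot = FALSE)$counts
  best_t <- NA; best_var <- -1
  total <- sum(h); mids <- (brks[-1] + brks[-257]) / 2
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best_var) { best_var <- bc; best_t <- brks[k + 1] }
  }
  best_t
}
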