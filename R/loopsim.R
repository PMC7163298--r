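# Loop-extrusion simulator: configuration, state, and the Gillespie engine
# wrappers. Segment indices are 0-based throughout; segment i covers genomic
# interval [i*segment_bp, (i+1)*segment_bp).

#' Chromosome discretization and ter geometry
#'
#' The E. coli chromosome (4,641 kbp) is discretized into 1-kbp segments. The
#' MatP-occupied \emph{ter} region is a half-open segment-index interval
#' (indices modulo \code{n_segments}); the default is an 800-kbp arc centered
#' on the \emph{ter3} coordinate at 1644 kb, i.e. segments [1244, 2044).
#'
#' @param n_segments number of DNA segments (default 4641).
#' @param segment_bp basepairs per segment (default 1000).
#' @param circular logical; circular chromosome (default TRUE).
#' @param ter_interval length-2 integer vector, half-open 0-based segment
#'   range \code{[lo, hi)} of the MatP-occupied region; may wrap around the
#'   origin (\code{lo > hi}).
#' @param matp_active logical; if TRUE, MukBEF binding to or moving into the
#'   ter interval leads to instant dissociation (MatP displacement).
#' @return an object of class \code{chromosome_config}.
#' @export
chromosome_config <- function(n_segments = 4641L, segment_bp = 1000L,
                              circular = TRUE,
                              ter_interval = c(1244L, 2044L),
                              matp_active = TRUE) {
  n_segments <- as.integer(n_segments)
  stopifnot(n_segments >= 3L, segment_bp > 0)
  ter_interval <- as.integer(ter_interval) %% n_segments
  len <- (ter_interval[2] - ter_interval[1]) %% n_segments
  if (isTRUE(matp_active) && (len <= 0L || len >= n_segments))
    stop("ter_interval must satisfy 0 < length < n_segments")
  structure(list(n_segments = n_segments, segment_bp = as.integer(segment_bp),
                 circular = isTRUE(circular), ter_interval = ter_interval,
                 matp_active = isTRUE(matp_active)),
            class = "chromosome_config")
}

#' Kinetic parameters of the loop-extrusion model
#'
#' Rates as measured or assumed for MukBEF: unbinding rate
#' \code{k_unbind} = 0.0154 / s (65 s mean residency), binding rate
#' \code{k_bind} = 3.9e-6 / s per adjacent free segment pair per free
#' (cytosolic) complex, and extrusion rate \code{k_move} = 0.6 segments per
#' dimer per second (600 bp/s, the in vitro condensin estimate). Wild-type
#' cells carry about 110 MukBEF dimer-of-dimers complexes.
#'
#' @param k_bind binding rate, 1/s per eligible adjacent free segment pair per
#'   free complex.
#' @param k_unbind unbinding rate, 1/s per bound complex.
#' @param k_move extrusion stepping rate, segments/s per dimer.
#' @param n_total total MukBEF dimer-of-dimers copy number.
#' @param directionality \code{"bidirectional"} (both dimers extrude) or
#'   \code{"unidirectional"} (one dimer anchored; moving side chosen uniformly
#'   at random at binding).
#' @param t_end simulated time at which the state is read out, seconds. The
#'   default 500 s lets the loop structure reach maturation (several mean
#'   residency times).
#' @param seed integer RNG seed, or NULL to use the current RNG stream.
#' @return an object of class \code{loop_params}.
#' @export
loop_params <- function(k_bind = 3.9e-6, k_unbind = 0.0154, k_move = 0.6,
                        n_total = 110L,
                        directionality = c("bidirectional", "unidirectional"),
                        t_end = 500, seed = NULL) {
  directionality <- match.arg(directionality)
  if (any(c(k_bind, k_unbind, k_move) < 0)) stop("rates must be >= 0")
  if (n_total < 0) stop("n_total must be >= 0")
  if (t_end <= 0) stop("t_end must be > 0")
  structure(list(k_bind = k_bind, k_unbind = k_unbind, k_move = k_move,
                 n_total = as.integer(n_total), directionality = directionality,
                 t_end = t_end, seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "loop_params")
}

empty_complexes <- function() {
  data.frame(id = integer(0), left = integer(0), right = integer(0),
             anchor = integer(0), moving_side = character(0),
             stringsAsFactors = FALSE)
}

side_code <- function(s) match(s, c("both", "left_only", "right_only")) - 1L
side_name <- function(code) c("both", "left_only", "right_only")[code + 1L]

#' Initialize an empty simulation state
#'
#' @param config a \code{\link{chromosome_config}}.
#' @param params a \code{\link{loop_params}}.
#' @return an object of class \code{muk_state}: time 0, an empty chromosome
#'   and all \code{n_total} complexes cytosolic. If \code{params$seed} is set
#'   the RNG is seeded, so subsequent stepping is reproducible.
#' @export
init_state <- function(config, params) {
  stopifnot(inherits(config, "chromosome_config"), inherits(params, "loop_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  structure(list(time = 0, config = config, params = params,
                 complexes = empty_complexes(),
                 bind_time = numeric(0),
                 n_free = params$n_total, next_id = 1L,
                 counters = c(binds = 0, unbinds = 0, moves = 0, displacements = 0)),
            class = "muk_state")
}

#' @export
print.muk_state <- function(x, ...) {
  cat(sprintf("<muk_state> t = %.1f s, %d bound / %d total complexes\n",
              x$time, nrow(x$complexes), x$params$n_total))
  cat(sprintf("  events: %s\n",
              paste(names(x$counters), round(x$counters), sep = "=", collapse = " ")))
  invisible(x)
}

validate_state <- function(state) {
  cx <- state$complexes
  cfg <- state$config
  if (state$n_free + nrow(cx) != state$params$n_total)
    stop("conservation violated: n_free + bound != n_total")
  occ <- c(cx$left, cx$right)
  if (anyDuplicated(occ)) stop("inconsistent occupancy: segment held twice")
  if (any(occ < 0 | occ >= cfg$n_segments)) stop("segment index out of range")
  if (any(cx$left == cx$right)) stop("complex occupying a single segment")
  if (cfg$matp_active && length(occ) &&
      any(in_ter_interval(occ, cfg)))
    stop("occupied segment inside active ter interval")
  invisible(state)
}

in_ter_interval <- function(seg, config) {
  len <- (config$ter_interval[2] - config$ter_interval[1]) %% config$n_segments
  ((seg - config$ter_interval[1]) %% config$n_segments) < len
}

call_core <- function(state, t_end, max_events = Inf, record_unbinds = FALSE,
                      stop_after_unbinds = 0L) {
  cfg <- state$config; p <- state$params
  cx <- state$complexes
  m <- cbind(id = cx$id, left = cx$left, right = cx$right, anchor = cx$anchor,
             moving_side = if (nrow(cx)) side_code(cx$moving_side) else integer(0))
  storage.mode(m) <- "integer"
  ter_len <- (cfg$ter_interval[2] - cfg$ter_interval[1]) %% cfg$n_segments
  res <- sim_core(cfg$n_segments, cfg$circular,
                  cfg$ter_interval[1], ter_len, cfg$matp_active,
                  p$k_bind, p$k_unbind, p$k_move,
                  p$n_total, match(p$directionality, c("bidirectional", "unidirectional")) - 1L,
                  state$time, t_end,
                  m, state$bind_time, state$next_id,
                  max_events, record_unbinds, as.integer(stop_after_unbinds))
  out <- state
  out$time <- res$time
  cxm <- res$complexes
  out$complexes <- data.frame(id = cxm[, "id"], left = cxm[, "left"],
                              right = cxm[, "right"], anchor = cxm[, "anchor"],
                              moving_side = side_name(cxm[, "moving_side"]),
                              stringsAsFactors = FALSE)
  out$bind_time <- res$bind_time
  out$n_free <- res$n_free
  out$next_id <- res$next_id
  out$counters <- state$counters + res$counters
  attr(out, "unbind_spans") <- res$unbind_spans
  attr(out, "unbind_lifetimes") <- res$unbind_lifetimes
  attr(out, "n_events") <- res$n_events
  out
}

#' Advance the simulation by exactly one reaction event
#'
#' Applies one Gillespie event (bind, move, or unbind/displacement) with an
#' exponentially distributed waiting time, using the current RNG stream. If no
#' reaction can fire or the waiting time crosses \code{t_end}, the state is
#' returned advanced to \code{t_end}.
#'
#' @param state a \code{muk_state}.
#' @param t_end time horizon, seconds (default: \code{params$t_end}).
#' @return the updated \code{muk_state}.
#' @export
step_sim <- function(state, t_end = state$params$t_end) {
  stopifnot(inherits(state, "muk_state"))
  validate_state(call_core(state, t_end, max_events = 1))
}

#' Run the loop-extrusion simulation to its readout time
#'
#' Exact stochastic simulation (Gillespie direct method) of MukBEF
#' dimer-of-dimers loop extrusion, read out at \code{params$t_end} (default
#' 500 s). Deterministic given \code{params$seed}.
#'
#' @inheritParams init_state
#' @return the final \code{muk_state}.
#' @examples
#' s <- run_sim(chromosome_config(), loop_params(seed = 1))
#' looped_fraction(s)
#' @export
run_sim <- function(config = chromosome_config(), params = loop_params()) {
  state <- init_state(config, params)
  validate_state(call_core(state, params$t_end))
}

#' Run independent simulation replicas
#'
#' Replica \code{i} uses seed \code{base_seed + i - 1}, so any subset of
#' replicas is reproducible in isolation.
#'
#' @inheritParams init_state
#' @param n_replicas number of independent runs.
#' @param base_seed seed of the first replica.
#' @return a list of \code{muk_state} snapshots.
#' @export
run_replicas <- function(config = chromosome_config(), params = loop_params(),
                         n_replicas = 200L, base_seed = 1L) {
  stopifnot(n_replicas >= 1)
  lapply(seq_len(n_replicas), function(i) {
    p <- params
    p$seed <- as.integer(base_seed + i - 1L)
    run_sim(config, p)
  })
}

#' Closed-form expected loop size of an isolated complex
#'
#' For a single complex that never collides, each actively extruding dimer
#' makes on average \code{k_move / k_unbind} steps before unbinding, and each
#' step grows the loop span by one segment. With the initial span of 2
#' segments (the two adjacent sites occupied at binding) the expected span at
#' unbinding is \code{2 + 2 k_move / k_unbind} segments for bidirectional
#' extrusion and \code{2 + k_move / k_unbind} for unidirectional extrusion.
#' With the default rates this gives approximately 80 and 40 kbp.
#'
#' @param params a \code{\link{loop_params}}.
#' @param config a \code{\link{chromosome_config}} (for the kbp conversion).
#' @return expected loop size in kbp.
#' @export
analytic_mean_loop <- function(params = loop_params(), config = chromosome_config()) {
  if (params$k_unbind <= 0) stop("k_unbind must be > 0 (expected loop size diverges)")
  n_motors <- if (params$directionality == "bidirectional") 2 else 1
  segs <- 2 + n_motors * params$k_move / params$k_unbind
  segs * config$segment_bp / 1000
}

#' Simulate unbinding events of an isolated complex
#'
#' Runs the full engine with a single complex (\code{n_total = 1}) and records
#' the loop span and bound lifetime at every spontaneous unbinding event, for
#' comparison with \code{\link{analytic_mean_loop}} and the exponential
#' residency law. MatP displacement is off by default so that no lifetime is
#' truncated.
#'
#' @param n_unbinds number of unbinding events to collect.
#' @param params a \code{\link{loop_params}}; \code{n_total} is forced to 1.
#' @param config a \code{\link{chromosome_config}}.
#' @return data.frame with columns \code{span_kbp} and \code{lifetime_s}.
#' @export
simulate_unbind_events <- function(n_unbinds = 10000L,
                                   params = loop_params(),
                                   config = chromosome_config(matp_active = FALSE)) {
  p <- params
  p$n_total <- 1L
  state <- init_state(config, p)
  res <- call_core(state, t_end = Inf, record_unbinds = TRUE,
                   stop_after_unbinds = n_unbinds)
  data.frame(span_kbp = attr(res, "unbind_spans") * config$segment_bp / 1000,
             lifetime_s = attr(res, "unbind_lifetimes"))
}
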