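# Single-molecule tracking analytics: track linking, apparent diffusion
# coefficients, bound-fraction classification, residency-time survival
# analysis with photobleaching correction.
#
# A localization table is a data.frame with columns `frame`, `x_um`, `y_um`
# and optionally `w_short_nm`, `w_long_nm`, `intensity`. Tracked tables gain a
# `track_id` column.

# ---- linking ---------------------------------------------------------------

# Optimal assignment of detections to open tracks within the linking radius:
# maximize the number of links, then minimize the summed step distance.
# Feasible pairs are decomposed into connected components; small components
# are solved exactly by enumeration, large ones greedily.
assign_links <- function(dist_mat, radius) {
  nr <- nrow(dist_mat); nc <- ncol(dist_mat)
  feas <- dist_mat <= radius
  match_row <- rep(NA_integer_, nr)
  if (!any(feas)) return(match_row)
  # connected components over the bipartite feasibility graph
  comp_r <- rep(0L, nr); comp_c <- rep(0L, nc); ncomp <- 0L
  for (r0 in seq_len(nr)) {
    if (comp_r[r0] > 0L || !any(feas[r0, ])) next
    ncomp <- ncomp + 1L
    qr <- r0
    while (length(qr)) {
      r <- qr[1L]; qr <- qr[-1L]
      if (comp_r[r] > 0L) next
      comp_r[r] <- ncomp
      for (cc in which(feas[r, ])) {
        if (comp_c[cc] == 0L) {
          comp_c[cc] <- ncomp
          qr <- c(qr, which(feas[, cc] & comp_r == 0L))
        }
      }
    }
  }
  for (k in seq_len(ncomp)) {
    rows <- which(comp_r == k); cols <- which(comp_c == k)
    if (length(rows) == 1L) {
      match_row[rows] <- cols[which.min(dist_mat[rows, cols])]
      next
    }
    if (length(rows) <= 9L) {
      best <- solve_component(dist_mat, feas, rows, cols)
      match_row[rows] <- best
    } else {
      # greedy fallback: repeatedly take the globally closest feasible pair
      sub <- dist_mat[rows, cols, drop = FALSE]
      sub[!feas[rows, cols, drop = FALSE]] <- Inf
      while (any(is.finite(sub))) {
        ij <- arrayInd(which.min(sub), dim(sub))
        match_row[rows[ij[1L]]] <- cols[ij[2L]]
        sub[ij[1L], ] <- Inf; sub[, ij[2L]] <- Inf
      }
    }
  }
  match_row
}

# exact search over assignments within one component (maximize links, then
# minimize total distance)
solve_component <- function(dist_mat, feas, rows, cols) {
  nr <- length(rows)
  best_n <- -1L; best_sum <- Inf; best_asg <- rep(NA_integer_, nr)
  used <- logical(length(cols))
  asg <- rep(NA_integer_, nr)
  rec <- function(i, nlink, ssum) {
    # bound: even linking every remaining row cannot beat best
    if (nlink + (nr - i + 1L) < best_n) return()
    if (i > nr) {
      if (nlink > best_n || (nlink == best_n && ssum < best_sum)) {
        best_n <<- nlink; best_sum <<- ssum; best_asg <<- asg
      }
      return()
    }
    for (j in seq_along(cols)) {
      if (used[j] || !feas[rows[i], cols[j]]) next
      used[j] <<- TRUE; asg[i] <<- cols[j]
      rec(i + 1L, nlink + 1L, ssum + dist_mat[rows[i], cols[j]])
      used[j] <<- FALSE; asg[i] <<- NA_integer_
    }
    rec(i + 1L, nlink, ssum) # leave row i unlinked
  }
  rec(1L, 0L, 0)
  best_asg
}

#' Link localizations into single-molecule tracks
#'
#' Localizations in consecutive frames within a window of \code{radius_um}
#' are linked into tracks. When several localizations fall within the window,
#' links are chosen so that the number of links is maximal and the sum of
#' step distances is minimal. A transient disappearance of up to
#' \code{max_gap} frames (blinking or a missed localization) is tolerated;
#' set \code{max_gap = 0} for long-exposure residency movies where missing
#' frames are not allowed.
#'
#' @param locs localization table (columns \code{frame}, \code{x_um},
#'   \code{y_um}, ...).
#' @param radius_um linking window, micrometers (default 0.48).
#' @param max_gap maximum number of missing frames inside a track (0 or 1).
#' @return the table with a \code{track_id} column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(locs, radius_um = 0.48, max_gap = 1L) {
  if (!nrow(locs)) {
    locs$track_id <- integer(0)
    return(locs)
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  tid <- integer(nrow(locs))
  xs <- locs$x_um; ys <- locs$y_um
  by_frame <- split(seq_len(nrow(locs)), locs$frame)
  frames <- as.numeric(names(by_frame))
  next_id <- 1L
  # open tracks
  op_id <- integer(0); op_x <- numeric(0); op_y <- numeric(0); op_f <- integer(0)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    alive <- op_f >= f - 1L - max_gap
    op_id <- op_id[alive]; op_x <- op_x[alive]; op_y <- op_y[alive]; op_f <- op_f[alive]
    idx <- by_frame[[fi]]
    matched_det <- rep(NA_integer_, length(idx)) # index into open tracks
    if (length(op_id) && length(idx)) {
      dm <- sqrt(outer(op_x, xs[idx], "-")^2 +
                 outer(op_y, ys[idx], "-")^2)
      m <- assign_links(dm, radius_um)
      for (r in which(!is.na(m))) matched_det[m[r]] <- r
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (!is.na(matched_det[k])) {
        r <- matched_det[k]
        tid[i] <- op_id[r]
        op_x[r] <- xs[i]; op_y[r] <- ys[i]; op_f[r] <- f
      } else {
        tid[i] <- next_id
        op_id <- c(op_id, next_id); op_x <- c(op_x, xs[i])
        op_y <- c(op_y, ys[i]); op_f <- c(op_f, f)
        next_id <- next_id + 1L
      }
    }
  }
  locs$track_id <- tid
  locs[order(tid, locs$frame), , drop = FALSE]
}

# ---- mobility --------------------------------------------------------------

#' Apparent diffusion coefficient of one track
#'
#' \code{D* = 1/(4 n dt) * sum_i [(x_i - x_{i+1})^2 + (y_i - y_{i+1})^2]}
#' over the \code{n} one-frame steps of the track. Tracks with fewer than
#' \code{min_steps} one-frame steps are omitted (\code{NA}).
#'
#' @param track data.frame with \code{frame}, \code{x_um}, \code{y_um} for a
#'   single molecule.
#' @param frame_time frame interval \code{dt}, seconds (default 15.48 ms, the
#'   fast-tracking exposure).
#' @param min_steps minimum number of steps (default 4).
#' @return D* in um^2/s, or \code{NA} for omitted tracks.
#' @export
apparent_diffusion <- function(track, frame_time = 0.01548, min_steps = 4L) {
  o <- order(track$frame)
  dx <- diff(track$x_um[o]); dy <- diff(track$y_um[o])
  one <- diff(track$frame[o]) == 1L
  n <- sum(one)
  if (n < min_steps) return(NA_real_)
  sum(dx[one]^2 + dy[one]^2) / (4 * n * frame_time)
}

#' Apparent diffusion coefficients of all tracks in a linked table
#'
#' @param tracks a linked localization table (with \code{track_id}).
#' @inheritParams apparent_diffusion
#' @return named numeric vector of D* per track, short tracks dropped.
#' @export
apparent_diffusion_all <- function(tracks, frame_time = 0.01548, min_steps = 4L) {
  d <- vapply(split(tracks, tracks$track_id), apparent_diffusion, numeric(1),
              frame_time = frame_time, min_steps = min_steps)
  d[!is.na(d)]
}

#' Mobility threshold separating bound from mobile molecules
#'
#' The threshold is the lower \code{quantile} (default 5 percent) of D* in a
#' reference sample where MukBEF cannot bind the chromosome (a Delta-mukE
#' strain in the experiments). Without a reference sample the packaged
#' constant 0.0875 um^2/s is returned.
#'
#' @param reference_dstars numeric vector of reference D* values, or NULL.
#' @param probs quantile (default 0.05).
#' @return threshold in um^2/s.
#' @export
bound_threshold <- function(reference_dstars = NULL, probs = 0.05) {
  if (is.null(reference_dstars)) return(0.0875)
  if (!length(reference_dstars)) stop("empty reference sample and no default")
  unname(quantile(reference_dstars, probs))
}

#' Fraction of molecules classified as bound
#'
#' @param dstars numeric vector of apparent diffusion coefficients.
#' @param threshold mobility threshold, um^2/s; values strictly below it are
#'   classified bound.
#' @return fraction in [0, 1].
#' @export
bound_fraction <- function(dstars, threshold = bound_threshold()) {
  if (!length(dstars)) stop("bound fraction undefined for empty input")
  mean(dstars < threshold)
}

#' Filter localizations by elliptical fit widths
#'
#' In long-exposure movies mobile molecules blur into the background; bound
#' molecules produce diffraction-limited spots with a short-axis width below
#' 160 nm and a long-axis width below 200 nm (strict inequalities).
#'
#' @param locs localization table with \code{w_short_nm} and \code{w_long_nm}.
#' @param short_max_nm,long_max_nm width bounds in nm.
#' @return the filtered table.
#' @export
spot_width_filter <- function(locs, short_max_nm = 160, long_max_nm = 200) {
  stopifnot(all(c("w_short_nm", "w_long_nm") %in% names(locs)))
  locs[locs$w_short_nm < short_max_nm & locs$w_long_nm < long_max_nm, , drop = FALSE]
}

# ---- residency -------------------------------------------------------------

# drop tracks whose first frame lies within the final `frac` of the movie:
# their durations would be right-censored by the observation window
drop_late_tracks <- function(tracks, frac = 0.1) {
  if (!nrow(tracks)) return(tracks)
  last <- max(tracks$frame)
  cutoff <- last - ceiling(frac * (last - min(tracks$frame)))
  starts <- vapply(split(tracks$frame, tracks$track_id), min, numeric(1))
  late <- as.integer(names(starts)[starts > cutoff])
  tracks[!tracks$track_id %in% late, , drop = FALSE]
}

#' Empirical survival curve of residency times
#'
#' Right-continuous survival probability \code{S(t) = P(T > t)} evaluated at
#' 0 and at each observed duration.
#'
#' @param durations_s positive durations, seconds.
#' @return data.frame with columns \code{t} and \code{surv};
#'   \code{surv[t = 0] = 1}.
#' @export
residency_survival <- function(durations_s) {
  stopifnot(length(durations_s) > 0L, all(durations_s > 0))
  ts <- sort(unique(durations_s))
  surv <- vapply(ts, function(t) mean(durations_s > t), numeric(1))
  data.frame(t = c(0, ts), surv = c(1, surv))
}

#' Fit a double exponential to a survival curve
#'
#' Least-squares fit of \code{A1 exp(-t/tau_fast) + A2 exp(-t/tau_slow)} with
#' weights \code{1/y} compensating for the small values in the tail, started
#' from a grid of time-constant pairs. The two exponentials correspond to
#' non-specific and specific DNA binding; the specific residency time is
#' \code{tau_slow}. Zero-survival points are excluded (infinite weight). With
#' effectively single-exponential data the fit degenerates to
#' \code{tau_fast == tau_slow} or a vanishing amplitude; both are valid
#' outputs.
#'
#' @param curve data.frame with columns \code{t} and \code{surv} (at least 10
#'   usable points).
#' @param n_starts number of multi-start initializations.
#' @return object of class \code{double_exp_fit}: amplitudes \code{A1}
#'   (fast), \code{A2} (slow), time constants \code{tau_fast},
#'   \code{tau_slow} (s), weighted RSS and fit metadata.
#' @export
fit_double_exponential <- function(curve, n_starts = 12L) {
  d <- curve[curve$surv > 0 & curve$t >= 0, , drop = FALSE]
  if (nrow(d) < 10L) stop("need at least 10 survival points with surv > 0")
  tmax <- max(d$t[d$t > 0])
  # crude single-exponential scale from the curve tail
  tau0 <- tmax / max(-log(min(d$surv)), 1e-6)
  grid <- expand.grid(f = c(0.05, 0.15, 0.5), s = c(1, 2.5, 6, 15))
  starts <- unique(rbind(
    data.frame(tau1 = tau0 * grid$f, tau2 = tau0 * grid$s),
    data.frame(tau1 = tau0, tau2 = tau0 * 2)))
  starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]
  w <- 1 / d$surv
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        surv ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2), data = d,
        start = list(A1 = 0.5, A2 = 0.5,
                     tau1 = starts$tau1[k], tau2 = starts$tau2[k]),
        weights = w,
        lower = c(0, 0, 1e-9, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * (d$surv - predict(fit, d))^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("double-exponential fit failed to converge from all starts (",
         nrow(starts), " initializations, ", nrow(d), " points)")
  p <- coef(best$fit)
  if (p[["tau1"]] <= p[["tau2"]]) {
    out <- list(A1 = p[["A1"]], A2 = p[["A2"]],
                tau_fast = p[["tau1"]], tau_slow = p[["tau2"]])
  } else {
    out <- list(A1 = p[["A2"]], A2 = p[["A1"]],
                tau_fast = p[["tau2"]], tau_slow = p[["tau1"]])
  }
  # component carrying most of the integrated survival mass (A * tau); for
  # effectively single-exponential data the other component is spurious
  out$tau_dominant <- if (out$A1 * out$tau_fast >= out$A2 * out$tau_slow)
    out$tau_fast else out$tau_slow
  structure(c(out, list(rss_weighted = best$rss, n_points = nrow(d),
                        n_starts = nrow(starts))),
            class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<double_exp_fit> A1=%.3f tau_fast=%.2fs | A2=%.3f tau_slow=%.2fs (wRSS %.3g, %d pts)\n",
    x$A1, x$tau_fast, x$A2, x$tau_slow, x$rss_weighted, x$n_points))
  invisible(x)
}

#' Fit a single exponential to a survival curve
#'
#' Weighted (1/y) least-squares fit of \code{A exp(-t/tau)}; appropriate for
#' the bleaching-time survival curve of a fixed (immobilized) sample, which
#' has no binding kinetics.
#'
#' @inheritParams fit_double_exponential
#' @return list with \code{A}, \code{tau} and \code{rss_weighted}.
#' @export
fit_single_exponential <- function(curve) {
  d <- curve[curve$surv > 0 & curve$t >= 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 survival points with surv > 0")
  w <- 1 / d$surv
  tau0 <- max(d$t) / max(-log(min(d$surv)), 1e-6)
  fit <- minpack.lm::nlsLM(surv ~ A * exp(-t / tau), data = d,
                           start = list(A = 1, tau = tau0), weights = w,
                           lower = c(0, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- coef(fit)
  list(A = p[["A"]], tau = p[["tau"]],
       rss_weighted = sum(w * (d$surv - predict(fit, d))^2))
}

#' Effective bleaching time constant from a fixed-sample movie
#'
#' Runs the residency tracking pipeline (width filter, gap-free linking) on a
#' movie of immobilized molecules and fits the survival curve of track
#' durations. The resulting constant absorbs bleaching, blinking and
#' detection losses, and is the correct \code{t_bleach_s} for
#' \code{\link{bleach_correct}} measured under identical imaging conditions.
#'
#' @param locs localization table of the fixed-sample movie.
#' @param frame_time frame interval, seconds.
#' @param model \code{"single"} (clean immobilized sample) or
#'   \code{"double"} (takes the dominant component by integrated mass).
#' @return bleaching time constant, seconds.
#' @export
measure_bleach_time <- function(locs, frame_time = 1,
                                model = c("single", "double")) {
  model <- match.arg(model)
  kept <- spot_width_filter(locs)
  tracks <- link_tracks(kept, max_gap = 0L)
  tracks <- drop_late_tracks(tracks, 0.1)
  curve <- residency_survival(as.numeric(table(tracks$track_id)) * frame_time)
  if (model == "single") fit_single_exponential(curve)$tau
  else fit_double_exponential(curve)$tau_dominant
}

#' Photobleaching correction of a measured residency time
#'
#' A molecule disappears when it unbinds or its fluorophore bleaches,
#' whichever comes first, so the measured time constant underestimates the
#' true one: \code{t_bound = t_measured * t_bleach / (t_bleach - t_measured)}.
#' The measured bleaching time constant for the dye used here was
#' 48.8 +/- 8.3 s.
#'
#' @param t_measured_s measured (apparent) residency time constant, s.
#' @param t_bleach_s bleaching time constant, s; \code{Inf} returns
#'   \code{t_measured_s} unchanged.
#' @return corrected residency time, seconds.
#' @export
bleach_correct <- function(t_measured_s, t_bleach_s = 48.8) {
  stopifnot(t_measured_s > 0, t_bleach_s > 0)
  if (is.infinite(t_bleach_s)) return(t_measured_s)
  if (t_measured_s >= t_bleach_s)
    stop("t_measured >= t_bleach: uncorrectable (correction has a pole)")
  t_measured_s * t_bleach_s / (t_bleach_s - t_measured_s)
}

#' Fraction of fluorescent-protein fusions that are mature
#'
#' With expression at equilibrium, fluorescent molecules represent a fraction
#' \code{1 / (1 + maturation_halftime / generation_time)} of the total
#' abundance (91 percent for mYPet's 11.9 min half-time and a 116 min
#' generation time).
#'
#' @param maturation_halftime_min fluorophore maturation half-time, minutes.
#' @param generation_min cell generation time, minutes.
#' @return mature fraction in (0, 1].
#' @export
mature_fraction <- function(maturation_halftime_min = 11.9, generation_min = 116) {
  stopifnot(generation_min > 0, maturation_halftime_min >= 0)
  1 / (1 + maturation_halftime_min / generation_min)
}

#' Residency-time analysis pipeline for a long-exposure movie
#'
#' Applies the bound-molecule spot-width filter, links tracks with no gaps
#' allowed, measures immobile-track durations (frames times the frame time),
#' fits the double-exponential survival model and bleach-corrects the slow
#' (specific-binding) time constant.
#'
#' Binding events that begin close to the end of the movie are right-censored
#' (the observation window cannot contain them). Excluding events that end at
#' the movie boundary would bias the sample short (long events are the ones
#' censored), so instead all tracks \emph{starting} within the final
#' \code{censor_margin_frac} of the movie are excluded; the remaining tracks
#' are observed over a window much longer than the measured time constants.
#'
#' @param locs localization table of a long-exposure movie.
#' @param frame_time frame interval, seconds (default 1 s).
#' @param t_bleach_s bleaching time constant used for the correction.
#' @param radius_um linking window.
#' @param censor_margin_frac fraction of the movie at its end within which no
#'   new track is accepted for analysis.
#' @return list with \code{durations_s}, \code{curve}, \code{fit},
#'   \code{t_measured_s} (= tau_slow) and \code{t_bound_s}.
#' @export
residency_pipeline <- function(locs, frame_time = 1, t_bleach_s = 48.8,
                               radius_um = 0.48, censor_margin_frac = 0.1) {
  kept <- spot_width_filter(locs)
  tracks <- link_tracks(kept, radius_um = radius_um, max_gap = 0L)
  tracks <- drop_late_tracks(tracks, censor_margin_frac)
  durations <- as.numeric(table(tracks$track_id)) * frame_time
  curve <- residency_survival(durations)
  fit <- fit_double_exponential(curve)
  list(durations_s = durations, curve = curve, fit = fit,
       t_measured_s = fit$tau_slow,
       t_bound_s = bleach_correct(fit$tau_slow, t_bleach_s))
}
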