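# Ground-truthed synthetic data generators: two-population single-molecule
# tracks (with bleaching and blinking), PSF-blurred filament images, and
# hand-specified toy loop states. Every generator is deterministic under its
# seed and returns the ground truth next to the data.

#' Parameters of the synthetic track generator
#'
#' Emulates a tracking experiment on a mixed population: a fraction
#' \code{f_bound} of molecules is chromosome-associated (slow, small
#' \code{D_bound} mimicking residual chromosome motion), the rest diffuses at
#' \code{D_free}. Bound molecules stay for an exponential residency time; a
#' fraction \code{f_specific} of them binds specifically (mean
#' \code{mean_residency_s}), the rest non-specifically (mean
#' \code{nonspecific_residency_s}). Fluorophores bleach with an exponential
#' time constant \code{t_bleach_s} and blink (per-frame missed detection with
#' probability \code{blink_prob}). Localizations carry Gaussian error
#' \code{loc_error_nm} and elliptical fit widths: diffraction-limited for
#' immobile molecules, blurred for mobile ones.
#'
#' @param D_bound,D_free diffusion coefficients, um^2/s.
#' @param f_bound bound fraction.
#' @param mean_residency_s specific-binding mean residency, s.
#' @param nonspecific_residency_s non-specific binding mean residency, s.
#' @param f_specific fraction of binding events that are specific.
#' @param t_bleach_s bleaching time constant, s.
#' @param blink_prob per-frame missed-detection probability (fluorophore
#'   blinking or a failed localization). Defaults to 0.02 in fast mode; in
#'   residency mode 1 s exposures integrate over the sub-millisecond dark
#'   states, so missed frames are rare (default 0.005).
#' @param loc_error_nm 1-D localization error, nm.
#' @param conf_radius_um confinement radius (stationary standard deviation)
#'   of the tethered motion of bound molecules, um. Bound molecules move as
#'   an Ornstein-Uhlenbeck process with short-time diffusion \code{D_bound}
#'   inside this confinement, as chromosomal loci do.
#' @param mode \code{"fast"} (15.48 ms frames, short fluorophore on-time
#'   under high excitation) or \code{"residency"} (1 s frames, the 48.8 s
#'   bleaching constant); sets the defaults of \code{frame_time_s},
#'   \code{t_bleach_s}, \code{n_frames} and \code{n_molecules} unless given
#'   explicitly.
#' @param frame_time_s frame interval, s.
#' @param n_molecules number of molecules.
#' @param n_frames movie length, frames.
#' @param field_um imaging field side length, um.
#' @param seed RNG seed.
#' @return object of class \code{track_sim_params}.
#' @export
track_sim_params <- function(mode = c("fast", "residency"),
                             D_bound = 0.01, D_free = 0.5, f_bound = 0.48,
                             mean_residency_s = 65,
                             nonspecific_residency_s = 3, f_specific = 0.5,
                             t_bleach_s = NULL, blink_prob = NULL,
                             loc_error_nm = 25, conf_radius_um = 0.1,
                             frame_time_s = NULL,
                             n_molecules = NULL, n_frames = NULL,
                             field_um = 40, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(frame_time_s)) frame_time_s <- if (mode == "fast") 0.01548 else 1
  if (is.null(t_bleach_s)) t_bleach_s <- if (mode == "fast") 0.3 else 48.8
  if (is.null(blink_prob)) blink_prob <- if (mode == "fast") 0.02 else 0.005
  if (is.null(n_frames)) n_frames <- if (mode == "fast") 4000L else 3000L
  if (is.null(n_molecules)) n_molecules <- if (mode == "fast") 3000L else 6000L
  stopifnot(f_bound >= 0, f_bound <= 1, f_specific >= 0, f_specific <= 1,
            blink_prob >= 0, blink_prob < 1,
            D_bound >= 0, D_free >= 0, mean_residency_s > 0,
            nonspecific_residency_s > 0, t_bleach_s > 0, frame_time_s > 0,
            conf_radius_um >= 0,
            n_molecules >= 1, n_frames >= 1)
  structure(as.list(environment()), class = "track_sim_params")
}

#' Simulate single-molecule tracking data with ground truth
#'
#' Each molecule is assigned bound/free, activated at a uniformly random
#' frame, followed with Brownian steps at its diffusion coefficient, and
#' disappears at bleaching, unbinding (bound molecules), or the end of the
#' movie. Blinking removes single frames. With \code{fixed = TRUE} all
#' molecules are immobile with infinite residency, emulating a
#' chemically fixed sample used to measure the bleaching-time distribution.
#'
#' @param params a \code{\link{track_sim_params}}.
#' @param fixed logical; simulate a fixed (immobilized) control sample.
#' @return list with \code{locs} (localization table: \code{frame},
#'   \code{x_um}, \code{y_um}, \code{w_short_nm}, \code{w_long_nm},
#'   \code{intensity}, plus the ground-truth \code{mol_id} column that the
#'   analyses ignore) and \code{truth} (per-molecule ground truth).
#' @export
simulate_tracks <- function(params = track_sim_params(), fixed = FALSE) {
  p <- params
  set.seed(p$seed)
  nm <- p$n_molecules
  bound <- if (fixed) rep(TRUE, nm) else runif(nm) < p$f_bound
  specific <- bound & (runif(nm) < p$f_specific)
  residency_s <- rep(Inf, nm)
  if (!fixed) {
    residency_s[bound] <- ifelse(specific[bound],
                                 rexp(sum(bound), 1 / p$mean_residency_s),
                                 rexp(sum(bound), 1 / p$nonspecific_residency_s))
  }
  bleach_s <- rexp(nm, 1 / p$t_bleach_s)
  start <- sample.int(p$n_frames, nm, replace = TRUE)
  D <- ifelse(bound, p$D_bound, p$D_free)
  if (fixed) D <- rep(0, nm)

  visible_s <- pmin(bleach_s, residency_s)
  # a molecule is recorded in the frames it survives entirely
  n_vis <- pmin(pmax(floor(visible_s / p$frame_time_s), 1L),
                p$n_frames - start + 1L)

  sd_step <- sqrt(2 * D * p$frame_time_s)
  sd_loc <- p$loc_error_nm / 1000
  # flat vectors over all (molecule, frame) records
  mol <- rep.int(seq_len(nm), n_vis)
  total <- length(mol)
  frame <- unlist(lapply(seq_len(nm), function(m) start[m]:(start[m] + n_vis[m] - 1L)),
                  use.names = FALSE)
  first <- c(TRUE, mol[-1L] != mol[-total])
  anchor_x <- runif(nm, 0, p$field_um)
  anchor_y <- runif(nm, 0, p$field_um)
  # free molecules: unconfined Brownian walk (cumulative Gaussian steps).
  # bound molecules: tethered motion, an Ornstein-Uhlenbeck process around
  # the binding site with short-time diffusion D_bound and stationary sd
  # conf_radius_um, so fast-exposure steps have variance 2*D_bound*dt while
  # long-exposure positions stay within the confinement radius.
  imm_mol <- bound | fixed
  a_ou <- ifelse(p$conf_radius_um > 0 & D > 0,
                 exp(-D * p$frame_time_s / p$conf_radius_um^2), 0)
  # tethered molecules are sampled at 10 sub-steps per frame and averaged:
  # the camera integrates over the exposure, so the localization is the
  # motion-blurred centroid of the confined trajectory
  sub <- 10L
  walk1 <- function(m) {
    k <- n_vis[m]
    if (imm_mol[m]) {
      if (D[m] <= 0 || p$conf_radius_um <= 0) return(rep(0, k))
      a1 <- exp(-D[m] * p$frame_time_s / sub / p$conf_radius_um^2)
      dev <- rnorm(k * sub, 0,
                   p$conf_radius_um * c(1, rep(sqrt(1 - a1^2), k * sub - 1L)))
      ou <- stats::filter(dev, a1, method = "recursive")
      colMeans(matrix(ou, sub, k))
    } else {
      cumsum(c(0, rnorm(k - 1L, 0, sd_step[m])))
    }
  }
  x <- anchor_x[mol] + unlist(lapply(seq_len(nm), walk1), use.names = FALSE)
  y <- anchor_y[mol] + unlist(lapply(seq_len(nm), walk1), use.names = FALSE)
  keep <- runif(total) >= p$blink_prob
  keep[first] <- TRUE
  imm <- bound[mol] | fixed
  k2 <- sum(keep)
  locs <- data.frame(
    mol_id = mol[keep],
    frame = frame[keep],
    x_um = x[keep] + rnorm(k2, 0, sd_loc),
    y_um = y[keep] + rnorm(k2, 0, sd_loc),
    w_short_nm = pmax(rnorm(k2, ifelse(imm[keep], 130, 230),
                            ifelse(imm[keep], 8, 20)), 50),
    w_long_nm = pmax(rnorm(k2, ifelse(imm[keep], 150, 260),
                           ifelse(imm[keep], 10, 25)), 60),
    intensity = rnorm(k2, 1000, 100))
  locs <- locs[order(locs$frame, locs$mol_id), , drop = FALSE]
  rownames(locs) <- NULL
  truth <- data.frame(mol_id = seq_len(nm), bound = bound, specific = specific,
                      D_true = D, residency_s = residency_s,
                      bleach_s = bleach_s, start_frame = start,
                      n_frames_visible = n_vis)
  list(locs = locs, truth = truth, params = p)
}

#' Specification of a synthetic filament image
#'
#' A line or circle centerline of known length with a Gaussian cross-section
#' of width \code{sigma_nm}, sampled on a pixel grid, plus background and
#' noise. Emulates a projected super-resolution image of an axial core
#' (lengths around 1.0-1.5 um, FWHM around 130 nm).
#'
#' @param shape \code{"line"} or \code{"circle"}.
#' @param centerline_length_um exact centerline length (circumference for a
#'   circle), um.
#' @param sigma_nm Gaussian cross-section standard deviation, nm.
#' @param peak_intensity peak intensity above background, a.u.
#' @param background background level, a.u.
#' @param noise_model \code{"gaussian"}, \code{"poisson"} or \code{"none"}.
#' @param noise_sd Gaussian noise standard deviation, a.u.
#' @param pixel_nm pixel size, nm.
#' @param orientation_deg in-plane rotation of a line, degrees.
#' @param margin_um margin around the shape, um.
#' @param seed RNG seed for the noise.
#' @return object of class \code{filament_spec}.
#' @export
filament_spec <- function(shape = c("line", "circle"),
                          centerline_length_um = 1.0, sigma_nm = 56,
                          peak_intensity = 1000, background = 100,
                          noise_model = c("gaussian", "poisson", "none"),
                          noise_sd = 20, pixel_nm = 40, orientation_deg = 0,
                          margin_um = 0.5, seed = 1L) {
  shape <- match.arg(shape)
  noise_model <- match.arg(noise_model)
  stopifnot(centerline_length_um > 0, sigma_nm > 0, pixel_nm > 0,
            margin_um >= 0, background >= 0)
  structure(as.list(environment()), class = "filament_spec")
}

#' Render a synthetic filament image with ground truth
#'
#' Pixel intensity is \code{background + peak * exp(-d^2 / (2 sigma^2))}
#' where \code{d} is the distance from the pixel center to the parametric
#' centerline, plus noise. Intensities are sampled at pixel centers.
#'
#' @param spec a \code{\link{filament_spec}}.
#' @return list with \code{image} (an \code{\link{image_frame}}) and
#'   \code{truth} (exact centerline length, sigma, shape geometry).
#' @export
render_filament <- function(spec = filament_spec()) {
  s <- spec
  set.seed(s$seed)
  px_um <- s$pixel_nm / 1000
  sigma_px <- s$sigma_nm / s$pixel_nm
  margin_px <- s$margin_um / px_um
  if (s$shape == "line") {
    len_px <- s$centerline_length_um / px_um
    th <- s$orientation_deg * pi / 180
    half <- c(cos(th), sin(th)) * len_px / 2
    extent <- abs(half) + margin_px
    nr <- ceiling(2 * extent[1L]) + 1L
    nc <- ceiling(2 * extent[2L]) + 1L
    c0 <- c((nr + 1) / 2, (nc + 1) / 2)
    a <- c0 - half; b <- c0 + half
    if (any(c(a, b) < 1) || a[1L] > nr || b[1L] > nr || a[2L] > nc || b[2L] > nc)
      stop("shape exceeds the image frame")
    gi <- matrix(seq_len(nr), nr, nc)
    gj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ab <- b - a
    tt <- pmin(pmax(((gi - a[1L]) * ab[1L] + (gj - a[2L]) * ab[2L]) / sum(ab^2), 0), 1)
    d2 <- (gi - (a[1L] + tt * ab[1L]))^2 + (gj - (a[2L] + tt * ab[2L]))^2
    truth_geom <- list(a_px = a, b_px = b)
  } else {
    r_px <- s$centerline_length_um / (2 * pi) / px_um
    sz <- ceiling(2 * (r_px + margin_px)) + 1L
    nr <- nc <- sz
    c0 <- c((nr + 1) / 2, (nc + 1) / 2)
    if (r_px + margin_px > min(nr, nc) / 2 + 1)
      stop("shape exceeds the image frame")
    gi <- matrix(seq_len(nr), nr, nc)
    gj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d2 <- (sqrt((gi - c0[1L])^2 + (gj - c0[2L])^2) - r_px)^2
    truth_geom <- list(center_px = c0, radius_px = r_px)
  }
  img <- s$background + s$peak_intensity * exp(-d2 / (2 * sigma_px^2))
  img <- switch(s$noise_model,
                none = img,
                gaussian = pmax(img + rnorm(length(img), 0, s$noise_sd), 0),
                poisson = matrix(rpois(length(img), img), nrow(img)))
  dim(img) <- c(nr, nc)
  list(image = image_frame(img, s$pixel_nm),
       truth = c(list(shape = s$shape,
                      centerline_length_um = s$centerline_length_um,
                      sigma_nm = s$sigma_nm, fwhm_nm = 2.355 * s$sigma_nm),
                 truth_geom),
       spec = s)
}

#' Write the ground truth of a synthetic dataset as a JSON sidecar
#'
#' @param x result of \code{\link{simulate_tracks}} or
#'   \code{\link{render_filament}} (any list with \code{truth} and parameter
#'   fields).
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  obj <- list(truth = x$truth,
              params = unclass(x$params %||% x$spec))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Hand-specified loop state for exhaustive testing
#'
#' Builds a \code{muk_state}-shaped snapshot from an explicit complex table
#' on a small chromosome, so that loop statistics can be computed by hand or
#' by brute force.
#'
#' @param complexes data.frame with columns \code{left} and \code{right}
#'   (0-based segment indices; the loop span runs from left to right the
#'   "short way" through the anchor, i.e. span = (right - left) mod n + 1).
#' @param n_segments chromosome size, segments.
#' @param segment_bp basepairs per segment.
#' @param matp_active,ter_interval optional ter geometry.
#' @return a \code{muk_state}.
#' @export
toy_loop_state <- function(complexes, n_segments = 20L, segment_bp = 1000L,
                           matp_active = FALSE, ter_interval = c(0L, 1L)) {
  cx <- as.data.frame(complexes)
  stopifnot(all(c("left", "right") %in% names(cx)))
  cx$left <- as.integer(cx$left) %% n_segments
  cx$right <- as.integer(cx$right) %% n_segments
  if (any(cx$left == cx$right)) stop("fixture error: complex with left == right")
  occ <- c(cx$left, cx$right)
  if (anyDuplicated(occ)) stop("fixture error: overlapping dimer placements")
  if (is.null(cx$id)) cx$id <- seq_len(nrow(cx))
  if (is.null(cx$anchor)) cx$anchor <- cx$left
  if (is.null(cx$moving_side)) cx$moving_side <- rep("both", nrow(cx))
  cfg <- chromosome_config(n_segments, segment_bp, circular = TRUE,
                           ter_interval = ter_interval,
                           matp_active = matp_active)
  structure(list(time = 0, config = cfg,
                 params = loop_params(n_total = nrow(cx)),
                 complexes = cx[, c("id", "left", "right", "anchor", "moving_side")],
                 bind_time = rep(0, nrow(cx)),
                 n_free = 0L, next_id = nrow(cx) + 1L,
                 counters = c(binds = 0, unbinds = 0, moves = 0, displacements = 0)),
            class = "muk_state")
}
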