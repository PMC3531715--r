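# Planar multi-segment biomechanics of a body swinging about a fixed bar:
# angular position/velocity, joint angles, centre of gravity, moment of
# inertia about the body CG, and mass-normalised total mechanical energy.

MARKER_NAMES <- c("wrist", "elbow", "shoulder", "hip", "knee", "ankle")

#' Five-segment planar body model
#'
#' Anthropometric description of the digitized gymnast model: body mass and,
#' per segment (forearm, arm, trunk, thigh, shank), the fraction of body mass,
#' the centre-of-gravity position and the radius of gyration about the
#' transverse axis (both as fractions of segment length), and the marker pair
#' spanning the segment. The bilateral limb segments carry doubled mass
#' fractions because one limb stands for both; head and hands/feet mass is
#' folded into the trunk and distal limb segments. Default fractions follow
#' the usual adjusted cadaver-based tables and are configurable via YAML, not
#' hard-coded truth.
#'
#' @param path optional YAML file with fields `body_mass`, `gravity` and a
#'   `segments` map (each entry: `from`, `to`, `mass_fraction`, `cg_fraction`,
#'   `gyration_fraction`, `length`); defaults to the file shipped with the
#'   package.
#' @param body_mass override body mass in kg.
#' @param segments optional data frame (columns `name`, `from`, `to`,
#'   `mass_fraction`, `cg_fraction`, `gyration_fraction`, `length`) used
#'   instead of the YAML segment table, e.g. for reduced test models.
#' @param gravity gravitational acceleration, m/s^2 (used with `segments`).
#' @return An object of class `body_model`: `M` (kg), `g` (m/s^2), and
#'   `segments` (data frame, one row per segment).
#' @export
body_model <- function(path = NULL, body_mass = NULL, segments = NULL,
                       gravity = 9.81) {
  if (!is.null(segments)) {
    cfg <- list(body_mass = body_mass %||% 65, gravity = gravity)
    seg <- as.data.frame(segments)
  } else {
    if (is.null(path))
      path <- system.file("extdata", "body_model.yaml", package = "emgsynergy")
    cfg <- yaml::read_yaml(path)
    seg <- do.call(rbind, lapply(names(cfg$segments), function(nm) {
      s <- cfg$segments[[nm]]
      data.frame(name = nm, from = s$from, to = s$to,
                 mass_fraction = s$mass_fraction, cg_fraction = s$cg_fraction,
                 gyration_fraction = s$gyration_fraction, length = s$length)
    }))
    if (!is.null(body_mass)) cfg$body_mass <- body_mass
  }
  if (abs(sum(seg$mass_fraction) - 1) > 1e-9)
    stop("segment mass fractions must sum to 1", call. = FALSE)
  if (any(seg$mass_fraction <= 0) || any(seg$cg_fraction <= 0) ||
      any(seg$cg_fraction >= 1) || any(seg$gyration_fraction < 0) ||
      any(seg$length <= 0))
    stop("segment fractions must lie in (0, 1), gyration fractions be non-negative and lengths be positive",
         call. = FALSE)
  structure(list(M = cfg$body_mass, g = cfg$gravity %||% 9.81,
                 segments = seg),
            class = "body_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> M=%g kg, g=%g m/s^2, %d segments\n",
              x$M, x$g, nrow(x$segments)))
  invisible(x)
}

marker_xy <- function(markers, name) {
  cols <- paste0(name, c("_x", "_y"))
  if (!all(cols %in% names(markers)))
    stop(sprintf("marker '%s' missing from trajectories", name), call. = FALSE)
  as.matrix(markers[, cols])
}

# Central finite difference with one-sided ends; x may be a vector or a
# 2-column matrix. Returns the derivative at the sampling rate fs.
central_diff <- function(x, fs) {
  if (is.matrix(x)) {
    d <- apply(x, 2L, central_diff, fs = fs)
    if (!is.matrix(d)) d <- matrix(d, nrow = 1L)  # single-frame input
    return(d)
  }
  n <- length(x)
  if (n == 1L) return(0)
  if (n == 2L) return(rep((x[2L] - x[1L]) * fs, 2L))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# Unwrap a sequence of angles in radians.
unwrap_rad <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

#' Low-pass smooth marker trajectories
#'
#' Zero-phase Butterworth low-pass (default 5 Hz, 4th order) applied to every
#' coordinate column, the standard treatment of digitized positions before
#' differentiation.
#'
#' @param markers data frame of marker trajectories (coordinate columns end in
#'   `_x` / `_y`).
#' @param fs frame rate in Hz.
#' @param cutoff,order filter parameters.
#' @return The smoothed data frame.
#' @export
smooth_positions <- function(markers, fs, cutoff = 5, order = 4) {
  if (!(cutoff > 0 && cutoff < fs / 2))
    stop("cutoff must lie in (0, fs/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad_n <- round(3 * fs / cutoff)
  coord <- grep("_(x|y)$", names(markers), value = TRUE)
  for (cl in coord)
    markers[[cl]] <- filtfilt_reflect(bf, markers[[cl]], pad_n)
  markers
}

#' Angular position of the body around the bar
#'
#' The angle between the bar-to-hip axis and the downward vertical, in
#' degrees, increasing in the direction of rotation (auto-detected from the
#' net rotation unless `direction` is supplied). Returned both unwrapped
#' (cumulative, for differentiation) and wrapped to `[0, 360)` per cycle.
#'
#' @param hip_xy two-column matrix (or data frame) of hip marker positions.
#' @param bar_xy bar position, default the origin.
#' @param direction `+1`/`-1` to force the rotation sense, `NULL` to detect.
#' @return A list: `theta` (wrapped, deg), `theta_unwrapped` (deg),
#'   `direction`.
#' @export
angular_position <- function(hip_xy, bar_xy = c(0, 0), direction = NULL) {
  hip_xy <- as.matrix(hip_xy)
  rel <- sweep(hip_xy, 2L, bar_xy)
  rad <- sqrt(rowSums(rel^2))
  if (any(rad < 1e-9))
    stop("hip marker coincides with the bar", call. = FALSE)
  raw <- atan2(rel[, 1L], -rel[, 2L])  # 0 at vertical below the bar
  un <- unwrap_rad(raw)
  if (is.null(direction))
    direction <- if (un[length(un)] >= un[1L]) 1 else -1
  un <- un * direction
  list(theta = (un * 180 / pi) %% 360,
       theta_unwrapped = un * 180 / pi,
       direction = direction)
}

#' Shoulder and hip joint angles
#'
#' Interior angles of the digitized model, in degrees: shoulder between the
#' trunk (shoulder to hip) and upper arm (shoulder to elbow) vectors; hip
#' between the trunk (hip to shoulder) and thigh (hip to knee) vectors. 180
#' degrees means segments aligned; flexion decreases the angle.
#'
#' @param markers data frame with elbow, shoulder, hip and knee marker
#'   columns.
#' @return A list of numeric vectors `shoulder` and `hip` (degrees).
#' @export
joint_angles <- function(markers) {
  interior <- function(v1, v2) {
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    if (any(n1 < 1e-9) || any(n2 < 1e-9))
      stop("degenerate (zero-length) segment", call. = FALSE)
    cosang <- rowSums(v1 * v2) / (n1 * n2)
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  sh <- marker_xy(markers, "shoulder"); el <- marker_xy(markers, "elbow")
  hp <- marker_xy(markers, "hip"); kn <- marker_xy(markers, "knee")
  list(shoulder = interior(hp - sh, el - sh),
       hip = interior(sh - hp, kn - hp))
}

#' Angular velocity of the body
#'
#' Central finite difference of the unwrapped angular position, in deg/s.
#'
#' @param theta_unwrapped unwrapped angular position in degrees (from
#'   [angular_position]).
#' @param fs frame rate in Hz.
#' @return A numeric vector, deg/s (one-sided differences at the ends).
#' @export
angular_velocity <- function(theta_unwrapped, fs) {
  if (length(theta_unwrapped) < 3L)
    stop("need at least 3 frames", call. = FALSE)
  central_diff(theta_unwrapped, fs)
}

#' Segment and whole-body centres of gravity and their kinematics
#'
#' Places each segment's CG at its model fraction along the marker-to-marker
#' line, combines them into the whole-body CG by mass-fraction weighting, and
#' differentiates (central differences) to obtain segment linear velocities
#' and angular velocities (from each segment's unwrapped orientation angle).
#' Heights are relative to the bar (y = 0 at bar level).
#'
#' @param markers data frame of marker trajectories.
#' @param model a [body_model].
#' @param fs frame rate in Hz.
#' @return A list: `cg` (n x 2 whole-body CG), and `segments` — per segment a
#'   list with `cg` (n x 2), `v` (speed m/s), `omega` (rad/s), `h` (m),
#'   `length` (m per frame).
#' @export
body_cg <- function(markers, model, fs) {
  stopifnot(inherits(model, "body_model"))
  segs <- model$segments
  out <- list()
  n <- nrow(markers)
  cg_total <- matrix(0, n, 2L)
  for (i in seq_len(nrow(segs))) {
    a <- marker_xy(markers, segs$from[i])
    b <- marker_xy(markers, segs$to[i])
    d <- b - a
    len <- sqrt(rowSums(d^2))
    if (any(len < 1e-9)) stop("degenerate (zero-length) segment", call. = FALSE)
    cg_i <- a + segs$cg_fraction[i] * d
    vel <- central_diff(cg_i, fs)
    ang <- unwrap_rad(atan2(d[, 2L], d[, 1L]))
    out[[segs$name[i]]] <- list(cg = cg_i,
                                v = sqrt(rowSums(vel^2)),
                                omega = central_diff(ang, fs),
                                h = cg_i[, 2L],
                                length = len)
    cg_total <- cg_total + segs$mass_fraction[i] * cg_i
  }
  list(cg = cg_total, segments = out)
}

#' Moment of inertia about the whole-body centre of gravity
#'
#' Per frame, sums over segments the segment's own moment of inertia
#' `I_i = (M m_i) (l_i r_i)^2` (with `l_i` the instantaneous marker-to-marker
#' length and `r_i` the radius-of-gyration fraction) plus the parallel-axis
#' term `(M m_i) d_i^2`, `d_i` being the distance from the segment CG to the
#' whole-body CG.
#'
#' @inheritParams body_cg
#' @return A numeric vector of `I_G` in kg m^2, one value per frame.
#' @export
moment_of_inertia <- function(markers, model, fs) {
  bc <- body_cg(markers, model, fs)
  segs <- model$segments
  IG <- numeric(nrow(markers))
  for (i in seq_len(nrow(segs))) {
    s <- bc$segments[[segs$name[i]]]
    mi <- model$M * segs$mass_fraction[i]
    I_i <- mi * (s$length * segs$gyration_fraction[i])^2
    d2 <- rowSums((s$cg - bc$cg)^2)
    IG <- IG + I_i + mi * d2
  }
  IG
}

#' Mass-normalised total mechanical energy
#'
#' Per frame, sums over segments the translational kinetic energy of the
#' segment CG, the rotational kinetic energy about the segment CG and the
#' gravitational potential energy (heights relative to the bar), then divides
#' by body mass. Only energy differences are physically meaningful; the
#' potential reference is the bar level.
#'
#' @inheritParams body_cg
#' @return A numeric vector of `E_Tot` in J/kg, one value per frame (the
#'   first and last frames use one-sided velocity estimates).
#' @export
total_energy <- function(markers, model, fs) {
  bc <- body_cg(markers, model, fs)
  segs <- model$segments
  E <- numeric(nrow(markers))
  for (i in seq_len(nrow(segs))) {
    s <- bc$segments[[segs$name[i]]]
    mi <- model$M * segs$mass_fraction[i]
    I_i <- mi * (s$length * segs$gyration_fraction[i])^2
    E <- E + 0.5 * mi * s$v^2 + 0.5 * I_i * s$omega^2 + mi * model$g * s$h
  }
  E / model$M
}

#' Full kinematic and dynamic profile of a swing record
#'
#' Convenience wrapper computing the angular position and velocity, joint
#' angles, whole-body CG, moment of inertia and mass-normalised energy of a
#' marker record in one pass.
#'
#' @inheritParams body_cg
#' @param smooth apply [smooth_positions] first.
#' @param cutoff,order smoothing parameters.
#' @return An object of class `swing_kinematics` with elements `theta`,
#'   `theta_unwrapped`, `omega_G`, `shoulder`, `hip`, `cg`, `I_G`, `E_Tot`,
#'   `time_s`, `fs`.
#' @export
swing_kinematics <- function(markers, model, fs, smooth = FALSE, cutoff = 5,
                             order = 4) {
  if (smooth) markers <- smooth_positions(markers, fs, cutoff, order)
  ap <- angular_position(marker_xy(markers, "hip"))
  ja <- joint_angles(markers)
  bc <- body_cg(markers, model, fs)
  structure(list(theta = ap$theta, theta_unwrapped = ap$theta_unwrapped,
                 omega_G = angular_velocity(ap$theta_unwrapped, fs),
                 shoulder = ja$shoulder, hip = ja$hip, cg = bc$cg,
                 I_G = moment_of_inertia(markers, model, fs),
                 E_Tot = total_energy(markers, model, fs),
                 time_s = if ("time_s" %in% names(markers)) markers$time_s
                          else (seq_len(nrow(markers)) - 1L) / fs,
                 fs = fs),
            class = "swing_kinematics")
}

#' @export
print.swing_kinematics <- function(x, ...) {
  cat(sprintf("<swing_kinematics> %d frames @ %g Hz, %.1f rotations\n",
              length(x$theta), x$fs,
              (x$theta_unwrapped[length(x$theta_unwrapped)] -
               x$theta_unwrapped[1L]) / 360))
  invisible(x)
}

#' Re-index a cyclic profile from time to angular position
#'
#' Interpolates a time-indexed variable onto a regular angular grid
#' (0 to 360 degrees) within each full rotation, then averages across cycles.
#' Useful for presenting profiles as a function of body position angle.
#'
#' @param theta_unwrapped unwrapped angular position, degrees.
#' @param x variable sampled at the same frames.
#' @param n_points grid size over one rotation (default 200).
#' @return A list: `angle` (grid, deg), `mean` (cycle-averaged profile),
#'   `cycles` (matrix, one row per complete rotation).
#' @export
profile_by_angle <- function(theta_unwrapped, x, n_points = 200) {
  th0 <- theta_unwrapped - theta_unwrapped[1L]
  n_cyc <- floor(th0[length(th0)] / 360)
  if (n_cyc < 1L) stop("need at least one complete rotation", call. = FALSE)
  grid <- seq(0, 360, length.out = n_points + 1L)[seq_len(n_points)]
  rows <- t(vapply(seq_len(n_cyc), function(ci) {
    approx(th0, x, xout = grid + (ci - 1L) * 360)$y
  }, numeric(n_points)))
  list(angle = grid, mean = colMeans(rows), cycles = rows)
}
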