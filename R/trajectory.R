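#' Echo train description
#'
#' An arithmetic sequence of echo times for a multi-echo readout.
#'
#' @param te_first First echo time in ms. Must be positive.
#' @param delta_te Echo spacing in ms. Must be positive.
#' @param n_echoes Number of echoes (>= 1).
#' @return An object of class `echo_train` with fields `te_first`,
#'   `delta_te` and `n_echoes`.
#' @examples
#' tr <- echo_train(2.37, 1.88, 35)
#' echo_times(tr)[1:3]
#' @export
echo_train <- function(te_first, delta_te, n_echoes) {
  stopifnot(is.numeric(te_first), length(te_first) == 1L, te_first > 0)
  stopifnot(is.numeric(delta_te), length(delta_te) == 1L, delta_te > 0)
  n_echoes <- as.integer(n_echoes)
  stopifnot(length(n_echoes) == 1L, n_echoes >= 1L)
  structure(
    list(te_first = te_first, delta_te = delta_te, n_echoes = n_echoes),
    class = "echo_train"
  )
}

#' Echo times of an echo train
#'
#' @param train An [echo_train()] object.
#' @return Numeric vector of echo times in ms, strictly increasing.
#' @export
echo_times <- function(train) {
  stopifnot(inherits(train, "echo_train"))
  train$te_first + (seq_len(train$n_echoes) - 1) * train$delta_te
}

#' Spoke angle of the blip-gradient multi-echo radial scheme
#'
#' Radial spokes from all shots (excitations) and all echoes of one frame
#' are distributed uniformly over the full circle: the spoke for shot `l`
#' and echo `m` has angle `2*pi/(n_echoes*n_shots) * ((l-1)*n_echoes + m-1)`,
#' i.e. consecutive echoes within a shot advance by one elementary increment
#' (the blip gradient rotates the readout between echoes) and consecutive
#' shots advance by `n_echoes` increments.
#'
#' @param l Shot (TR) index, 1-based.
#' @param m Echo index, 1-based.
#' @param n_shots Number of shots per frame.
#' @param n_echoes Number of echoes per shot.
#' @return Angle in radians in `[0, 2*pi)`. Vectorized over `l` and `m`.
#' @export
spoke_angle <- function(l, m, n_shots, n_echoes) {
  n_shots <- as.integer(n_shots); n_echoes <- as.integer(n_echoes)
  stopifnot(n_shots >= 1L, n_echoes >= 1L)
  if (any(l < 1L | l > n_shots)) stop("shot index out of range [1, n_shots]")
  if (any(m < 1L | m > n_echoes)) stop("echo index out of range [1, n_echoes]")
  2 * pi / (n_echoes * n_shots) * ((l - 1) * n_echoes + (m - 1))
}

#' Small-golden-angle frame rotation
#'
#' Consecutive k-space frames are rotated against each other by the
#' second-order golden angle 180/phi^2 (about 68.75 degrees), giving
#' near-uniform incremental coverage when frames are combined.
#'
#' @param frame Frame index, 0-based; frame 0 has no rotation.
#' @return Offset angle in degrees in `[0, 360)`. Vectorized.
#' @export
frame_angle_offset <- function(frame) {
  stopifnot(all(frame >= 0))
  phi <- (1 + sqrt(5)) / 2
  (frame * 180 / phi^2) %% 360
}

#' Build a multi-echo radial trajectory
#'
#' Generates spoke angles and explicit k-space sample coordinates for the
#' blip-gradient multi-echo radial FLASH scheme. Each spoke is a full
#' diameter with `samples_per_spoke` samples; sample `i` (1-based) sits at
#' radius `i - 1 - samples_per_spoke/2` cycles/FOV along the spoke
#' direction, so the centre sample (index `samples_per_spoke/2 + 1`) is
#' exactly at k = 0. Coordinates are in cycles/FOV, range `[-N/2, N/2)`
#' with `N = samples_per_spoke`.
#'
#' @param n_shots Shots (TRs) per frame.
#' @param n_echoes Echoes per shot.
#' @param samples_per_spoke Readout samples per spoke (even).
#' @param n_frames Number of frames (consecutive frames get the
#'   small-golden-angle offset); default 1.
#' @return An object of class `radial_trajectory`: list with `n_shots`,
#'   `n_echoes`, `samples_per_spoke`, `n_frames`, `angles` (array
#'   shot x echo x frame, radians), `frame_offsets` (degrees) and `coords`,
#'   a list indexed by echo; `coords[[m]]` is a `(n_shots*n_frames) x
#'   samples_per_spoke x 2` array of (kx, ky) in cycles/FOV.
#' @export
build_trajectory <- function(n_shots, n_echoes, samples_per_spoke, n_frames = 1L) {
  n_shots <- as.integer(n_shots); n_echoes <- as.integer(n_echoes)
  samples_per_spoke <- as.integer(samples_per_spoke)
  n_frames <- as.integer(n_frames)
  stopifnot(n_shots >= 1L, n_echoes >= 1L, samples_per_spoke >= 1L, n_frames >= 1L)
  if (samples_per_spoke %% 2L != 0L)
    stop("samples_per_spoke must be even (centre sample at index N/2 + 1)")

  offs <- frame_angle_offset(seq_len(n_frames) - 1L) * pi / 180
  base <- outer(seq_len(n_shots), seq_len(n_echoes),
                function(l, m) spoke_angle(l, m, n_shots, n_echoes))
  angles <- array(0, dim = c(n_shots, n_echoes, n_frames))
  for (f in seq_len(n_frames)) angles[, , f] <- (base + offs[f]) %% (2 * pi)

  radius <- seq_len(samples_per_spoke) - 1L - samples_per_spoke %/% 2L
  coords <- vector("list", n_echoes)
  for (m in seq_len(n_echoes)) {
    th <- as.vector(angles[, m, ])               # shots fastest, then frames
    cs <- cos(th); sn <- sin(th)
    kx <- outer(cs, radius)                      # spoke x sample
    ky <- outer(sn, radius)
    coords[[m]] <- array(c(kx, ky), dim = c(length(th), samples_per_spoke, 2L))
  }

  structure(
    list(n_shots = n_shots, n_echoes = n_echoes,
         samples_per_spoke = samples_per_spoke, n_frames = n_frames,
         angles = angles, frame_offsets = frame_angle_offset(seq_len(n_frames) - 1L),
         coords = coords),
    class = "radial_trajectory"
  )
}

#' Flat coordinate table of a trajectory
#'
#' @param traj A [build_trajectory()] object.
#' @return data.frame with columns echo, spoke, sample, kx, ky (cycles/FOV).
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  S <- traj$samples_per_spoke
  out <- lapply(seq_len(traj$n_echoes), function(m) {
    co <- traj$coords[[m]]
    ns <- dim(co)[1]
    data.frame(
      echo = m,
      spoke = rep(seq_len(ns), times = S),
      sample = rep(seq_len(S), each = ns),
      kx = as.vector(co[, , 1]),
      ky = as.vector(co[, , 2])
    )
  })
  do.call(rbind, out)
}

#' Write a trajectory as a plain-text table
#'
#' @param traj A [build_trajectory()] object.
#' @param path Output file path (tab-separated text).
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(trajectory_table(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Nominal in-plane resolution of an acquisition
#'
#' @param fov_mm Field of view in mm.
#' @param matrix_size Acquisition matrix size (pixels).
#' @return Nominal pixel size in mm (`fov_mm / matrix_size`).
#' @export
nominal_resolution <- function(fov_mm, matrix_size) {
  stopifnot(fov_mm > 0, matrix_size >= 1)
  fov_mm / matrix_size
}
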