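# Trajectories: jittered synthetic ensembles, subsampling and averaging.
#
# A trajectory stores a shared topology (a StructureModel) plus an
# n_atoms x 3 x n_frames coordinate array and per-frame timestamps (ps).

#' Trajectory constructor
#'
#' @param topology StructureModel supplying atom naming
#' @param coords numeric array n_atoms x 3 x n_frames
#' @param timestamps ps, strictly increasing, one per frame
#' @return object of class \code{imclip_trajectory}
#' @export
trajectory <- function(topology, coords, timestamps) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("coordinate array does not match the topology atom count")
  if (dim(coords)[3] != length(timestamps))
    stop("one timestamp per frame required")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(topology = topology, coords = coords,
                 timestamps = timestamps),
            class = "imclip_trajectory")
}

#' @export
print.imclip_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              n_frames(x), dim(x$coords)[1],
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj \code{imclip_trajectory}
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a StructureModel
#' @param traj \code{imclip_trajectory}
#' @param i frame index
#' @export
frame_model <- function(traj, i) {
  m <- traj$topology
  m$atoms$x <- traj$coords[, 1, i]
  m$atoms$y <- traj$coords[, 2, i]
  m$atoms$z <- traj$coords[, 3, i]
  m
}

#' Generate a jittered synthetic trajectory
#'
#' Frames are independent isotropic Gaussian per-atom displacements of the
#' reference coordinates (standard deviation \code{amplitude} per
#' Cartesian component); frame k is timestamped k * timestep, so
#' \code{n_frames} frames span \code{n_frames * timestep} ps.
#'
#' @param model reference StructureModel
#' @param n_frames number of frames (>= 1)
#' @param amplitude per-component jitter standard deviation, A (>= 0)
#' @param timestep frame spacing, ps
#' @param seed integer seed
#' @return \code{\link{trajectory}}
#' @export
perturb_trajectory <- function(model, n_frames, amplitude = 0.3,
                               timestep = 100, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (amplitude < 0) stop("amplitude must be >= 0")
  set.seed(as.integer(seed))
  ref <- as.matrix(model$atoms[, c("x", "y", "z")])
  na <- nrow(ref)
  coords <- array(rep(ref, n_frames), dim = c(na, 3, n_frames))
  if (amplitude > 0)
    coords <- coords + array(stats::rnorm(na * 3 * n_frames, sd = amplitude),
                             dim = c(na, 3, n_frames))
  trajectory(model, coords, timestamps = seq_len(n_frames) * timestep)
}

#' Subsample a trajectory on a fixed time stride
#'
#' Keeps the frames at t = k * stride, k = 1, 2, ... (t = 0 excluded), so
#' a 1 us trajectory at a 100 ps stride yields exactly 10 000 snapshots.
#'
#' @param traj \code{imclip_trajectory}
#' @param stride ps; must be a multiple of the native frame spacing
#' @return subsampled \code{imclip_trajectory}
#' @export
subsample <- function(traj, stride) {
  if (stride <= 0) stop("stride must be positive")
  native <- min(diff(c(0, traj$timestamps)))
  if (stride < native - 1e-9)
    stop("stride is smaller than the native frame spacing (", native, " ps)")
  total <- max(traj$timestamps)
  wanted <- seq(stride, total, by = stride)
  keep <- match(wanted, traj$timestamps)
  if (anyNA(keep))
    stop("stride does not divide into the timestamp grid")
  trajectory(traj$topology, traj$coords[, , keep, drop = FALSE],
             traj$timestamps[keep])
}

#' Average structure of a trajectory
#'
#' Superposes every frame onto the first by least squares on all atoms
#' (via \code{bio3d::fit.xyz}) and returns the coordinate mean as a
#' StructureModel.
#'
#' @param traj \code{imclip_trajectory} with >= 2 frames
#' @return StructureModel of the averaged coordinates
#' @export
average_structure <- function(traj) {
  nf <- n_frames(traj)
  if (nf < 2) stop("averaging needs at least 2 frames")
  na <- dim(traj$coords)[1]
  flat <- t(vapply(seq_len(nf), function(i) as.vector(t(traj$coords[, , i])),
                   numeric(3 * na)))
  fitted <- bio3d::fit.xyz(fixed = flat[1, ], mobile = flat,
                           fixed.inds = seq_len(3 * na),
                           mobile.inds = seq_len(3 * na))
  avg <- colMeans(fitted)
  m <- traj$topology
  xyz <- matrix(avg, ncol = 3, byrow = TRUE)
  m$atoms$x <- xyz[, 1]
  m$atoms$y <- xyz[, 2]
  m$atoms$z <- xyz[, 3]
  m
}
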