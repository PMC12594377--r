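#' Derive joint-center velocity from position
#'
#' Backward finite differences with the first frame's velocity set to zero:
#' \code{v[1, ] = 0}, \code{v[t, ] = p[t, ] - p[t-1, ]} (optionally scaled by
#' the sampling rate to physical units per second).
#'
#' @param p Numeric matrix of positions, frames in rows, channels in columns.
#' @param scale_by_rate Multiply differences by \code{sampling_rate}. The
#'   default keeps raw first differences; the downstream encoders are
#'   scale-equivariant through batch normalization.
#' @param sampling_rate Frames per second (used when \code{scale_by_rate}).
#' @return Matrix of velocities, same shape as \code{p}.
#' @export
derive_velocity <- function(p, scale_by_rate = FALSE, sampling_rate = 100) {
  p <- as.matrix(p)
  if (nrow(p) < 2) stop("need at least 2 frames to derive velocity")
  if (anyNA(p) || any(!is.finite(p))) stop("positions contain NA or non-finite values")
  v <- p - p[c(1L, seq_len(nrow(p) - 1L)), , drop = FALSE]
  v[1L, ] <- 0
  if (scale_by_rate) v <- v * sampling_rate
  v
}

#' Derive joint-center acceleration from velocity
#'
#' Backward finite differences of the velocity with the edge-handling rule
#' that the first two and the last acceleration frames are zero:
#' \code{a[1, ] = a[2, ] = a[T, ] = 0}.
#'
#' @param v Numeric matrix of velocities, frames in rows.
#' @inheritParams derive_velocity
#' @return Matrix of accelerations, same shape as \code{v}.
#' @export
derive_acceleration <- function(v, scale_by_rate = FALSE, sampling_rate = 100) {
  v <- as.matrix(v)
  Tn <- nrow(v)
  if (Tn < 3) stop("need at least 3 frames to derive acceleration")
  if (anyNA(v) || any(!is.finite(v))) stop("velocities contain NA or non-finite values")
  a <- v - v[c(1L, seq_len(Tn - 1L)), , drop = FALSE]
  a[c(1L, 2L, Tn), ] <- 0
  if (scale_by_rate) a <- a * sampling_rate
  a
}

#' Augment joint-center positions with velocity and acceleration
#'
#' Expands 2-D joint-center positions into the three kinematic modalities
#' the student model consumes: position, velocity and acceleration, the
#' derivatives obtained by finite differencing with zeroed edge frames.
#'
#' @param p Numeric matrix of positions, frames in rows (a whole trial or a
#'   single window).
#' @inheritParams derive_velocity
#' @return Object of class \code{augmented_kinematics}: a list with
#'   \code{positions}, \code{velocities}, \code{accelerations} and
#'   \code{sampling_rate}.
#' @export
augment <- function(p, scale_by_rate = FALSE, sampling_rate = 100) {
  p <- as.matrix(p)
  if (nrow(p) < 3) stop("need at least 3 frames to augment kinematics")
  v <- derive_velocity(p, scale_by_rate, sampling_rate)
  a <- derive_acceleration(v, scale_by_rate, sampling_rate)
  structure(list(positions = p, velocities = v, accelerations = a,
                 sampling_rate = sampling_rate),
            class = "augmented_kinematics")
}
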