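# Normalized activation profiles and distance/similarity matrices.

#' Min-max normalize trajectories into activation profiles
#'
#' Each tracked species' time-course is independently rescaled to the
#' range `[0, 1]`, so that profile comparison reflects the shape of the
#' activation pattern and not its amplitude. Rows whose dynamic range
#' falls below a degeneracy threshold (`1e-12 * max(1, max)`) are set to
#' all-zero and flagged, so the profile count stays stable across
#' stimulus levels.
#'
#' @param traj a `trajectory_set`.
#' @param tracked_ids species ids to include (rows of the profile matrix).
#' @return a list of class `"profile_matrix"`: `X` (N x T matrix, rows in
#'   `[0,1]`), `protein_ids`, `stimulus_level`, `degenerate` (logical
#'   vector).
#' @export
normalize_profiles <- function(traj, tracked_ids) {
  if (!length(tracked_ids)) stop("domain error: empty tracked set")
  missing <- setdiff(tracked_ids, rownames(traj$amounts))
  if (length(missing))
    stop("lookup error: unknown tracked species ",
         paste(missing, collapse = ", "))
  raw <- traj$amounts[tracked_ids, , drop = FALSE]
  if (ncol(raw) < 2) stop("domain error: need at least 2 time samples")
  lo <- apply(raw, 1, min); hi <- apply(raw, 1, max)
  rng <- hi - lo
  degenerate <- rng < 1e-12 * pmax(1, hi)
  X <- (raw - lo) / ifelse(degenerate, 1, rng)
  X[degenerate, ] <- 0
  structure(list(X = X, protein_ids = tracked_ids,
                 stimulus_level = traj$stimulus_level,
                 degenerate = stats::setNames(degenerate, tracked_ids)),
            class = "profile_matrix")
}

#' Pairwise Euclidean distances between activation profiles
#'
#' @param profiles a `profile_matrix`.
#' @return symmetric N x N matrix of Euclidean distances, zero diagonal.
#' @export
pairwise_distances <- function(profiles) {
  D <- as.matrix(stats::dist(profiles$X, method = "euclidean"))
  dimnames(D) <- list(profiles$protein_ids, profiles$protein_ids)
  D
}

#' Exponential similarity from a distance matrix
#'
#' Transforms distances to similarities `A_ij = exp(-D_ij / sigma)` with
#' zero diagonal. `sigma` is the "radius of influence"; with
#' `sigma = "auto"` it is set to the average interpoint distance (the mean
#' of the off-diagonal upper triangle of `D`).
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param sigma `"auto"` or a positive number.
#' @return a similarity matrix with attribute `"sigma"`.
#' @export
similarity_from_distances <- function(D, sigma = "auto") {
  if (identical(sigma, "auto")) {
    sigma <- mean(D[upper.tri(D)])
    if (!is.finite(sigma) || sigma <= 0)
      stop("degenerate-sigma error: average interpoint distance is 0")
  }
  if (sigma <= 0) stop("domain error: sigma must be > 0")
  A <- exp(-D / sigma)
  diag(A) <- 0
  attr(A, "sigma") <- sigma
  A
}

#' Profile matrix for one stimulus level, end to end
#'
#' Convenience wrapper: simulate (or take) one trajectory set and build
#' the similarity matrix used by the dominant-sets clustering.
#'
#' @param traj a `trajectory_set`.
#' @param tracked_ids species ids to include.
#' @param sigma see [similarity_from_distances()].
#' @return list with `profiles`, `D`, `A`.
#' @export
profile_similarity <- function(traj, tracked_ids, sigma = "auto") {
  profiles <- normalize_profiles(traj, tracked_ids)
  D <- pairwise_distances(profiles)
  A <- similarity_from_distances(D, sigma)
  list(profiles = profiles, D = D, A = A)
}
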