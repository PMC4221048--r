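# Stimulus-encoding output parameters and k-nearest-neighbour mutual
# information (Kraskov-Stoegbauer-Grassberger estimator, variant 1).

FEATURE_NAMES <- c("auc_out", "auc_out_i", "maxrate_out", "maxrate_timing",
                   "maxrate_out_i", "maxrate_timing_i", "auc_sum",
                   "maxrate_or", "min_timing_or")

#' Extract the nine stimulus-encoding output parameters
#'
#' From the raw (unnormalized) trajectories of the two output species
#' (surface and internalized readout): area under the curve by the
#' trapezoid rule over the full run; maximum activation rate as the
#' largest forward difference on the sampling grid; its timing (earliest
#' grid time on ties); plus the combined parameters
#' `auc_sum = auc_out + auc_out_i`,
#' `maxrate_or = max(maxrate_out, maxrate_out_i)` and
#' `min_timing_or = min` of the two timings.
#'
#' @param traj a `trajectory_set`.
#' @param output_ids character pair: surface output id first, internalized
#'   second. A single id is accepted (the second channel is then zero).
#' @return named numeric vector of the nine parameters (units:
#'   molecules*min for AUCs, molecules/min for rates, min for timings).
#' @export
extract_features <- function(traj, output_ids) {
  missing <- setdiff(output_ids, rownames(traj$amounts))
  if (length(missing))
    stop("lookup error: unknown output species ",
         paste(missing, collapse = ", "))
  times <- traj$grid$times
  chan <- function(id) {
    if (is.na(id)) return(list(auc = 0, maxrate = 0, timing = 0))
    y <- traj$amounts[id, ]
    auc <- pracma::trapz(times, y)
    r <- diff(y) / diff(times)
    i <- which.max(r)  # earliest max on ties
    list(auc = auc, maxrate = max(r),
         timing = if (all(y == 0)) 0 else times[i])
  }
  ids <- c(output_ids, NA)[1:2]
  s <- chan(ids[1]); ii <- chan(ids[2])
  c(auc_out = s$auc, auc_out_i = ii$auc,
    maxrate_out = s$maxrate, maxrate_timing = s$timing,
    maxrate_out_i = ii$maxrate, maxrate_timing_i = ii$timing,
    auc_sum = s$auc + ii$auc,
    maxrate_or = max(s$maxrate, ii$maxrate),
    min_timing_or = min(s$timing, ii$timing))
}

#' Feature table over a batch of simulations
#'
#' @param batch a `batch_result`.
#' @param output_ids passed to [extract_features()].
#' @return data.frame with `stimulus_level` plus the nine parameter
#'   columns, one row per simulation.
#' @export
feature_table <- function(batch, output_ids) {
  feats <- t(vapply(batch$trajectories, extract_features,
                    numeric(length(FEATURE_NAMES)), output_ids = output_ids))
  out <- data.frame(stimulus_level = batch$stimulus_levels, feats)
  stopifnot(!anyNA(out))
  out
}

#' kNN mutual information (KSG variant 1)
#'
#' The Kraskov-Stoegbauer-Grassberger estimator with max-norm
#' neighbourhoods in the joint space:
#' `MI = psi(k) + psi(n) - < psi(n_x + 1) + psi(n_y + 1) >`, where
#' `n_x(i)` counts samples with `|x_j - x_i|` strictly less than the
#' distance to the k-th joint-space neighbour of i. Natural log (nats).
#' A deterministic, seeded jitter of scale `1e-10 * SD` is added to each
#' margin to break ties (the estimator assumes continuous marginals);
#' the estimate is clipped below at zero.
#'
#' @param x,y numeric samples of equal length n > k.
#' @param k neighbour count (default 5).
#' @param jitter_seed seed for the tie-breaking jitter (default 1).
#' @return mutual information in nats (non-negative scalar).
#' @export
knn_mutual_information <- function(x, y, k = 5, jitter_seed = 1) {
  n <- length(x)
  if (length(y) != n) stop("domain error: x and y differ in length")
  if (k < 1) stop("domain error: k must be >= 1")
  if (n <= k) stop("domain error: need more samples than k")
  rng <- local_rng(jitter_seed)
  jit <- function(v) {
    s <- stats::sd(v)
    v + rng$rnorm(n, sd = 1e-10 * if (s > 0) s else 1)
  }
  x <- jit(x); y <- jit(y)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  # distance to the k-th joint neighbour of each point
  eps <- apply(dz, 1, function(r) sort.int(r, partial = k)[k])
  nx <- rowSums(dx < eps) - 1  # exclude self
  ny <- rowSums(dy < eps) - 1
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(0, mi)
}

#' Rank the output parameters by mutual information with stimulus level
#'
#' One KSG estimate per parameter column against `stimulus_level`,
#' sorted descending; ties keep name order (stable sort).
#'
#' @param table a [feature_table()].
#' @param k neighbour count (default 5).
#' @param jitter_seed passed to [knn_mutual_information()].
#' @return data.frame with `parameter`, `mi` (nats), `k`, in rank order.
#' @export
rank_parameters <- function(table, k = 5, jitter_seed = 1) {
  pars <- setdiff(colnames(table), "stimulus_level")
  mi <- vapply(pars, function(p)
    knn_mutual_information(table$stimulus_level, table[[p]], k = k,
                           jitter_seed = jitter_seed), numeric(1))
  out <- data.frame(parameter = pars, mi = unname(mi), k = k)
  out <- out[order(-out$mi, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}
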