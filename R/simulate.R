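# Deterministic mass-action ODE integration (embedded Runge-Kutta-Fehlberg
# 4(5) via deSolve) and batch simulation over stimulus grids.

#' Uniform sampling grid
#'
#' @param t_end end time in minutes (default 100, the length of one
#'   network simulation).
#' @param n_samples number of samples including both endpoints; the
#'   default 1001 gives dt = 0.1 min, fine enough to resolve the fastest
#'   activation transients.
#' @return a list of class `"time_grid"` with elements `t_end`,
#'   `n_samples`, `times`.
#' @export
time_grid <- function(t_end = 100, n_samples = 1001) {
  stopifnot(t_end > 0, n_samples >= 2)
  structure(list(t_end = t_end, n_samples = as.integer(n_samples),
                 times = seq(0, t_end, length.out = n_samples)),
            class = "time_grid")
}

# Precompile the reaction list into index form for a fast RHS:
# rate_r = k_r * prod(c[idx_r]); dc/dt = S %*% rates.
compile_network <- function(net) {
  n <- nrow(net$species)
  ids <- net$species$id
  dir <- list()  # directed (irreversible) reaction channels
  for (rx in net$reactions) {
    dir[[length(dir) + 1]] <- list(k = rx$kf, re = rx$reactants, pr = rx$products)
    if (!is.na(rx$kr))
      dir[[length(dir) + 1]] <- list(k = rx$kr, re = rx$products, pr = rx$reactants)
  }
  m <- length(dir)
  S <- matrix(0, n, m, dimnames = list(ids, NULL))
  idx <- vector("list", m)
  k <- numeric(m)
  for (j in seq_len(m)) {
    d <- dir[[j]]
    k[j] <- d$k
    idx[[j]] <- rep(match(d$re$id, ids), d$re$stoich)
    ri <- match(d$re$id, ids); pi <- match(d$pr$id, ids)
    S[ri, j] <- S[ri, j] - d$re$stoich
    S[pi, j] <- S[pi, j] + d$pr$stoich
  }
  pinned <- match(net$knocked, ids)
  list(S = S, idx = idx, k = k, n = n, ids = ids,
       pinned = pinned[!is.na(pinned)])
}

#' Integrate a reaction network
#'
#' Solves the mass-action system dc/dt = S v(c) with an embedded adaptive
#' Runge-Kutta-Fehlberg 4(5) scheme, sampling the solution on a uniform
#' grid. The stimulus species is initialized at `stimulus_level`
#' (molecules/cell); with `stimulus_mode = "clamped"` it is instead held
#' constant at that level for the whole run. Knocked-out species have
#' their derivative pinned at zero. Tiny negative excursions (inevitable
#' with non-stiff adaptive steps) are clipped to zero on output; excursions
#' below `-10 * atol` abort the run.
#'
#' @param net a `reaction_network`.
#' @param stimulus_level stimulus amount in molecules/cell, or `NULL` to
#'   use the model's own initial amount.
#' @param grid a [time_grid()].
#' @param rtol,atol relative/absolute integration tolerances.
#' @param stimulus_mode `"initial"` (ligand depletes through its binding
#'   reactions) or `"clamped"` (held constant).
#' @param method a deSolve method; default `"rk45f"` (Runge-Kutta-Fehlberg).
#' @return a list of class `"trajectory_set"`: `stimulus_level`, `grid`,
#'   `amounts` (species x time matrix, molecules/cell).
#' @export
integrate_network <- function(net, stimulus_level = NULL, grid = time_grid(),
                              rtol = 1e-6, atol = 1e-6,
                              stimulus_mode = c("initial", "clamped"),
                              method = "rk45f") {
  stimulus_mode <- match.arg(stimulus_mode)
  stopifnot(rtol > 0, atol > 0)
  if (!is.null(stimulus_level) && stimulus_level < 0)
    stop("domain error: stimulus_level must be >= 0")
  cmp <- compile_network(net)
  y0 <- stats::setNames(net$species$initial_amount, cmp$ids)
  stim <- stimulus_id(net)
  if (!is.null(stimulus_level)) {
    if (!length(stim))
      stop("structural error: network has no stimulus species")
    y0[stim] <- stimulus_level
  }
  clamp_i <- if (stimulus_mode == "clamped" && length(stim))
    match(stim, cmp$ids) else integer()
  pinned <- c(cmp$pinned, clamp_i)
  y0[cmp$pinned] <- 0
  S <- cmp$S; idx <- cmp$idx; kk <- cmp$k; m <- length(kk)
  rhs <- function(t, y, parms) {
    rates <- kk
    for (j in seq_len(m)) rates[j] <- kk[j] * prod(y[idx[[j]]])
    dy <- drop(S %*% rates)
    if (length(pinned)) dy[pinned] <- 0
    list(dy)
  }
  if (is.character(method) && method %in% c("rk45f", "rk45ck", "rk45dp7",
                                            "rk45e", "rk45dp6"))
    method <- deSolve::rkMethod(method)
  sol <- deSolve::ode(y = y0, times = grid$times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("numerical error: integrator failed (istate ",
         attr(sol, "istate")[1], ")")
  amounts <- t(unclass(sol)[, -1, drop = FALSE])
  rownames(amounts) <- cmp$ids
  if (!all(is.finite(amounts)))
    stop("numerical error: non-finite amounts in solution")
  if (min(amounts) < -10 * atol)
    stop("numerical error: negative excursion beyond tolerance (min ",
         format(min(amounts)), ")")
  amounts[amounts < 0] <- 0
  structure(list(stimulus_level = if (is.null(stimulus_level))
    unname(y0[stim][1]) else stimulus_level,
    grid = grid, amounts = amounts),
    class = "trajectory_set")
}

#' Simulate a network over a set of stimulus levels
#'
#' One independent integration per level, order preserved.
#'
#' @param net a `reaction_network`.
#' @param stimulus_levels non-empty vector of non-negative levels
#'   (molecules/cell).
#' @param grid a [time_grid()].
#' @param ... passed to [integrate_network()].
#' @return a list of class `"batch_result"`: `stimulus_levels`,
#'   `trajectories` (one `trajectory_set` per level).
#' @export
batch_simulate <- function(net, stimulus_levels, grid = time_grid(), ...) {
  if (!length(stimulus_levels))
    stop("domain error: stimulus_levels must be non-empty")
  if (any(stimulus_levels < 0))
    stop("domain error: stimulus levels must be >= 0")
  trajs <- vector("list", length(stimulus_levels))
  for (i in seq_along(stimulus_levels)) {
    trajs[[i]] <- tryCatch(
      integrate_network(net, stimulus_levels[i], grid, ...),
      error = function(e) stop("at stimulus level ", stimulus_levels[i],
                               ": ", conditionMessage(e)))
  }
  structure(list(stimulus_levels = stimulus_levels, trajectories = trajs),
            class = "batch_result")
}

#' Standard EGF stimulus grids
#'
#' Two grids are used in the analysis: the `clustering` grid of 101 levels
#' spanning 5 to 5000 molecules/cell (uniformly spaced), along which
#' per-level clusterings are compared; and the `mi` grid used for
#' information estimates, the union of the three arithmetic ranges 1..500
#' step 1, 500..1000 step 10 and 1000..5000 step 50, duplicates removed
#' (630 unique levels).
#'
#' @param spec `"clustering"` or `"mi"`.
#' @return numeric vector of stimulus levels, strictly increasing.
#' @export
make_egf_grid <- function(spec = c("clustering", "mi")) {
  spec <- tryCatch(match.arg(spec),
                   error = function(e) stop("domain error: unknown grid spec"))
  if (spec == "clustering") return(seq(5, 5000, length.out = 101))
  sort(unique(c(seq(1, 500, 1), seq(500, 1000, 10), seq(1000, 5000, 50))))
}

#' Write a trajectory set as tidy CSV
#'
#' Long format with columns `species`, `time_min`, `amount`.
#'
#' @param traj a `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  df <- data.frame(
    species = rep(rownames(traj$amounts), each = ncol(traj$amounts)),
    time_min = rep(traj$grid$times, times = nrow(traj$amounts)),
    amount = as.vector(t(traj$amounts)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
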