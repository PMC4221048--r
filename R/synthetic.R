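# Synthetic generators: toy signalling cascades, planted profile groups,
# sample pairs with known mutual information, and clustering ensembles.
# These emulate the structure of the EGFR/MAPK study system (layered
# cascade, duplicated internalized route, phosphatases, degradation
# sinks, one stimulus, two outputs) without reproducing any published
# parameterization; they are structural stand-ins for validation.

#' Generate a toy mass-action signalling cascade
#'
#' Builds a layered kinase cascade: the stimulus ligand binds a receptor;
#' the active receptor complex drives tier-1 activation, each active tier
#' catalyzes the next (successively larger substrate pools, mimicking
#' cascade amplification), and the last tier's active form is the network
#' output. Options add an "internalized" parallel route (the active
#' receptor internalizes and drives a duplicate chain of active forms
#' over the shared substrate pools, with its own output), per-tier
#' phosphatases (enzymatic back-reactions; plain first-order decay
#' otherwise), and first-order degradation of the receptor complexes into
#' tagged sink species. Rate constants are drawn reproducibly around
#' field-typical base values scaled by `rate_scale`.
#'
#' @param n_tiers number of kinase tiers (>= 2, default 3).
#' @param dual_route add the internalized parallel route (default TRUE).
#' @param with_phosphatases enzymatic deactivation (default TRUE).
#' @param with_degradation receptor degradation sinks (default TRUE).
#' @param rate_scale multiplies every rate constant (default 1).
#' @param seed integer seed for the rate draws (default 1).
#' @return a `reaction_network` with one stimulus species and one
#'   (`dual_route = FALSE`) or two output species.
#' @export
make_toy_cascade <- function(n_tiers = 3, dual_route = TRUE,
                             with_phosphatases = TRUE,
                             with_degradation = TRUE,
                             rate_scale = 1, seed = 1) {
  stopifnot(n_tiers >= 2)
  rng <- local_rng(seed)
  draw <- function(base) base * rate_scale * rng$rlnorm(1, sdlog = 0.2)

  sp_id <- character(); sp_amt <- numeric(); sp_tags <- list()
  add_sp <- function(id, amt, tags = character()) {
    sp_id <<- c(sp_id, id); sp_amt <<- c(sp_amt, amt)
    sp_tags[[length(sp_tags) + 1]] <<- tags
  }
  rxs <- list()
  add_rx <- function(re, pr, kf, kr = NA_real_)
    rxs[[length(rxs) + 1]] <<- reaction(re, pr, kf = kf, kr = kr)

  add_sp("S", 0, "stimulus")
  add_sp("R", 10000, "surface")
  add_sp("RS", 0, "surface")
  add_rx(c("S", "R"), "RS", draw(1e-4), draw(0.01))
  if (dual_route) {
    add_sp("RSi", 0, "internalized")
    add_rx("RS", "RSi", draw(0.05))
  }
  if (with_degradation) {
    add_sp("RS_deg", 0, c("surface", "degraded"))
    add_rx("RS", "RS_deg", draw(0.02))
    if (dual_route) {
      add_sp("RSi_deg", 0, c("internalized", "degraded"))
      add_rx("RSi", "RSi_deg", draw(0.05))
    }
  }
  for (j in seq_len(n_tiers)) {
    pool <- 2000 * 2^j  # amplification: larger pools downstream
    last <- j == n_tiers
    add_sp(paste0("X", j), pool, "surface")
    add_sp(paste0("X", j, "a"), 0,
           c("surface", if (last) "output"))
    up <- if (j == 1) "RS" else paste0("X", j - 1, "a")
    add_rx(c(up, paste0("X", j)), c(up, paste0("X", j, "a")), draw(2e-5))
    if (dual_route) {
      add_sp(paste0("X", j, "ai"), 0,
             c("internalized", if (last) "output"))
      upi <- if (j == 1) "RSi" else paste0("X", j - 1, "ai")
      add_rx(c(upi, paste0("X", j)), c(upi, paste0("X", j, "ai")), draw(2e-5))
    }
    if (with_phosphatases) {
      add_sp(paste0("P", j), 500, "surface")
      add_rx(c(paste0("P", j), paste0("X", j, "a")),
             c(paste0("P", j), paste0("X", j)), draw(2e-4))
      if (dual_route)
        add_rx(c(paste0("P", j), paste0("X", j, "ai")),
               c(paste0("P", j), paste0("X", j)), draw(2e-4))
    } else {
      add_rx(paste0("X", j, "a"), paste0("X", j), draw(0.1))
      if (dual_route)
        add_rx(paste0("X", j, "ai"), paste0("X", j), draw(0.1))
    }
  }
  reaction_network(species_table(sp_id, sp_amt, tags = sp_tags), rxs)
}

#' Planted groups of activation profiles
#'
#' Generates `n_groups * n_per_group` profiles: each group is a distinct
#' smooth template (single fast peak, biphasic double peak, slow ramp,
#' rise-to-plateau, fast early spike, drop-and-recover — echoing the
#' archetypal dynamics of signalling protein groups) plus i.i.d. Gaussian
#' noise, then min-max normalized per profile.
#'
#' @param n_groups number of groups (1..6 use the named templates; more
#'   are generated as additional shifted bumps).
#' @param n_per_group profiles per group.
#' @param T number of time samples (default 101).
#' @param noise_sd Gaussian noise SD added before normalization.
#' @param seed integer seed.
#' @return a list: `profiles` (a `profile_matrix`), `labels` (integer
#'   vector of planted group labels).
#' @export
make_planted_profiles <- function(n_groups, n_per_group, T = 101,
                                  noise_sd = 0.01, seed = 1) {
  stopifnot(n_groups >= 1, n_per_group >= 1, T >= 4, noise_sd >= 0)
  t <- seq(0, 1, length.out = T)
  templates <- list(
    function(t) (t / 0.1) * exp(1 - t / 0.1),                 # fast peak, decline
    function(t) exp(-((t - 0.2) / 0.08)^2) +
                0.8 * exp(-((t - 0.6) / 0.12)^2),             # biphasic
    function(t) t,                                            # slow rise
    function(t) 1 - exp(-8 * t),                              # rise to plateau
    function(t) exp(-((t - 0.04) / 0.025)^2) +
                0.3 * exp(-((t - 0.25) / 0.1)^2),             # fastest spike
    function(t) pmin(t / 0.02, 1) *
                (0.25 + 0.75 * exp(-((t - 0.02) / 0.06)^2)) +
                0.35 * (1 - exp(-4 * pmax(t - 0.1, 0)))       # drop & recover
  )
  if (n_groups > length(templates))
    for (g in (length(templates) + 1):n_groups) {
      ctr <- 0.5 * (g - length(templates)) / (n_groups - length(templates) + 1)
      templates[[g]] <- local({
        c0 <- 0.3 + ctr
        function(t) exp(-((t - c0) / 0.07)^2)
      })
    }
  rng <- local_rng(seed)
  N <- n_groups * n_per_group
  X <- matrix(0, N, T)
  labels <- rep(seq_len(n_groups), each = n_per_group)
  for (i in seq_len(N)) {
    base <- templates[[labels[i]]](t)
    X[i, ] <- base + rng$rnorm(T, sd = noise_sd)
  }
  lo <- apply(X, 1, min); hi <- apply(X, 1, max)
  X <- (X - lo) / pmax(hi - lo, .Machine$double.eps)
  ids <- paste0("g", labels, "_", sequence(rep(n_per_group, n_groups)))
  rownames(X) <- ids
  profiles <- structure(list(X = X, protein_ids = ids, stimulus_level = NA,
                             degenerate = stats::setNames(rep(FALSE, N), ids)),
                        class = "profile_matrix")
  list(profiles = profiles, labels = labels)
}

#' Sample pairs with known mutual information
#'
#' Reproducible (x, y) samples with an analytic MI value: bivariate
#' Gaussian with correlation `rho` (MI = -1/2 log(1 - rho^2) nats),
#' independent Gaussians (MI = 0), or an exact deterministic copy
#' (MI = +Inf sentinel).
#'
#' @param family `"gaussian"`, `"independent"` or `"deterministic"`.
#' @param n sample count (>= 10).
#' @param seed integer seed.
#' @param rho Gaussian correlation, `|rho| < 1`.
#' @return list with `x`, `y`, `mi` (analytic value in nats).
#' @export
make_known_mi_pairs <- function(family = c("gaussian", "independent",
                                           "deterministic"),
                                n, seed = 1, rho = 0) {
  family <- match.arg(family)
  stopifnot(n >= 10)
  if (abs(rho) >= 1) stop("domain error: |rho| must be < 1")
  rng <- local_rng(seed)
  x <- rng$rnorm(n)
  switch(family,
    gaussian = list(x = x, y = rho * x + sqrt(1 - rho^2) * rng$rnorm(n),
                    mi = -0.5 * log(1 - rho^2)),
    independent = list(x = x, y = rng$rnorm(n), mi = 0),
    deterministic = list(x = x, y = x, mi = Inf))
}

#' Ensemble of noisy clusterings around a planted partition
#'
#' A balanced base partition of `n_points` into `n_groups`; each of the
#' `n_clusterings` copies independently reassigns every point, with
#' probability `flip_prob`, to a uniformly drawn group.
#'
#' @param n_points,n_groups,n_clusterings sizes.
#' @param flip_prob per-point flip probability in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `clusterings` (list of label vectors) and
#'   `true_labels`.
#' @export
make_clustering_ensemble <- function(n_points, n_groups, n_clusterings,
                                     flip_prob = 0, seed = 1) {
  stopifnot(flip_prob >= 0, flip_prob < 1, n_groups >= 1)
  base <- rep(seq_len(n_groups), length.out = n_points)
  rng <- local_rng(seed)
  clusterings <- lapply(seq_len(n_clusterings), function(j) {
    lab <- base
    flip <- rng$runif(n_points) < flip_prob
    if (any(flip))
      lab[flip] <- rng$sample(n_groups, sum(flip), replace = TRUE)
    lab
  })
  list(clusterings = clusterings, true_labels = base)
}
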