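# Consensus clustering: aggregate an ensemble of clusterings through the
# co-assignment matrix, re-cluster it with dominant sets, and pick
# representative members per group.

#' Build the consensus (co-assignment) matrix of a clustering ensemble
#'
#' `P_ij` is the fraction of clusterings in which points i and j share a
#' group. Invariant to relabeling within each input clustering. The
#' diagonal is set to zero, matching the adjacency convention used by the
#' dominant-sets stage.
#'
#' @param clusterings list (length >= 2) of equal-length label vectors or
#'   `ds_clustering` objects.
#' @return symmetric N x N matrix with entries in `[0, 1]`, zero
#'   diagonal, attribute `"n_clusterings"`.
#' @export
build_consensus <- function(clusterings) {
  labs <- lapply(clusterings, function(cl)
    if (inherits(cl, "ds_clustering")) cl$labels else cl)
  if (length(labs) < 2)
    stop("domain error: need at least 2 clusterings")
  n <- length(labs[[1]])
  if (!all(vapply(labs, length, integer(1)) == n))
    stop("domain error: clusterings differ in length")
  P <- matrix(0, n, n)
  for (lab in labs) P <- P + outer(lab, lab, "==")
  P <- P / length(labs)
  diag(P) <- 0
  if (!is.null(names(labs[[1]]))) dimnames(P) <- list(names(labs[[1]]),
                                                      names(labs[[1]]))
  attr(P, "n_clusterings") <- length(labs)
  P
}

#' Cluster the consensus matrix with dominant sets
#'
#' Treats the consensus matrix as an adjacency matrix and runs the
#' dominant-sets peel on it, with a permutation chance level. Extracted
#' groups whose cohesiveness falls below the chance level are retained
#' and flagged (not discarded); points never co-clustered with anyone end
#' up as singleton groups.
#'
#' @param P consensus matrix from [build_consensus()].
#' @param n_perm,alpha,seed chance-level settings (defaults 1000, 0.005).
#' @param use_chance set `FALSE` to skip the permutation calibration.
#' @return a `ds_clustering` (see [peel_clustering()]).
#' @export
consensus_cluster <- function(P, n_perm = 1000, alpha = 0.005, seed = 1,
                              use_chance = TRUE) {
  A <- unclass(P)
  diag(A) <- 0
  thr <- if (use_chance) chance_level(A, n_perm = n_perm, alpha = alpha,
                                      seed = seed) else NULL
  peel_clustering(A, chance_threshold = thr, stop_below_chance = FALSE)
}

#' Representative members of each group
#'
#' For each group, the `k` members with the highest membership weight in
#' the converged replicator vector, in descending order of "typicality".
#' Ties break by member index order.
#'
#' @param clustering a `ds_clustering`.
#' @param k maximum number of representatives per group (default 3).
#' @return data.frame with `group`, `rank`, `protein`, `membership`.
#' @export
representatives <- function(clustering, k = 3) {
  if (k < 1) stop("domain error: k must be >= 1")
  rows <- list()
  for (g in seq_along(clustering$groups)) {
    grp <- clustering$groups[[g]]
    w <- grp$membership
    ord <- order(-w, seq_along(w))
    take <- ord[seq_len(min(k, length(w)))]
    rows[[g]] <- data.frame(group = g, rank = seq_along(take),
                            protein = names(w)[take],
                            membership = unname(w[take]))
  }
  do.call(rbind, rows)
}

#' Export a consensus clustering as a flat table
#'
#' @param clustering a `ds_clustering`.
#' @return data.frame with `protein`, `group`, `membership`,
#'   `below_chance`.
#' @export
clustering_table <- function(clustering) {
  rows <- list()
  for (g in seq_along(clustering$groups)) {
    grp <- clustering$groups[[g]]
    rows[[g]] <- data.frame(protein = names(grp$membership),
                            group = g,
                            membership = unname(grp$membership),
                            below_chance = isTRUE(grp$below_chance))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
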