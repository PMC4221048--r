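# Dominant-sets clustering. A dominant set is a subset of points whose
# internal similarity exceeds its similarity to the rest; it is
# characterized as a local maximizer of the cohesiveness F(m) = m'Am over
# the probability simplex, found by discrete replicator dynamics.

#' Extract the dominant set of a similarity matrix
#'
#' Maximizes `F(m) = m' A m` over the simplex with the multiplicative
#' replicator update `m_i <- m_i * (Am)_i / (m'Am)`, initialized at the
#' barycenter. On a symmetric non-negative matrix the update never
#' decreases F, and its support at convergence identifies the maximally
#' cohesive subset. Iteration stops when `|F_t - F_{t-1}| < tol` or after
#' `max_iter` updates; members are the indices with
#' `m_i > support_eps * max(m)`.
#'
#' The start point carries a small deterministic tilt (relative size
#' 1e-3, decreasing with index) away from the exact barycenter: on
#' matrices with symmetric ties the barycenter is itself an unstable
#' fixed point, and the tilt lets the dynamics escape it,
#' deterministically favouring lower indices. Where the barycenter is a
#' true maximizer (e.g. uniform similarities) the dynamics return to it.
#' Convergence requires both the F-change below `tol` and the membership
#' change below 1e-9, so the saddle-escape phase (tiny F-change, growing
#' membership change) is not mistaken for convergence.
#'
#' @param A symmetric non-negative similarity matrix, zero diagonal.
#' @param tol convergence tolerance on F (default 1e-12).
#' @param max_iter iteration cap (default 1e4).
#' @param support_eps relative membership threshold (default 1e-6).
#' @param trace if `TRUE`, attach the per-iteration F trajectory.
#' @return a list of class `"dominant_set"`: `members` (indices),
#'   `membership` (weights over members, summing to 1), `cohesiveness`
#'   (F at convergence), `degenerate` flag; with `trace`, an `f_trace`
#'   attribute.
#' @export
extract_dominant_set <- function(A, tol = 1e-12, max_iter = 1e4,
                                 support_eps = 1e-6, trace = FALSE) {
  n <- nrow(A)
  stopifnot(n >= 1, ncol(A) == n)
  if (n == 1 || all(A == 0)) {
    return(structure(list(members = 1L,
                          membership = stats::setNames(1, rownames(A)[1]),
                          cohesiveness = 0,
                          degenerate = TRUE),
                     class = "dominant_set"))
  }
  m <- (1 + 1e-3 * (n - seq_len(n)) / n) / n
  m <- m / sum(m)
  f <- drop(crossprod(m, A %*% m))
  f_trace <- if (trace) f else NULL
  for (it in seq_len(max_iter)) {
    Am <- drop(A %*% m)
    denom <- sum(m * Am)
    if (denom <= 0) break  # no internal similarity left
    m_new <- m * Am / denom
    f_new <- drop(crossprod(m_new, A %*% m_new))
    if (trace) f_trace <- c(f_trace, f_new)
    dm <- max(abs(m_new - m))
    m <- m_new
    if (abs(f_new - f) < tol && dm < 1e-9) { f <- f_new; break }
    f <- f_new
  }
  members <- which(m > support_eps * max(m))
  membership <- m[members] / sum(m[members])
  names(membership) <- rownames(A)[members]
  out <- structure(list(members = members, membership = membership,
                        cohesiveness = f, degenerate = FALSE),
                   class = "dominant_set")
  if (trace) attr(out, "f_trace") <- f_trace
  out
}

#' Iterative dominant-sets clustering (peel-off strategy)
#'
#' Repeatedly extracts the dominant set of the residual similarity matrix
#' and removes its members, until the residual set is empty, has fewer
#' than 2 points, or (when `chance_threshold` is given) the newly
#' extracted set's cohesiveness falls below threshold — remaining points
#' then become trailing singleton groups. Groups are ranked by
#' cohesiveness (label 1 = most cohesive); ties break on the lower
#' smallest member index, so output is deterministic and invariant to
#' input point order up to relabeling.
#'
#' @param A symmetric non-negative similarity matrix, zero diagonal.
#' @param chance_threshold optional cohesiveness below which extracted
#'   sets are considered unstructured (see [chance_level()]).
#' @param stop_below_chance if `TRUE` (default), peeling stops at the
#'   first below-chance set and the remaining points become singletons;
#'   if `FALSE`, below-chance sets are retained as groups and flagged
#'   (the convention used for the consensus clustering, where the least
#'   coherent group is reported with a below-chance mark).
#' @param ... passed to [extract_dominant_set()].
#' @return a list of class `"ds_clustering"`: `labels` (length-N integer
#'   vector, 1 = most cohesive group), `groups` (ordered list with
#'   `members`, `membership`, `cohesiveness`, `below_chance`),
#'   `chance_threshold`.
#' @export
peel_clustering <- function(A, chance_threshold = NULL,
                            stop_below_chance = TRUE, ...) {
  n <- nrow(A)
  stopifnot(n >= 1)
  ids <- rownames(A) %||% as.character(seq_len(n))
  active <- seq_len(n)
  groups <- list()
  while (length(active) >= 2) {
    ds <- extract_dominant_set(A[active, active, drop = FALSE], ...)
    members_global <- active[ds$members]
    below <- !is.null(chance_threshold) && ds$cohesiveness < chance_threshold
    if (below && stop_below_chance) break
    groups[[length(groups) + 1]] <-
      list(members = members_global,
           membership = stats::setNames(ds$membership, ids[members_global]),
           cohesiveness = ds$cohesiveness,
           below_chance = below)
    active <- setdiff(active, members_global)
  }
  # leftovers (residual < 2 points, or below-chance stop): singletons
  for (i in active) {
    groups[[length(groups) + 1]] <-
      list(members = i, membership = stats::setNames(1, ids[i]),
           cohesiveness = 0,
           below_chance = !is.null(chance_threshold) && 0 < chance_threshold)
  }
  # rank groups by cohesiveness, ties by smallest member index
  ord <- order(-vapply(groups, `[[`, numeric(1), "cohesiveness"),
               vapply(groups, function(g) min(g$members), numeric(1)))
  groups <- groups[ord]
  labels <- integer(n)
  for (g in seq_along(groups)) labels[groups[[g]]$members] <- g
  names(labels) <- ids
  structure(list(labels = labels, groups = groups,
                 chance_threshold = chance_threshold),
            class = "ds_clustering")
}

#' @export
print.ds_clustering <- function(x, ...) {
  cat("dominant-sets clustering:", length(x$groups), "groups over",
      length(x$labels), "points\n")
  for (g in seq_along(x$groups)) {
    grp <- x$groups[[g]]
    cat(sprintf("  group %d: %d members, F = %.4g%s\n", g,
                length(grp$members), grp$cohesiveness,
                if (isTRUE(grp$below_chance)) " (below chance)" else ""))
  }
  invisible(x)
}

#' Permutation chance level for dominant-set cohesiveness
#'
#' Estimates the cohesiveness that dominant sets reach on structureless
#' data: the extractor is run on `n_perm` randomized copies of `A` and the
#' `(1 - alpha)` quantile of the resulting cohesiveness distribution is
#' returned. Two nulls are available: `"shuffle"` (default) permutes the
#' off-diagonal upper-triangle entries and mirrors them, preserving
#' symmetry and the similarity distribution while destroying structure;
#' `"rowcol"` applies one random permutation jointly to rows and columns
#' (which preserves cohesiveness structure exactly and is retained only
#' as a diagnostic).
#'
#' @param A symmetric non-negative similarity matrix, zero diagonal.
#' @param n_perm number of randomized copies (default 1000).
#' @param alpha significance level (default 0.005): the threshold is the
#'   cohesiveness exceeded by only `alpha` of the null extractions.
#' @param null `"shuffle"` or `"rowcol"`.
#' @param seed integer seed.
#' @return the threshold cohesiveness (numeric scalar) with attribute
#'   `"distribution"` (the null cohesiveness values).
#' @export
chance_level <- function(A, n_perm = 1000, alpha = 0.005,
                         null = c("shuffle", "rowcol"), seed = 1) {
  null <- match.arg(null)
  stopifnot(n_perm >= 100, alpha > 0, alpha < 1)
  n <- nrow(A)
  ut <- upper.tri(A)
  rng <- local_rng(seed)
  fs <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Ap <- A
    if (null == "shuffle") {
      v <- A[ut]
      Ap[ut] <- rng$sample(v)
      Ap[lower.tri(Ap)] <- t(Ap)[lower.tri(Ap)]
    } else {
      perm <- rng$sample(n)
      Ap <- A[perm, perm]
    }
    fs[p] <- extract_dominant_set(Ap)$cohesiveness
  }
  thr <- unname(stats::quantile(fs, probs = 1 - alpha, type = 7))
  attr(thr, "distribution") <- fs
  thr
}

#' Cohesiveness-vs-rank table of a clustering
#'
#' One row per group in rank order, with the chance level (if any) as a
#' reference column — the diagnostic used to decide how many groups carry
#' structure.
#'
#' @param clustering a `ds_clustering`.
#' @return data.frame with `rank`, `size`, `cohesiveness`, `below_chance`,
#'   `chance_level`.
#' @export
cohesiveness_table <- function(clustering) {
  data.frame(
    rank = seq_along(clustering$groups),
    size = vapply(clustering$groups, function(g) length(g$members), integer(1)),
    cohesiveness = vapply(clustering$groups, `[[`, numeric(1), "cohesiveness"),
    below_chance = vapply(clustering$groups, function(g)
      isTRUE(g$below_chance), logical(1)),
    chance_level = if (is.null(clustering$chance_threshold)) NA_real_
                   else as.numeric(clustering$chance_threshold))
}
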