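# Comparing clusterings: the variation-of-information metric and a
# classical (Torgerson) MDS embedding of a set of clusterings.

#' Variation of information between two clusterings
#'
#' `VI(c1, c2) = H(c1) + H(c2) - 2 I(c1, c2)` in nats, computed from the
#' contingency table of label co-occurrence with the convention
#' `0 log 0 = 0`. VI is a true metric on partitions: symmetric, zero iff
#' the partitions coincide (up to label permutation), satisfies the
#' triangle inequality, and is bounded by `log N`.
#'
#' @param c1,c2 label vectors of equal length (positive integers; any
#'   labelling works, only the induced partitions matter).
#' @return VI in nats (non-negative scalar).
#' @export
vi_distance <- function(c1, c2) {
  if (length(c1) != length(c2))
    stop("domain error: label vectors differ in length")
  n <- length(c1)
  tab <- table(c1, c2) / n
  px <- rowSums(tab); py <- colSums(tab)
  plogp <- function(p) sum(ifelse(p > 0, p * log(p), 0))
  hx <- -plogp(px); hy <- -plogp(py)
  hxy <- -plogp(as.vector(tab))
  # VI = H(X) + H(Y) - 2 I = 2 H(X,Y) - H(X) - H(Y)
  max(0, 2 * hxy - hx - hy)
}

#' Pairwise VI distance matrix over a list of clusterings
#'
#' @param clusterings list of equal-length label vectors (or
#'   `ds_clustering` objects, whose labels are used).
#' @return symmetric M x M matrix of VI distances (nats), zero diagonal.
#' @export
pairwise_vi <- function(clusterings) {
  labs <- lapply(clusterings, function(cl)
    if (inherits(cl, "ds_clustering")) cl$labels else cl)
  m <- length(labs)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    D[i, j] <- D[j, i] <- vi_distance(labs[[i]], labs[[j]])
  D
}

#' Test whether two label vectors induce the same partition
#'
#' Label-permutation-invariant equality: each vector is brought to a
#' canonical form (groups renumbered by first occurrence) and the forms
#' compared.
#'
#' @param c1,c2 label vectors of equal length.
#' @return `TRUE` iff the partitions coincide.
#' @export
same_partition <- function(c1, c2) {
  canon <- function(x) match(x, unique(x))
  identical(canon(unname(c1)), canon(unname(c2)))
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS: double-center `-1/2 J D^2 J`, take the top-`d`
#' eigenpairs, and scale eigenvectors by the square root of their
#' eigenvalues. Negative eigenvalues are truncated at zero; if fewer than
#' `d` positive eigenvalues exist the missing coordinates are zero-padded
#' with a warning. Coordinates are determined only up to rotation and
#' reflection, so comparisons should be made on embedded distances.
#'
#' @param D symmetric distance matrix.
#' @param d embedding dimension (default 2).
#' @return a list of class `"mds_embedding"`: `coords` (M x d), `stress`
#'   (normalized residual `sqrt(sum((D - Dhat)^2) / sum(D^2))`),
#'   `eigenvalues`.
#' @export
mds_embed <- function(D, d = 2) {
  stopifnot(d >= 1)
  m <- nrow(D)
  B <- -0.5 * scale(t(scale(t(D^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  pos <- sum(eg$values > sqrt(.Machine$double.eps) * max(abs(eg$values), 1))
  k <- min(d, pos)
  if (k < d)
    warning("only ", pos, " positive eigenvalues; zero-padding to ", d,
            " dimensions")
  coords <- matrix(0, m, d)
  if (k >= 1)
    coords[, seq_len(k)] <-
      eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(eg$values[seq_len(k)]), k)
  Dhat <- as.matrix(stats::dist(coords))
  denom <- sum(D^2)
  stress <- if (denom > 0) sqrt(sum((D - Dhat)^2) / denom) else 0
  structure(list(coords = coords, stress = stress, eigenvalues = eg$values),
            class = "mds_embedding")
}

#' First MDS coordinate as a function of stimulus level
#'
#' The diagnostic used to read regime changes off the clustering
#' comparison: the first embedding coordinate of each per-level
#' clustering, ordered by stimulus level.
#'
#' @param map an `mds_embedding` with one row per level.
#' @param levels stimulus levels (same order as the embedded rows).
#' @return data.frame with columns `level`, `r1`, sorted by level.
#' @export
r1_vs_level <- function(map, levels) {
  if (length(levels) != nrow(map$coords))
    stop("domain error: one coordinate row per level required")
  out <- data.frame(level = levels, r1 = map$coords[, 1])
  out[order(out$level), , drop = FALSE]
}
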