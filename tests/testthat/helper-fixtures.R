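# Shared fixtures and independent oracles, all built in code.

# one-step decay A -> B
decay_network <- function(k = 0.1, a0 = 100) {
  reaction_network(
    species_table(c("A", "B"), c(a0, 0)),
    list(reaction("A", "B", kf = k)))
}

# closed reversible A <-> B
reversible_network <- function(kf = 0.3, kr = 0.1, a0 = 50, b0 = 10) {
  reaction_network(
    species_table(c("A", "B"), c(a0, b0)),
    list(reaction("A", "B", kf = kf, kr = kr)))
}

# small 3-tier cascade without the dual route (9 species)
small_cascade <- function(seed = 7) {
  make_toy_cascade(n_tiers = 3, dual_route = FALSE,
                   with_degradation = FALSE, seed = seed)
}

# fixed-step classical RK4 oracle, independent of deSolve
rk4_oracle <- function(net, stimulus_level, times, dt = 1e-3) {
  ids <- net$species$id
  y <- stats::setNames(net$species$initial_amount, ids)
  stim <- stimulus_id(net)
  if (length(stim) && !is.null(stimulus_level)) y[stim] <- stimulus_level
  rxs <- list()
  for (rx in net$reactions) {
    rxs[[length(rxs) + 1]] <- list(k = rx$kf, re = rx$reactants, pr = rx$products)
    if (!is.na(rx$kr))
      rxs[[length(rxs) + 1]] <- list(k = rx$kr, re = rx$products, pr = rx$reactants)
  }
  deriv <- function(y) {
    dy <- numeric(length(y))
    for (r in rxs) {
      v <- r$k * prod(y[r$re$id]^r$re$stoich)
      dy[match(r$re$id, ids)] <- dy[match(r$re$id, ids)] - v * r$re$stoich
      dy[match(r$pr$id, ids)] <- dy[match(r$pr$id, ids)] + v * r$pr$stoich
    }
    dy
  }
  out <- matrix(NA_real_, length(ids), length(times), dimnames = list(ids, NULL))
  t <- 0; ti <- 1
  t_end <- max(times)
  repeat {
    while (ti <= length(times) && times[ti] <= t + 1e-12) {
      out[, ti] <- y; ti <- ti + 1
    }
    if (t >= t_end || ti > length(times)) break
    h <- min(dt, times[ti] - t)
    k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  out
}

# block similarity matrix with planted groups
block_similarity <- function(sizes, within = 0.9, between = 0.01) {
  labels <- rep(seq_along(sizes), sizes)
  A <- ifelse(outer(labels, labels, "=="), within, between)
  diag(A) <- 0
  attr(A, "labels") <- labels
  A
}

# exhaustive dominant-set oracle: score every non-empty subset by F at the
# fixed point of replicator dynamics run inside the subset; return the best
exhaustive_dominant_set <- function(A, tol = 1e-10, max_iter = 1000) {
  n <- nrow(A)
  best <- list(f = -Inf, subset = NULL)
  for (code in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    ns <- length(subset)
    if (ns == 1) { f <- 0 }
    else {
      As <- A[subset, subset]
      m <- rep(1 / ns, ns)
      f <- drop(crossprod(m, As %*% m))
      for (it in seq_len(max_iter)) {
        Am <- drop(As %*% m); den <- sum(m * Am)
        if (den <= 0) break
        m <- m * Am / den
        f2 <- drop(crossprod(m, As %*% m))
        if (abs(f2 - f) < tol) { f <- f2; break }
        f <- f2
      }
    }
    if (f > best$f + 1e-12) best <- list(f = f, subset = subset)
  }
  best
}

# plug-in VI oracle computed straight from the definition (double loop)
vi_oracle <- function(c1, c2) {
  n <- length(c1)
  g1 <- unique(c1); g2 <- unique(c2)
  H <- function(cl, gs) {
    p <- vapply(gs, function(g) mean(cl == g), numeric(1))
    -sum(p * log(p))
  }
  I <- 0
  for (a in g1) for (b in g2) {
    pab <- mean(c1 == a & c2 == b)
    if (pab > 0) I <- I + pab * log(pab / (mean(c1 == a) * mean(c2 == b)))
  }
  H(c1, g1) + H(c2, g2) - 2 * I
}

random_labels <- function(n, kmax = 6) sample(seq_len(kmax), n, replace = TRUE)
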