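# Independent oracles used across the suite. These deliberately avoid the
# package's own lattice/neighbour code paths.

# Brute-force neighbour oracle: voxel centres on the offset hexagonal grid,
# neighbours = the voxels at minimal-image distance 2r.
oracle_neighbors <- function(W, H, r = 3.62e-9) {
  j <- rep(0:(H - 1), each = W)
  i <- rep(0:(W - 1), times = H)
  x <- 2 * r * i + (j %% 2) * r
  y <- sqrt(3) * r * j
  width <- W * 2 * r; height <- H * sqrt(3) * r
  n <- W * H
  out <- vector("list", n)
  for (v in seq_len(n)) {
    dx <- abs(x - x[v]); dx <- pmin(dx, width - dx)
    dy <- abs(y - y[v]); dy <- pmin(dy, height - dy)
    d2 <- dx^2 + dy^2
    out[[v]] <- sort(which(d2 > 1e-30 & d2 < (2.001 * r)^2) - 1L)
  }
  out
}

# Breadth-first-search connected components over an explicit neighbour list.
oracle_bfs_components <- function(voxels, nb_list) {
  idx <- stats::setNames(seq_along(voxels), voxels)
  lab <- integer(length(voxels))
  cur <- 0L
  for (s in seq_along(voxels)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb_list[[voxels[v] + 1L]]) {
        j <- idx[as.character(w)]
        if (!is.na(j) && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  lab
}

# Direct-method (first-principles Gillespie) stochastic simulation oracle
# for small well-mixed networks, independent of the package scheduler.
oracle_direct_ssa <- function(network, x0, t_end) {
  x <- x0[network$species]
  t <- 0
  repeat {
    a <- vapply(network$reactions, function(r) {
      ai <- r$k
      for (s in names(r$reactants)) {
        m <- r$reactants[[s]]
        ai <- ai * if (m == 2) x[[s]] * (x[[s]] - 1) / 2 else x[[s]]^m
      }
      ai
    }, numeric(1))
    atot <- sum(a)
    if (atot <= 0) break
    t <- t + stats::rexp(1, atot)
    if (t > t_end) break
    i <- sample.int(length(a), 1, prob = a)
    r <- network$reactions[[i]]
    for (s in names(r$reactants)) x[[s]] <- x[[s]] - r$reactants[[s]]
    for (s in names(r$products)) x[[s]] <- x[[s]] + r$products[[s]]
  }
  x
}

# Closed-form solution of the two-species mass action system
#   diamide' = -k * diamide * GSH,  GSH' = -2 * k * diamide * GSH
# (GSH - 2*diamide is conserved; the reduced ODE is logistic).
oracle_diamide_gsh <- function(d0, g0, k, t) {
  c0 <- g0 - 2 * d0
  if (abs(c0) < 1e-15) {
    d <- d0 / (1 + 2 * k * d0 * t)
    return(list(diamide = d, GSH = 2 * d))
  }
  # d(t) = c0 * d0 * exp(-k*c0*t) / (g0 - 2*d0*exp(-k*c0*t)) -- derived by
  # separating variables of d' = -k d (2d + c0)
  e <- exp(-k * c0 * t)
  d <- c0 * d0 * e / (g0 - 2 * d0 * e)
  list(diamide = d, GSH = 2 * d + c0)
}
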