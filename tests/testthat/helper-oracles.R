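# Independent brute-force reference implementations used as test oracles.
# These are deliberately written differently from the package code paths.

# --- recursive reference RDP ----------------------------------------------
# distance from point p to the infinite line through a-b, via vector
# rejection (the package uses the cross-product formula and an explicit
# stack)
ref_point_line_dist <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(sum((p - a)^2)))
  u <- ab / sqrt(L2)
  ap <- p - a
  rej <- ap - sum(ap * u) * u
  sqrt(sum(rej^2))
}

ref_rdp_indices <- function(pts, eps, i = 1, j = nrow(pts)) {
  if (j - i < 2) return(c(i, j))
  d <- vapply((i + 1):(j - 1), function(k)
    ref_point_line_dist(pts[k, ], pts[i, ], pts[j, ]), numeric(1))
  k <- (i:j)[which.max(d) + 1]
  if (max(d) > eps) {
    as.integer(sort(unique(c(ref_rdp_indices(pts, eps, i, k),
                             ref_rdp_indices(pts, eps, k, j)))))
  } else {
    as.integer(c(i, j))
  }
}

# --- turning angle via rotation matrices ----------------------------------
# the signed angle a such that rotating the normalized incoming segment by a
# gives the normalized outgoing segment; recovered from the rotation matrix
# entries rather than from atan2 of cross/dot
ref_turning_angle <- function(p1, p2, p3) {
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  v <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  # rotation taking u to v: columns of R in the basis (u, perp(u))
  ct <- sum(u * v)
  st <- u[1] * v[2] - u[2] * v[1]
  ang <- acos(max(-1, min(1, ct)))
  if (st < 0) ang <- -ang
  ang
}

# --- naive sliding-window turns per minute --------------------------------
ref_turns_per_minute <- function(ind, window = 120) {
  n <- length(ind)
  sums <- numeric(n - window + 1)
  for (s in seq_len(n - window + 1))
    sums[s] <- sum(ind[s:(s + window - 1)])
  mean(sums)
}

# --- batch joint-Gaussian Kalman oracle -----------------------------------
# The filtered state mean E[x_j | y_2..y_j] computed by building the full
# joint Gaussian of states and observations and conditioning, O(n^3);
# independent of the forward recursion.
ref_kalman_means <- function(z, dt, process_sd, measurement_sd) {
  n <- nrow(z)
  FF <- rbind(c(1, 0, dt, 0), c(0, 1, 0, dt), c(0, 0, 1, 0), c(0, 0, 0, 1))
  Q <- diag(c(0, 0, process_sd^2, process_sd^2))
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  R <- diag(max(measurement_sd^2, 1e-12), 2)
  m0 <- c(z[1, ], 0, 0)
  P0 <- diag(c(measurement_sd^2, measurement_sd^2, 1, 1))
  # joint prior over stacked states x_1..x_n
  mu <- matrix(0, n, 4)
  mu[1, ] <- m0
  for (j in 2:n) mu[j, ] <- FF %*% mu[j - 1, ]
  Sig <- matrix(0, 4 * n, 4 * n)
  blk <- function(i, j) list(r = (4 * (i - 1) + 1):(4 * i),
                             c = (4 * (j - 1) + 1):(4 * j))
  b <- blk(1, 1); Sig[b$r, b$c] <- P0
  for (j in 2:n) {
    # cross-covariances with all earlier states, then the diagonal block
    for (k in 1:(j - 1)) {
      bk <- blk(j - 1, k)
      bj <- blk(j, k)
      Sig[bj$r, bj$c] <- FF %*% Sig[bk$r, bk$c]
      Sig[bj$c, bj$r] <- t(Sig[bj$r, bj$c])
    }
    bjm <- blk(j - 1, j - 1); bj <- blk(j, j)
    Sig[bj$r, bj$c] <- FF %*% Sig[bjm$r, bjm$c] %*% t(FF) + Q
  }
  out <- matrix(0, n, 4)
  out[1, ] <- m0
  for (j in 2:n) {
    # observe y_2..y_j, condition x_j on them
    obs <- 2:j
    Hbig <- matrix(0, 2 * length(obs), 4 * n)
    for (ii in seq_along(obs)) {
      bo <- blk(obs[ii], 1)
      Hbig[(2 * ii - 1):(2 * ii), (4 * (obs[ii] - 1) + 1):(4 * obs[ii])] <- H
    }
    Rbig <- diag(rep(diag(R)[1], 2 * length(obs)))
    ymean <- Hbig %*% as.vector(t(mu))
    S <- Hbig %*% Sig %*% t(Hbig) + Rbig
    bj <- blk(j, j)
    Cxy <- Sig[bj$r, , drop = FALSE] %*% t(Hbig)
    yvec <- as.vector(t(z[obs, , drop = FALSE]))
    out[j, ] <- mu[j, ] + Cxy %*% solve(S, yvec - ymean)
  }
  out
}

# --- direct inward/outward classification ---------------------------------
ref_classify <- function(prev, cur, nxt, center) {
  angle_between <- function(a, b)
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
  u <- center - cur
  th1 <- angle_between(cur - prev, u)
  th2 <- angle_between(nxt - cur, u)
  if (th2 < th1 - 1e-12) "inward" else "outward"
}

# random-walk track generator for oracle comparisons
random_walk_pts <- function(n, step = 1.5) {
  ang <- cumsum(stats::runif(n - 1, -1, 1))
  rbind(c(0, 0), cbind(cumsum(step * cos(ang)), cumsum(step * sin(ang))))
}
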