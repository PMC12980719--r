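# Independent oracles and small geometry helpers used across the suite.

# Apply a random rigid motion (proper rotation + translation) to a geometry.
rigid_motion <- function(geometry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tr <- stats::runif(3, -3, 3)
  xyz <- sweep(coords(geometry) %*% t(R), 2, tr, "+")
  out <- geometry
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  list(geometry = out, rotation = R, translation = tr)
}

mirror_geometry <- function(geometry) {
  out <- geometry
  out$z <- -out$z
  out
}

# --- independent bond-order oracle: exhaustive enumeration -----------------
# Reimplements the valence-charge score from first principles (tiny valence
# table, w_v = 4, w_q = 1) and enumerates every order pattern on the
# adjustable (non-metal) bonds, returning the minimum-penalty pattern with
# lexicographic tie-break. Only usable for <= 8 adjustable bonds.
oracle_valences <- list(H = 1, C = 4, N = 3, O = 2, F = 1, Cl = c(1, 3, 5, 7),
                        S = c(2, 4, 6), P = c(3, 5))
oracle_metals <- c("Cr", "Fe", "Mo", "W", "Na", "K", "Li", "Mg", "Ca")

oracle_pattern_penalty <- function(elements, bonds_ij, orders) {
  s <- numeric(length(elements))
  for (r in seq_len(nrow(bonds_ij))) {
    s[bonds_ij$i[r]] <- s[bonds_ij$i[r]] + orders[r]
    s[bonds_ij$j[r]] <- s[bonds_ij$j[r]] + orders[r]
  }
  p <- 0
  for (a in seq_along(elements)) {
    v <- oracle_valences[[elements[a]]]
    if (is.null(v)) next
    vstar <- v[which.min(abs(s[a] - v))]
    p <- p + 4 * abs(s[a] - vstar) + 1 * abs(s[a] - vstar)
  }
  p
}

oracle_bond_orders <- function(elements, bonds_ij) {
  n_b <- nrow(bonds_ij)
  adjustable <- !(elements[bonds_ij$i] %in% oracle_metals |
                    elements[bonds_ij$j] %in% oracle_metals)
  n_adj <- sum(adjustable)
  stopifnot(n_adj <= 8)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:3), n_adj)))
  best <- NULL; best_p <- Inf
  for (g in seq_len(nrow(grid))) {
    orders <- rep(1, n_b)
    orders[adjustable] <- grid[g, ]
    p <- oracle_pattern_penalty(elements, bonds_ij, orders)
    key <- paste(orders, collapse = ",")
    if (p < best_p || (p == best_p && key < paste(best, collapse = ","))) {
      best_p <- p; best <- orders
    }
  }
  list(orders = best, penalty = best_p)
}

# --- independent dihedral oracle: Rodrigues rotation fitting ---------------
# Finds the rotation angle about the central axis that maps the projected
# first bond direction onto the projected last bond direction, by coarse
# grid search refined with optimize(); independent of the atan2 route.
oracle_dihedral <- function(p1, p2, p3, p4) {
  ax <- (p3 - p2); ax <- ax / sqrt(sum(ax^2))
  proj <- function(v) v - sum(v * ax) * ax
  u <- proj(p1 - p2); u <- u / sqrt(sum(u^2))
  w <- proj(p4 - p3); w <- w / sqrt(sum(w^2))
  rodrigues <- function(v, th) {
    v * cos(th) + pracma_cross(ax, v) * sin(th) + ax * sum(ax * v) *
      (1 - cos(th))
  }
  mis <- function(th) sum((rodrigues(u, th) - w)^2)
  grid <- seq(-pi, pi, length.out = 721)
  k <- which.min(vapply(grid, mis, numeric(1)))
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(mis, c(lo, hi), tol = 1e-12)
  # parabolic-vertex refinement: the misfit is locally quadratic, so the
  # three-point vertex recovers the minimum far below optimize()'s floor
  t0 <- opt$minimum; h <- 1e-4
  fm <- mis(t0 - h); f0 <- mis(t0); fp <- mis(t0 + h)
  denom <- fp - 2 * f0 + fm
  if (denom > 0) t0 <- t0 - h / 2 * (fp - fm) / denom
  th <- t0 * 180 / pi
  if (th <= -180) th <- th + 360
  th
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# --- brute-force RMSD oracle ----------------------------------------------
# Minimizes RMSD over explicit Euler-angle rotations (multi-start Nelder-
# Mead after centroid removal); slow but independent of the SVD route.
oracle_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rotmat <- function(e) {
    cx <- cos(e[1]); sx <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    cz <- cos(e[3]); sz <- sin(e[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(e) sqrt(mean(rowSums((A %*% t(rotmat(e)) - B)^2)))
  best <- Inf
  for (s in seq_len(8)) {
    start <- c(s * 0.7, s * 1.1, s * 1.9) %% (2 * pi)
    opt <- stats::optim(start, f, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  best
}

write_temp_xyz <- function(geometries, comments = NULL) {
  path <- tempfile(fileext = ".xyz")
  write_xyz(geometries, path, comments)
  path
}
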