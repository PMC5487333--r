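# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops and direct formula evaluation only.

# |phi| at every voxel = Euclidean distance (physical units) to the nearest
# voxel of the opposite label; negative inside.
bf_signed_distance <- function(mask, spacing = 1) {
  d <- dim(mask)
  if (length(spacing) == 1) spacing <- rep(spacing, length(d))
  idx <- as.matrix(expand.grid(lapply(d, seq_len)))
  pos <- sweep(idx, 2, spacing, `*`)
  inside <- as.vector(mask) > 0.5
  out <- numeric(nrow(idx))
  for (v in seq_len(nrow(idx))) {
    opp <- if (inside[v]) !inside else inside
    dd <- sweep(pos[opp, , drop = FALSE], 2, pos[v, ], `-`)
    out[v] <- sqrt(min(rowSums(dd * dd))) * (if (inside[v]) -1 else 1)
  }
  array(out, d)
}

# Pairwise kernel weight between grid points p and q (2D), from the
# continuous Gaussian formula with per-axis truncation at min(3*rho, n-1).
bf_kernel_weight <- function(p, q, rho, d) {
  w <- 1
  for (a in seq_along(d)) {
    u <- abs(p[a] - q[a])
    if (u > min(ceiling(3 * rho), d[a] - 1)) return(0)
    w <- w * gaussian_kernel_value(u, rho, ndim = 1)
  }
  w
}

# Direct double-loop e_i(x) = sum_y Kx(y) |I(x) - f(y)|^2 over the domain,
# with the kernel renormalized to unit mass over the domain at each x.
bf_e_field <- function(I, f, rho) {
  d <- dim(I)
  e <- array(0, d)
  for (x1 in seq_len(d[1])) for (x2 in seq_len(d[2])) {
    acc <- 0; mass <- 0
    for (y1 in seq_len(d[1])) for (y2 in seq_len(d[2])) {
      w <- bf_kernel_weight(c(x1, x2), c(y1, y2), rho, d)
      acc <- acc + w * (I[x1, x2] - f[y1, y2])^2
      mass <- mass + w
    }
    e[x1, x2] <- acc / mass
  }
  e
}

# 1D numerical minimization of the local fitting energy at point y (2D grids):
# f_i(y) minimizes sum_x K(y-x) |I(x) - f|^2 M_i(phi(x)) over the domain.
bf_fit_at_point <- function(I, phi, rho, eps, y, phase) {
  d <- dim(I)
  obj <- function(fv) {
    acc <- 0
    for (x1 in seq_len(d[1])) for (x2 in seq_len(d[2])) {
      w <- bf_kernel_weight(y, c(x1, x2), rho, d)
      if (w == 0) next
      H <- 0.5 * (1 + (2 / pi) * atan(phi[x1, x2] / eps))
      m <- if (phase == 1) 1 - H else H
      acc <- acc + w * (I[x1, x2] - fv)^2 * m
    }
    acc
  }
  stats::optimize(obj, range(I), tol = 1e-10)$minimum
}

# Double-loop fusion energy.
bf_fusion_energy <- function(phi, lsfs, weights) {
  total <- 0
  for (i in seq_along(lsfs))
    for (v in seq_along(phi))
      total <- total + weights[[i]][v] * (phi[v] - lsfs[[i]][v])^2
  total
}

# Boundary voxels (opposite-valued face neighbour; grid edge = outside), as
# an index matrix. Written with explicit neighbour loops.
bf_boundary <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  pts <- which(mask > 0.5, arr.ind = TRUE)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  keep <- logical(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    for (a in seq_len(nd)) for (s in c(-1, 1)) {
      q <- p; q[a] <- q[a] + s
      if (any(q < 1) || any(q > d)) { keep[k] <- TRUE
      } else if (mask[matrix(q, 1)] < 0.5) keep[k] <- TRUE
    }
  }
  pts[keep, , drop = FALSE]
}

# All-pairs Hausdorff distance over boundary point sets.
bf_hausdorff <- function(A, B, spacing = 1) {
  d <- dim(A)
  if (length(spacing) == 1) spacing <- rep(spacing, length(d))
  pa <- sweep(bf_boundary(A), 2, spacing, `*`)
  pb <- sweep(bf_boundary(B), 2, spacing, `*`)
  directed <- function(P, Q) {
    mx <- 0
    for (i in seq_len(nrow(P))) {
      dd <- sweep(Q, 2, P[i, ], `-`)
      mx <- max(mx, sqrt(min(rowSums(dd * dd))))
    }
    mx
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Central difference along the first axis with reflective padding (matrix).
central_diff_oracle <- function(m) {
  n <- nrow(m)
  up <- m[c(2, 1:(n - 1)), , drop = FALSE]; up[1, ] <- m[2, ]
  dn <- m[c(2:n, n - 1), , drop = FALSE]; dn[n, ] <- m[n - 1, ]
  (dn - up) / 2
}

# Random binary mask with at least one voxel of each label.
random_mask <- function(d, p = 0.4) {
  repeat {
    m <- array(as.numeric(stats::runif(prod(d)) < p), d)
    if (sum(m) > 0 && sum(m) < prod(d)) return(m)
  }
}
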