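# Independent oracles used to check the package's implementations.
# Each deliberately uses a different algorithm from the code it checks.

# --- rigid-body superposition: brute-force rotation search ------------

.euler_rot <- function(a, b, c) {
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

# Minimum RMSD over proper rotations+translations by grid search over
# Euler angles followed by Nelder-Mead refinement.
oracle_min_rmsd <- function(mobile, reference, grid_step = 20) {
  m <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  r <- sweep(as.matrix(reference), 2, colMeans(reference))
  rmsd_of <- function(p) {
    R <- .euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((m %*% t(R) - r)^2)))
  }
  gs <- grid_step * pi / 180
  best <- NULL; best_v <- Inf
  for (a in seq(0, 2 * pi - gs / 2, by = gs))
    for (b in seq(0, pi, by = gs))
      for (c in seq(0, 2 * pi - gs / 2, by = gs)) {
        v <- rmsd_of(c(a, b, c))
        if (v < best_v) { best_v <- v; best <- c(a, b, c) }
      }
  opt <- optim(best, rmsd_of, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt <- optim(opt$par, rmsd_of, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# --- SASA: Monte-Carlo surface sampling -------------------------------

oracle_mc_sasa <- function(xyz, radii_exp, n_samples = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(rnorm(3 * n_samples), n_samples, 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- u * radii_exp[i] + matrix(xyz[i, ], n_samples, 3, byrow = TRUE)
    acc <- rep(TRUE, n_samples)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & (d2 > radii_exp[j]^2)
    }
    total <- total + 4 * pi * radii_exp[i]^2 * mean(acc)
  }
  total
}

# Analytic buried area for two overlapping spheres (half the accessible
# area lost, i.e. half the sum of the two spherical caps).
analytic_two_sphere_buried <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (2 * pi * R1 * h1 + 2 * pi * R2 * h2) / 2
}

# --- global alignment: exhaustive enumeration -------------------------

# Maximum global alignment score by exhaustive recursion over all
# alignments, affine gaps (each run costs open + len * extend), end gaps
# penalized.  States: 0 = start/match, 1 = gap in a (b consumed),
# 2 = gap in b (a consumed).
oracle_nw_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  rec <- function(i, j, state) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, 0L))
    if (j <= nb) {  # gap in a: align b[j] against a gap
      cost <- if (state == 1L) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, 1L))
    }
    if (i <= na) {  # gap in b
      cost <- if (state == 2L) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# --- plane fitting: direct nonlinear optimisation ---------------------

# Best-fit plane by minimising the sum of squared orthogonal distances
# over a spherical parameterisation of the normal.
oracle_plane_normal <- function(points) {
  obj <- function(p) {
    n <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    ctr <- colMeans(points)
    sum((sweep(as.matrix(points), 2, ctr) %*% n)^2)
  }
  starts <- as.matrix(expand.grid(theta = seq(0.1, pi, length.out = 5),
                                  phi = seq(0, 2 * pi, length.out = 5)))
  best <- NULL; best_v <- Inf
  for (k in seq_len(nrow(starts))) {
    o <- optim(starts[k, ], obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
    if (o$value < best_v) { best_v <- o$value; best <- o$par }
  }
  n <- c(sin(best[1]) * cos(best[2]), sin(best[1]) * sin(best[2]),
         cos(best[1]))
  n / sqrt(sum(n^2))
}

# Angle in degrees between two planes fitted by the optimisation oracle.
oracle_plane_angle <- function(points_a, points_b) {
  na <- oracle_plane_normal(points_a)
  nb <- oracle_plane_normal(points_b)
  acos(min(1, abs(sum(na * nb)))) * 180 / pi
}

# --- small geometry helpers ------------------------------------------

random_rigid_transform <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  list(rotation = .euler_rot(ang[1], ang[2], ang[3]),
       translation = runif(3, -20, 20))
}

# Apply a rigid motion to a structure or coordinate matrix (independent
# of the package's apply_transform).
move_rigid <- function(x, trf) {
  if (is.data.frame(x)) {
    xyz <- as.matrix(x[, c("x", "y", "z")]) %*% t(trf$rotation)
    xyz <- sweep(xyz, 2, trf$translation, "+")
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    x
  } else {
    sweep(as.matrix(x) %*% t(trf$rotation), 2, trf$translation, "+")
  }
}
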