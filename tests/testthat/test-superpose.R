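test_that("superposing a set onto itself gives zero RMSD and the identity", {
  set.seed(1)
  p <- matrix(rnorm(30), 10, 3)
  s <- kabsch(p, p)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("an exact rigid copy is recovered with zero RMSD and the inverse motion", {
  set.seed(2)
  p <- matrix(rnorm(24), 8, 3)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  q <- sweep(p %*% t(R), 2, c(1, 2, 3), "+")
  s <- kabsch(q, p)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  # transform maps q back onto p
  expect_equal(apply_transform(q, s), p, tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD equals the brute-force rotation-search oracle", {
  # 4 points, one displaced by 1 A
  p <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  q <- p; q[4, 3] <- q[4, 3] + 1
  got <- kabsch(q, p)$rmsd
  expect_equal(got, oracle_min_rmsd(q, p), tolerance = 1e-4)
  # small random sets
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(rnorm(18, sd = 3), 6, 3)
    b <- a + matrix(rnorm(18, sd = 0.4), 6, 3)
    expect_equal(kabsch(a, b)$rmsd, oracle_min_rmsd(a, b), tolerance = 1e-4)
  }
})

test_that("RMSD is symmetric, motion-invariant and optimal vs random transforms", {
  set.seed(3)
  a <- matrix(rnorm(18, sd = 3), 6, 3)
  b <- a + matrix(rnorm(18, sd = 0.5), 6, 3)
  expect_equal(kabsch(a, b)$rmsd, kabsch(b, a)$rmsd, tolerance = 1e-9)
  trf <- random_rigid_transform(7)
  expect_equal(kabsch(move_rigid(a, trf), move_rigid(b, trf))$rmsd,
               kabsch(a, b)$rmsd, tolerance = 1e-9)
  # no random rigid transform beats the closed form
  best <- kabsch(a, b)$rmsd
  set.seed(4)
  rand_rmsd <- vapply(1:10000, function(k) {
    ang <- runif(3, 0, 2 * pi)
    R <- matrix(c(cos(ang[1]), -sin(ang[1]), 0,
                  sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
               -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cos(ang[3]), -sin(ang[3]),
               0, sin(ang[3]), cos(ang[3])), 3, 3, byrow = TRUE)
    moved <- a %*% t(R)
    moved <- sweep(moved, 2, colMeans(b) - colMeans(moved), "+")
    sqrt(mean(rowSums((moved - b)^2)))
  }, numeric(1))
  expect_gte(min(rand_rmsd) + 1e-12, best)
})

test_that("kabsch agrees with the bio3d reference implementation", {
  set.seed(5)
  a <- matrix(rnorm(45, sd = 4), 15, 3)
  b <- a + matrix(rnorm(45, sd = 0.8), 15, 3)
  got <- kabsch(a, b)$rmsd
  xyz_a <- matrix(t(a), nrow = 1)
  xyz_b <- matrix(t(b), nrow = 1)
  fitted <- bio3d::fit.xyz(fixed = xyz_b, mobile = xyz_a,
                           fixed.inds = 1:45, mobile.inds = 1:45)
  ref <- sqrt(mean(colSums(matrix((fitted - xyz_b)^2, nrow = 3))))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(0:4, 0, 0)
  expect_error(kabsch(line, line), "degenerate")
  expect_error(kabsch(matrix(rnorm(9), 3, 3), matrix(rnorm(12), 4, 3)),
               "differ in length")
})

test_that("alignment-based pairing emits only mutually aligned residues", {
  tr <- make_ca_trace(30, seed = 9)
  aln <- list(ids = c("a", "b"),
              a_aln = paste(rep("A", 30), collapse = ""),
              b_aln = paste(rep("A", 30), collapse = ""))
  class(aln) <- "aligned_pair"
  pr <- pair_by_alignment(tr, tr, aln)
  expect_equal(nrow(pr$xyz_a), 30)
  expect_equal(pr$xyz_a, pr$xyz_b)
  # a gap column drops exactly that pair
  gap <- list(ids = c("a", "b"),
              a_aln = paste(c(rep("A", 10), "-", rep("A", 20)), collapse = ""),
              b_aln = paste(c(rep("A", 10), "A", rep("A", 19), "-"),
                            collapse = ""))
  class(gap) <- "aligned_pair"
  pr2 <- pair_by_alignment(tr, tr, gap)
  expect_equal(nrow(pr2$xyz_a), 29)
})

test_that("domain superposition reports deviations with an analytic oracle", {
  tr <- make_ca_trace(60, seed = 11)
  d0 <- domain_superpose(tr, tr, c(1, 30), c(31, 60))
  expect_equal(d0$max_deviation, 0, tolerance = 1e-9)
  # rotate the report range by 5 degrees about an axis through the
  # fit-domain centroid; deviation of each point is 2 sin(theta/2) times
  # its distance from the axis
  th <- 5 * pi / 180
  axis <- c(0, 0, 1)
  fit_ca <- as.data.frame(tr)[1:30, ]
  ctr <- colMeans(as.matrix(fit_ca[, c("x", "y", "z")]))
  moved <- as.data.frame(tr)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  rep_xyz <- as.matrix(moved[31:60, c("x", "y", "z")])
  rot <- sweep(sweep(rep_xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  moved[31:60, c("x", "y", "z")] <- rot
  d <- domain_superpose(tr, b12_structure(moved), c(1, 30), c(31, 60))
  perp <- sweep(rep_xyz, 2, ctr)
  r_axis <- sqrt(perp[, 1]^2 + perp[, 2]^2)  # distance from the z-axis
  expected <- 2 * sin(th / 2) * max(r_axis)
  expect_equal(d$max_deviation, expected, tolerance = 1e-6)
  expect_error(domain_superpose(tr, tr, c(100, 120), c(1, 10)), "empty")
})
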