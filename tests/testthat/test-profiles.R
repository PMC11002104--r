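test_that("orientation centers, aligns, and is invariant to rigid motion", {
  u <- random_unit(40, seed = 11)
  un <- orient_unit(u$points, u$h)
  expect_lt(max(abs(colMeans(un$points))), 1e-9)
  cv <- crossprod(un$points) / nrow(un$points)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-6)   # diagonal covariance
  expect_true(all(diff(diag(cv)) <= 1e-9))       # descending variance

  for (s in 1:5) {
    moved <- rigid_motion(u$points, seed = 100 + s)
    un2 <- orient_unit(moved, u$h)
    expect_equal(un2$sigmas, un$sigmas, tolerance = 1e-6)
    # profiles identical up to the (sign-invariant) quantities downstream
    expect_equal(t_profile(un2), t_profile(un), tolerance = 1e-6)
    expect_equal(o_profile(un2), o_profile(un), tolerance = 1e-9)
  }
  expect_error(orient_unit(matrix(1, 4, 3), rep(1, 4)), "coincident")
})

test_that("sigma estimation follows the extent/3 rule with a floor", {
  pts <- rbind(c(9, 0, 0), c(-9, 0, 0), c(0, 3, 0), c(0, -3, 0))
  expect_equal(estimate_sigmas(pts, floor = 0), c(3, 1, 0))
  expect_equal(estimate_sigmas(pts, floor = 1), c(3, 1, 1))  # planar: floored
  expect_equal(estimate_sigmas(pts, floor = 0, rule = "extent6"), c(1.5, 0.5, 0))

  # unit-sphere surface sample: extent/3 concentrates near 1/3
  set.seed(42)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  s <- estimate_sigmas(dirs, floor = 0)
  expect_true(all(s >= 0.28 & s <= 0.36))
})

test_that("theoretical profile matches the closed-form Gaussian ratios", {
  # two residues mirror-symmetric about the origin
  un <- orient_unit(rbind(c(-3, 0, 0), c(3, 0, 0)), c(0.2, 0.9))
  expect_equal(t_profile(un), c(0.5, 0.5))

  # hand-built oriented unit: residues at origin and at 3 sigma on x
  unit <- structure(list(points = rbind(c(0, 0, 0), c(3, 0, 0)),
                         h = c(1, 1), labels = c("1", "2"),
                         sigmas = c(1, 1, 1)), class = "oriented_unit")
  t <- t_profile(unit)
  expect_equal(t[1] / t[2], exp(4.5), tolerance = 1e-12)
  expect_equal(sum(t), 1)
})

test_that("observed profile matches the scalar brute-force oracle", {
  for (s in 1:6) {
    n <- sample(10:50, 1)
    u <- random_unit(n, seed = 1000 + s)
    un <- orient_unit(u$points, u$h)
    expect_equal(o_profile(un, cutoff = 9),
                 o_profile_oracle(un$points, un$h, cutoff = 9),
                 tolerance = 1e-12)
    expect_equal(o_profile(un, cutoff = 9, include_self = TRUE),
                 o_profile_oracle(un$points, un$h, 9, include_self = TRUE),
                 tolerance = 1e-12)
  }
  # three collinear residues, one hydrophobic end
  un <- orient_unit(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)), c(1, 0, 0))
  expect_equal(o_profile(un, 9), o_profile_oracle(un$points, un$h, 9),
               tolerance = 1e-12)
})

test_that("the interaction weight vanishes at the cutoff and peaks at contact", {
  # residues exactly at the cutoff: weight polynomial has a root there,
  # so no pair interacts and the observed profile is degenerate
  un <- orient_unit(rbind(c(0, 0, 0), c(9, 0, 0)), c(1, 1))
  expect_error(o_profile(un, cutoff = 9), "degenerate")
  # near-zero separation: weight -> 1, equal sharing
  un2 <- orient_unit(rbind(c(0, 0, 0), c(1e-4, 0, 0)), c(0.3, 0.8))
  expect_equal(o_profile(un2, 9), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("uniform reference is 1/n and rejects empty units", {
  expect_equal(r_profile(4), rep(0.25, 4))
  expect_equal(r_profile(1), 1)
  expect_equal(sum(r_profile(137)), 1)
  expect_error(r_profile(0), "n >= 1")
})

test_that("modified field follows the double-normalization convention", {
  t <- c(0.5, 0.3, 0.2)
  expect_equal(m_profile(t, 0), t)                       # K = 0: pure water
  expect_equal(m_profile(t, 1), c(0.25, 0.35, 0.40))     # hand computation
  cn <- c(0, 0.2, 0.3) / 0.5
  expect_equal(m_profile(t, 1e6), cn, tolerance = 1e-5)  # K -> inf: complement
  expect_error(m_profile(t, -0.1), ">= 0")
  # uniform T has no complement
  expect_equal(m_profile(rep(0.25, 4), 3), rep(0.25, 4))
})

test_that("modified field moves monotonically toward the complement in K", {
  norm1 <- function(v) v / sum(v)
  set.seed(7)
  for (trial in 1:10) {
    t <- norm1(runif(30))
    cn <- norm1(max(t) - t)
    ks <- seq(0, 5, by = 0.25)
    d <- vapply(ks, function(k) sum(abs(m_profile(t, k) - cn)), numeric(1))
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("every profile sums to one and is nonnegative", {
  for (s in 1:10) {
    u <- random_unit(25, seed = 2000 + s)
    un <- orient_unit(u$points, u$h)
    for (p in list(t_profile(un), o_profile(un, 9), r_profile(25),
                   m_profile(t_profile(un), runif(1, 0, 3)))) {
      expect_equal(sum(p), 1, tolerance = 1e-9)
      expect_true(all(p >= 0))
    }
  }
})
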