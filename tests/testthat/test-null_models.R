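# Analytic and Monte-Carlo reference models.

test_that("random orientation reference: mean 1 radian, median 60", {
  ref <- random_orientation_reference()
  expect_equal(ref$mean_deg, 57.29578, tolerance = 1e-5)
  expect_equal(ref$median_deg, 60)
  # density integrates to 1 on [0, 90]
  expect_equal(integrate(ref$density, 0, 90)$value, 1, tolerance = 1e-6)

  # Monte-Carlo convergence to the analytic mean
  set.seed(1)
  v <- random_unit_vectors(1e6)
  ang <- acos(pmin(1, abs(v[, 3]))) * 180 / pi
  expect_lt(abs(mean(ang) - 180 / pi), 0.05)
})

test_that("random branching angles reproduce the sorted-rank moments", {
  ref <- random_branching_angle_reference(1e5, seed = 3)
  expect_lt(abs(ref$means[1] - 53.6), 0.5)
  expect_lt(abs(ref$means[2] - 95.3), 0.5)
  expect_lt(abs(ref$means[3] - 121.1), 0.5)
  expect_lt(abs(ref$sds[1] - 24.4), 0.5)
  expect_lt(abs(ref$sds[2] - 27.1), 0.5)
  expect_lt(abs(ref$sds[3] - 30.9), 0.5)
  # pairwise-mean symmetry: sorted means sum to 270 (3 MC standard errors)
  se <- sd(rowSums(ref$angles)) / sqrt(nrow(ref$angles))
  expect_lt(abs(sum(ref$means) - 270), 3 * se)
})

test_that("sorted-mean sum stays at 270 for smaller samples too", {
  for (n in c(1e3, 1e4)) {
    ref <- random_branching_angle_reference(n, seed = 11)
    se <- sd(rowSums(ref$angles)) / sqrt(n)
    expect_lt(abs(sum(ref$means) - 270), 3 * se)
  }
})

test_that("rigid-rod wall model hits its limits and matches rejection MC", {
  expect_equal(rigid_rod_orientation_model(15.4, 10), 180 / pi,
               tolerance = 1e-9)        # d >= L/2: unconstrained
  expect_equal(rigid_rod_orientation_model(15.4, 0), 90, tolerance = 1e-6)
  an <- rigid_rod_orientation_model(15.4, 15.4 / 4)
  mc <- rigid_rod_orientation_model(15.4, 15.4 / 4, n = 4e5, seed = 5,
                                    method = "mc")
  expect_lt(abs(an - mc), 0.2)
  # monotone decreasing in distance up to L/2, constant after
  ds <- seq(0, 7.7, length.out = 20)
  ms <- sapply(ds, function(d) rigid_rod_orientation_model(15.4, d))
  expect_true(all(diff(ms) <= 1e-9))
  expect_equal(rigid_rod_orientation_model(15.4, 7.8),
               rigid_rod_orientation_model(15.4, 20), tolerance = 1e-12)
})

test_that("buckling force follows the Euler formula", {
  expect_equal(buckling_force(0.040, 1), pi^2 * 0.040, tolerance = 1e-12)
  expect_equal(round(buckling_force(0.040, 1), 1), 0.4)
  expect_equal(buckling_force(0.040, 2), buckling_force(0.040, 1) / 4,
               tolerance = 1e-12)
  expect_equal(buckling_force(0, 1), 0)
})

test_that("tortuosity base angle inverts the isosceles triangle", {
  expect_equal(tortuosity_base_angle(1), 0)
  expect_equal(round(tortuosity_base_angle(1.15)), 30)
  expect_equal(tortuosity_base_angle(2), 60, tolerance = 1e-9)
  expect_error(tortuosity_base_angle(0.9), ">= 1")
})

test_that("random branch-end reference is deterministic and calibrated", {
  # degenerate shell of 2 voxels
  dims <- c(10, 10, 10)
  shell <- c(1L, 10L)   # linear indices: (1,1,1) and (10,1,1)
  r1 <- random_branch_end_reference(shell, dims, pitch = 2, n_points = 2,
                                    n_reps = 5, seed = 3)
  r2 <- random_branch_end_reference(shell, dims, pitch = 2, n_points = 2,
                                    n_reps = 5, seed = 3)
  expect_identical(r1, r2)
  expect_error(random_branch_end_reference(shell, dims, 2, n_points = 1),
               "at least 2")

  # 2D Poisson limit: mean NN distance ~ 1/(2 sqrt(lambda)) on a thin slab
  dims <- c(100, 100, 1)
  shell <- seq_len(100 * 100)
  n_pts <- 200
  area <- (100 * 2)^2
  lambda <- n_pts / area
  ref <- random_branch_end_reference(shell, dims, pitch = 2,
                                     n_points = n_pts, n_reps = 30, seed = 9)
  expect_lt(abs(ref$mean - 1 / (2 * sqrt(lambda))) / (1 / (2 * sqrt(lambda))),
            0.10)
})
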