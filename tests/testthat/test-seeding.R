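r_toy <- 0.45 / 0.67625   # dynamic radius of the 4-point worked example

test_that("dynamic radius parameter model evaluates as printed", {
  expect_equal(dynamic_T(2, 0.45, 1, 0.2), 0.67625)
  expect_equal(dynamic_T(3, 0.5, 1, 0.1), 0.7806)
  # degenerate all-duplicate data drive T negative -> configuration error
  expect_error(dynamic_T(1, 0, 0, 0), "manual")
})

test_that("dynamic radius is the T-scaled mean dissimilarity", {
  expect_equal(dynamic_radius(0.45, 0.67625), 0.45 / 0.67625)
  expect_equal(dynamic_radius(0.37, 1), 0.37)     # T = 1 identity
  expect_equal(dynamic_radius(0, 2), 0)           # duplicates downstream error
  expect_error(dynamic_radius(0.45, 0), "positive")
  expect_error(dynamic_radius(0.45, -1), "positive")
})

test_that("density counts the point itself and respects the active subset", {
  D <- toy_d()
  expect_equal(dissimilarity_density(D, r_toy), c(2L, 3L, 3L, 2L))
  expect_equal(dissimilarity_density(D, r = 1.5), rep(4L, 4))  # r >= max_d
  expect_equal(dissimilarity_density(D, r_toy, active = 3L), 1L)
  expect_error(dissimilarity_density(D, r = 0), "positive")
})

test_that("candidate-cluster alpha averages pairs over the neighbourhood", {
  D <- toy_d()
  expect_equal(candidate_alpha(D, r_toy, i = 2), 2 * (0.2 + 0.8 + 0.6) / 9)
  expect_equal(candidate_alpha(D, r_toy, i = 1, active = 1L), 0)  # singleton
  expect_equal(candidate_alpha(matrix(0, 3, 3), r = 1, i = 1), 0) # coincident
})

test_that("separation s follows the higher-density rule", {
  D <- toy_d()
  rho <- dissimilarity_density(D, r_toy)
  expect_equal(candidate_s(D, rho, i = 1), 0.2)    # nearest higher-density
  expect_equal(candidate_s(D, rho, i = 2), 0.8)    # density peak -> max
  expect_equal(candidate_s(D, rho = 1L, i = 3, active = 3L), 0)
})

test_that("weights combine density, compactness and separation", {
  alpha2 <- 2 * (0.2 + 0.8 + 0.6) / 9
  expect_equal(dissimilarity_weight(3, alpha2, 0.8), 6.75)
  expect_equal(dissimilarity_weight(2, 0, 0.5), 0)   # singleton convention
  expect_equal(dissimilarity_weight(1, 0.3, 0), 0)
})

test_that("first-centre selection breaks density ties by sum then index", {
  D <- toy_d()
  rho <- dissimilarity_density(D, r_toy)
  expect_equal(select_first_center(D, rho, r_toy), 2L)  # sums tie at 0.8
  # unique maximum: no tie-break needed
  expect_equal(select_first_center(D, c(1L, 5L, 2L, 1L), r_toy), 2L)
  # everything tied everywhere -> lowest index
  D0 <- matrix(0.5, 3, 3); diag(D0) <- 0
  expect_equal(select_first_center(D0, rep(3L, 3), r = 1), 1L)
})

test_that("the selection loop reproduces the worked example", {
  sd <- select_centers(toy_d(), r_toy)
  expect_equal(sd$centers, c(2L, 4L))
  expect_equal(sd$k, 2L)
  expect_equal(sd$removal_round, c(1L, 1L, 1L, 2L))
  expect_false(any(sd$noise))
  # round-1 densities on the full set; point 4 re-evaluated alone in round 2
  expect_equal(sd$rho, c(2, 3, 3, 1))
})

test_that("extreme radii give the expected cluster counts", {
  D <- toy_d()
  expect_equal(select_centers(D, r = 1.5)$k, 1L)       # absorbs everything
  # far-separated duplicate pairs with r between the two scales
  x <- cbind(c(0, 0.1, 10, 10.1))
  expect_equal(select_centers(dissimilarity_matrix(x), r = 0.5)$k, 2L)
  expect_error(select_centers(D, r = 0), "positive")
})

test_that("strict-mode removal rounds partition the samples within radius", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(10:40, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    D <- dissimilarity_matrix(x)
    r <- runif(1, 0.1, 1.2)
    sd <- select_centers(D, r)
    expect_true(all(sd$removal_round >= 1))           # everyone removed once
    expect_true(all(!is.na(sd$removal_round)))
    expect_true(all(sd$rho >= 1))
    # each point is within r of the centre selected in its removal round
    for (i in seq_len(n)) {
      ctr <- sd$centers[sd$removal_round[i]]
      expect_lte(unclass(D)[ctr, i], r)
    }
    # determinism
    expect_identical(sd$centers, select_centers(D, r)$centers)
  }
})

test_that("density is monotone non-decreasing in the radius", {
  set.seed(5)
  x <- matrix(rnorm(60), 30, 2)
  D <- dissimilarity_matrix(x)
  radii <- sort(runif(6, 0.05, 2))
  prev <- dissimilarity_density(D, radii[1])
  for (r in radii[-1]) {
    cur <- dissimilarity_density(D, r)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("density, alpha and s match their brute-force oracles", {
  set.seed(99)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    D <- unclass(dissimilarity_matrix(matrix(rnorm(n * 3), n, 3)))
    r <- runif(1, 0.2, 1.5)
    active <- sort(sample(n, sample(2:n, 1)))
    rho <- dissimilarity_density(D, r, active)
    expect_equal(rho, naive_density(D, r, active))
    for (i in sample(active, min(4, length(active)))) {
      expect_equal(candidate_alpha(D, r, i, active),
                   naive_alpha(D, r, i, active), tolerance = 1e-12)
      expect_equal(candidate_s(D, rho, i, active),
                   naive_s(D, rho, i, active), tolerance = 1e-12)
    }
  }
})

test_that("robust mode flags isolated points instead of seeding them", {
  # two tight pairs plus one far outlier
  x <- cbind(c(0, 0.05, 10, 10.05, 30))
  D <- dissimilarity_matrix(x)
  sd <- select_centers(D, r = 0.1, mode = "robust")
  expect_equal(sd$k, 2L)
  expect_equal(which(sd$noise), 5L)
  expect_equal(sd$omega[5], 0)
  # strict mode promotes the outlier to a centre instead
  expect_equal(select_centers(D, r = 0.1, mode = "strict")$k, 3L)
  # all-isolated data cannot seed robustly
  expect_error(select_centers(D, r = 0.001, mode = "robust"), "isolated")
})
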