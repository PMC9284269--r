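test_that("blob generator honours the spec of each cluster", {
  b <- make_blobs(k = 1, points_per_cluster = 30, noise_fraction = 0,
                  seed = 5)
  expect_true(all(b$labels == "1"))
  expect_equal(dim(b$x), c(30L, 3L))
  # reproducibility
  b2 <- make_blobs(k = 3, points_per_cluster = 20, seed = 9)
  b3 <- make_blobs(k = 3, points_per_cluster = 20, seed = 9)
  expect_identical(b2, b3)
  # group means near the generating centroids at n = 150
  b4 <- make_blobs(k = 3, points_per_cluster = 50, separation = 8,
                   within_sd = 1, seed = 21)
  for (cl in 1:3) {
    mu <- colMeans(b4$x[b4$labels == as.character(cl), ])
    expect_lt(sqrt(sum((mu - b4$centroids[cl, ])^2)), 0.5)
  }
  # centroids respect the separation constraint
  expect_gte(min(dist(b4$centroids)), 8)
})

test_that("noise points are uniform over an inflated bounding box", {
  b <- make_blobs(k = 3, points_per_cluster = 50, noise_fraction = 0.05,
                  seed = 13)
  expect_equal(sum(b$labels == "noise"), round(0.05 * 150))
  noise <- b$x[b$labels == "noise", , drop = FALSE]
  signal <- b$x[b$labels != "noise", , drop = FALSE]
  lo <- apply(signal, 2, min); hi <- apply(signal, 2, max)
  pad <- 0.2 * (hi - lo)
  expect_true(all(t(noise) >= lo - pad - 1e-9 & t(noise) <= hi + pad + 1e-9))
})

test_that("count generator moments match the configured means", {
  # large dispersion, no dropout: NB is near-Poisson, sample means tight
  sim <- make_counts(k = 2, cells_per_cluster = 200, n_genes = 60,
                     n_marker_genes = 5, base_mean = 4, fold_change = 6,
                     dispersion = 1e4, dropout_rate = 0, seed = 17)
  expect_identical(sim$counts,
                   make_counts(k = 2, cells_per_cluster = 200, n_genes = 60,
                               n_marker_genes = 5, base_mean = 4,
                               fold_change = 6, dispersion = 1e4,
                               dropout_rate = 0, seed = 17)$counts)
  c1 <- sim$counts[sim$labels == "1", ]
  # background gene in cluster 1: mean 4 within 3 standard errors
  se <- sqrt(4 / 200)
  expect_lt(abs(mean(c1[, 30]) - 4), 3 * se)
  # cluster-1 marker block elevated to base * fold
  se_m <- sqrt(24 / 200)
  expect_lt(abs(mean(c1[, 1]) - 24), 3 * se_m)
  # the same marker stays at baseline in cluster 2
  c2 <- sim$counts[sim$labels == "2", ]
  expect_lt(abs(mean(c2[, 1]) - 4), 3 * se)
})

test_that("dropout thins counts and fold_change 1 removes all signal", {
  sim <- make_counts(k = 2, cells_per_cluster = 100, n_genes = 40,
                     base_mean = 5, dropout_rate = 0.5, seed = 3)
  sim0 <- make_counts(k = 2, cells_per_cluster = 100, n_genes = 40,
                      base_mean = 5, dropout_rate = 0, seed = 3)
  expect_lt(mean(sim$counts), mean(sim0$counts) * 0.6)
  # null generator: marker block indistinguishable between clusters
  null <- make_counts(k = 2, cells_per_cluster = 150, n_genes = 30,
                      n_marker_genes = 5, base_mean = 5, fold_change = 1,
                      dispersion = 1e4, dropout_rate = 0, seed = 8)
  m1 <- mean(null$counts[null$labels == "1", 1:5])
  m2 <- mean(null$counts[null$labels == "2", 1:5])
  expect_lt(abs(m1 - m2), 4 * sqrt(5 / 750) * 2)
  expect_error(make_counts(k = 3, n_genes = 20, n_marker_genes = 10),
               "marker blocks")
})
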