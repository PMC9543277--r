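test_that("distance-band weights reproduce the collinear hand example", {
  pts <- cbind(c(0, 150, 300), 0)
  w <- distance_band_weights(pts, 200)
  expect_equal(w$neighbors, list(2L, c(1L, 3L), 2L))
  expect_equal(w$weights[[2]], c(0.5, 0.5))
  expect_equal(w$weights[[1]], 1)
  Wm <- weights_matrix(w)
  expect_equal(rowSums(Wm), c(1, 1, 1))
  expect_equal(diag(Wm), c(0, 0, 0))
})

test_that("isolated points become zero rows and are flagged", {
  pts <- cbind(c(0, 100, 5000), 0)
  w <- distance_band_weights(pts, 200)
  expect_equal(w$islands, 3L)
  expect_equal(sum(weights_matrix(w)[3, ]), 0)
  expect_error(distance_band_weights(cbind(c(0, 5000), 0), 200), "island")
  expect_warning(distance_band_weights(cbind(c(0, 0, 300), c(0, 0, 0)), 200),
                 "duplicate")
})

test_that("interior cells of the global-scale lattice get six neighbours at 200 km", {
  g <- build_planar_hex_grid(c(0, 2500, 0, 2500), 23323)
  spacing <- sqrt(3) * g$side
  expect_equal(spacing, 164.1, tolerance = 1e-3)  # centroid spacing ~164 km
  w <- distance_band_weights(g$centroids, 200)
  expect_equal(max(w$degree), 6)
  # second neighbour ring sits at spacing * sqrt(3) ~ 284 km, beyond the band
  expect_gt(spacing * sqrt(3), 200)
  xr <- range(g$centroids[, 1]); yr <- range(g$centroids[, 2])
  interior <- g$centroids[, 1] > xr[1] + 2 * spacing &
    g$centroids[, 1] < xr[2] - 2 * spacing &
    g$centroids[, 2] > yr[1] + 2 * spacing &
    g$centroids[, 2] < yr[2] - 2 * spacing
  expect_true(all(w$degree[interior] == 6))
})

test_that("great-circle weights respect spherical distances", {
  # one degree of latitude on the authalic sphere is ~111.2 km
  pts <- cbind(c(0, 0, 0), c(0, 1, 3))
  w <- distance_band_weights(pts, 120, metric = "great_circle")
  expect_equal(w$neighbors[[1]], 2L)
  expect_equal(w$neighbors[[3]], integer(0))
})

test_that("OLS matches the normal-equations oracle and its exact cases", {
  set.seed(50)
  X <- cbind(1, rnorm(50), runif(50))
  colnames(X) <- c("(Intercept)", "a", "b")
  y <- drop(X %*% c(2, -1, 3)) + rnorm(50)
  fit <- ols_fit(y, X)
  expect_lt(max(abs(fit$beta - oracle_normal_eq_beta(y, X))), 1e-10)
  expect_equal(fit$df, c(2L, 47L))

  y_exact <- drop(X %*% c(1, 2, 3))
  expect_equal(ols_fit(y_exact, X)$r2, 1, tolerance = 1e-12)

  y_const <- rnorm(30)
  fit0 <- ols_fit(y_const, matrix(1, 30, 1))
  expect_equal(unname(fit0$beta), mean(y_const))

  Xbad <- cbind(1, 1:20, 2 * (1:20))
  colnames(Xbad) <- c("(Intercept)", "x", "x_copy")
  expect_error(ols_fit(rnorm(20), Xbad), "x_copy")
})

test_that("eigenvalue log-determinant equals the dense determinant", {
  set.seed(60)
  lat <- lattice_20x20()
  keep <- sample(lat$W$n, 300)
  w <- distance_band_weights(lat$grid$centroids[keep, ],
                             1.4 * sqrt(3) * lat$side)
  omega <- paranet:::weights_eigenvalues(w)
  Wm <- weights_matrix(w)
  for (lam in c(-0.5, 0, 0.3, 0.9)) {
    dense <- determinant(diag(w$n) - lam * Wm, logarithm = TRUE)$modulus
    expect_equal(sum(log(1 - lam * omega)), as.numeric(dense),
                 tolerance = 1e-8)
  }
})

test_that("fixing lambda at zero reproduces the OLS fit", {
  set.seed(61)
  lat <- lattice_20x20()
  X <- cbind(1, rnorm(lat$W$n))
  y <- drop(X %*% c(1, 2)) + rnorm(lat$W$n)
  sar0 <- sar_error_fit(y, X, lat$W, lambda = 0)
  ols <- ols_fit(y, X)
  expect_lt(max(abs(sar0$beta - ols$beta)), 1e-10)
  expect_lt(abs(sar0$logLik - ols$logLik), 1e-10)
  expect_equal(sar0$lr_vs_ols, 0, tolerance = 1e-10)
})

test_that("the concentrated likelihood equals the full likelihood at the optimum", {
  set.seed(62)
  lat <- lattice_20x20()
  X <- cbind(1, rnorm(lat$W$n))
  y <- simulate_sar_response(X, lat$W, c(1, 2), 0.5, 1, seed = 99)
  fit <- sar_error_fit(y, X, lat$W)
  Wm <- weights_matrix(lat$W)
  A <- diag(fit$n) - fit$lambda * Wm
  e <- drop(A %*% (y - drop(X %*% fit$beta)))
  full <- -fit$n / 2 * log(2 * pi * fit$sigma2) -
    sum(e^2) / (2 * fit$sigma2) +
    as.numeric(determinant(A, logarithm = TRUE)$modulus)
  expect_equal(fit$logLik, full, tolerance = 1e-8)
})

test_that("SAR maximum likelihood dominates OLS and reports df = 1", {
  set.seed(63)
  lat <- lattice_20x20()
  X <- cbind(1, rnorm(lat$W$n))
  y <- simulate_sar_response(X, lat$W, c(1, 2), 0.7, 1, seed = 7)
  fit <- sar_error_fit(y, X, lat$W)
  ols <- ols_fit(y, X)
  expect_gte(fit$logLik, ols$logLik)
  expect_gte(fit$lr_vs_ols, 0)
  expect_equal(fit$lr_df, 1L)
  expect_gt(fit$lambda, fit$lambda_bounds[1])
  expect_lt(fit$lambda, fit$lambda_bounds[2])
  expect_error(sar_error_fit(y, X, lat$W, lambda = 2), "lambda must lie")
})

test_that("lambda is recovered from simulated spatial-error data", {
  lat <- lattice_20x20()
  err <- vapply(1:8, function(i) {
    X <- cbind(1, paranet:::with_seed(i, rnorm(lat$W$n)))
    y <- simulate_sar_response(X, lat$W, c(1, 2), 0.6, 1, seed = 500 + i)
    sar_error_fit(y, X, lat$W)$lambda - 0.6
  }, numeric(1))
  expect_lt(median(abs(err)), 0.1)
})

test_that("Nagelkerke R2 follows its formula and is monotone", {
  val <- nagelkerke_r2(-100, -500, 100)
  oracle <- (1 - exp(2 / 100 * (-500 - -100))) / (1 - exp(2 / 100 * -500))
  expect_equal(val, oracle, tolerance = 1e-12)
  expect_equal(nagelkerke_r2(-7, -7, 50), 0)
  expect_gt(nagelkerke_r2(-90, -500, 100), val)
  expect_error(nagelkerke_r2(-600, -500, 100), "logLik_model")
})

test_that("simulated SAR responses are seed-deterministic and autocorrelated", {
  lat <- lattice_20x20()
  X <- cbind(1, seq_len(lat$W$n) / lat$W$n)
  y1 <- simulate_sar_response(X, lat$W, c(1, 2), 0, 1.5, seed = 4)
  y2 <- simulate_sar_response(X, lat$W, c(1, 2), 0, 1.5, seed = 4)
  expect_identical(y1, y2)
  # lambda = 0: residual variance is about sigma^2
  expect_lt(abs(var(y1 - drop(X %*% c(1, 2))) - 1.5^2), 0.5)
  # lambda = 0.7: positive Moran autocorrelation of the spatial error
  Wm <- weights_matrix(lat$W)
  moran <- vapply(1:20, function(i) {
    y <- simulate_sar_response(X, lat$W, c(1, 2), 0.7, 1, seed = 600 + i)
    oracle_moran(y - drop(X %*% c(1, 2)), Wm)
  }, numeric(1))
  expect_true(all(moran > 0))
  expect_gt(mean(moran), 0.3)
})

test_that("weights serialise to GAL and CSV", {
  pts <- cbind(c(0, 150, 300), 0)
  w <- distance_band_weights(pts, 200, ids = c("a", "b", "c"))
  gal <- withr::local_tempfile(fileext = ".gal")
  write_weights_gal(w, gal)
  lines <- readLines(gal)
  expect_equal(lines[1], "3")
  expect_equal(lines[2], "a 1")
  expect_equal(lines[3], "b")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(w, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 4)
  expect_equal(sum(df$weight), 3)
})
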