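orth_maps <- function(n_voxels = 60) {
  rbind(A = c(rep(5, 20), rep(0, n_voxels - 20)),
        B = c(rep(0, n_voxels - 20), rep(5, 20)))
}

test_that("motion exclusion uses a strict inequality on the mean FD", {
  fd <- list(rep(0.2, 100), rep(0.25, 100), rep(0, 100))
  part <- exclude_high_motion(fd, threshold = 0.2)
  expect_identical(part$retained, c(1L, 3L))
  expect_identical(part$excluded, 2L)
  expect_error(exclude_high_motion(list(numeric(0))), "empty")
})

test_that("noiseless dual regression recovers the generating time series", {
  maps <- orth_maps()
  dat <- generate_rsn_data(2, 60, 80, maps, diag(2), noise_sd = 0, seed = 6)
  for (s in 1:2) {
    dr <- dual_regression(maps, dat$subject_data[[s]])
    for (k in 1:2) {
      expect_equal(cor(dr$timeseries[k, ], dat$truth$timeseries[[s]][k, ]), 1,
                   tolerance = 1e-10)
    }
  }
})

test_that("multiple regression handles correlated maps where simple regression fails", {
  # two maps with spatial correlation ~0.5
  n_vox <- 90
  maps <- rbind(A = c(rep(4, 60), rep(0, 30)),
                B = c(rep(0, 30), rep(4, 60)))
  C <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  dat <- generate_rsn_data(1, n_vox, 150, maps, C, noise_sd = 0, seed = 7)
  truth <- dat$truth$timeseries[[1]]
  dr <- dual_regression(maps, dat$subject_data[[1]])
  for (k in 1:2) expect_gt(cor(dr$timeseries[k, ], truth[k, ]), 0.999)
  # per-component simple regression (ignoring the other map) is biased
  d <- dat$subject_data[[1]]
  simple <- sapply(1:2, function(k) {
    ts_k <- as.vector(crossprod(maps[k, ], d)) / sum(maps[k, ]^2)
    cor(ts_k, truth[k, ])
  })
  expect_true(any(simple < 0.999))
})

test_that("noisy dual regression still recovers the time series well", {
  maps <- orth_maps()
  dat <- generate_rsn_data(1, 60, 500, maps, diag(2), noise_sd = 0.5, seed = 8)
  dr <- dual_regression(maps, dat$subject_data[[1]])
  for (k in 1:2) {
    expect_gt(cor(dr$timeseries[k, ], dat$truth$timeseries[[1]][k, ]), 0.9)
  }
})

test_that("PE maps reproduce the group maps up to positive scale at low noise", {
  maps <- orth_maps()
  dat <- generate_rsn_data(1, 60, 400, maps, diag(2), noise_sd = 0.05, seed = 9)
  dr <- dual_regression(maps, dat$subject_data[[1]])
  for (k in 1:2) {
    cosine <- sum(dr$pe_maps[k, ] * maps[k, ]) /
      sqrt(sum(dr$pe_maps[k, ]^2) * sum(maps[k, ]^2))
    expect_gt(cosine, 0.99)
  }
})

test_that("integrity is the mean PE over the mask and is linear in amplitude", {
  pe <- rbind(c(1, 3, 10, 10), c(2, 2, 2, 2))
  masks <- list(1:2, 3:4)
  integ <- network_integrity(pe, masks)
  expect_equal(unname(integ), c(2, 2))
  expect_equal(unname(network_integrity(pe * 2, masks)), c(4, 4))
  expect_error(network_integrity(pe, list(integer(0), 3:4)), "empty")
  expect_error(network_integrity(pe, list(1:2, 4:5)), "voxel range")
  # doubling a component's amplitude in the data doubles its integrity
  maps <- orth_maps()
  dat <- generate_rsn_data(1, 60, 300, maps, diag(2), noise_sd = 0, seed = 10)
  d1 <- dat$subject_data[[1]]
  ts <- dat$truth$timeseries[[1]]
  d2 <- t(maps) %*% rbind(2 * ts[1, ], ts[2, ])
  m_masks <- lapply(1:2, function(k) which(maps[k, ] > 3))
  i1 <- network_integrity(dual_regression(maps, d1)$pe_maps, m_masks)
  i2 <- network_integrity(dual_regression(maps, d2)$pe_maps, m_masks)
  expect_equal(unname(i2[1] / i1[1]), 2, tolerance = 1e-8)
  expect_equal(unname(i2[2]), unname(i1[2]), tolerance = 1e-8)
})

test_that("segregation is the Fisher-z of pairwise time-series correlations", {
  set.seed(11)
  base <- rnorm(1000)
  ts2 <- 0.5 * scale(base)[, 1] + sqrt(0.75) * rnorm(1000)
  ts <- rbind(A = base, B = ts2)
  z <- network_segregation(ts)
  expect_equal(z["A", "B"], atanh(cor(base, ts2)), tolerance = 1e-12)
  expect_true(is.na(z["A", "A"]))
  expect_equal(z, t(z))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)  # closed form r = 0.5
})

test_that("independent series give near-zero segregation", {
  # averaged over subjects so the check sits well inside Monte-Carlo noise
  # (single-draw sampling SD of z at n_time = 2000 is ~0.022)
  maps <- orth_maps()
  dat <- generate_rsn_data(8, 60, 2000, maps, diag(2), noise_sd = 0.2, seed = 12)
  zs <- vapply(dat$subject_data, function(d) {
    network_segregation(dual_regression(maps, d)$timeseries)[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(max(abs(zs)), 0.1)
})

test_that("degenerate time series are flagged", {
  ts <- rbind(A = rnorm(100), B = rep(1, 100))
  expect_error(network_segregation(ts), "constant time series for network B")
  same <- rbind(A = rnorm(100))
  dup <- rbind(same, A2 = same[1, ])
  expect_warning(z <- network_segregation(dup), "capped")
  expect_true(is.finite(z[1, 2]))
})

test_that("scaling a subject's data scales time series but not segregation", {
  maps <- orth_maps()
  dat <- generate_rsn_data(1, 60, 300, maps,
                           matrix(c(1, 0.4, 0.4, 1), 2, 2), noise_sd = 0.1, seed = 13)
  d <- dat$subject_data[[1]]
  dr1 <- dual_regression(maps, d)
  dr2 <- dual_regression(maps, 3 * d)
  expect_equal(dr2$timeseries, 3 * dr1$timeseries, tolerance = 1e-10)
  expect_equal(network_segregation(dr2$timeseries),
               network_segregation(dr1$timeseries), tolerance = 1e-10)
})

test_that("rsn_metrics combines exclusion, integrity and segregation per subject", {
  maps <- orth_maps()
  dat <- generate_rsn_data(4, 60, 200, maps, diag(2), noise_sd = 0.2, seed = 14)
  fd <- generate_fd_series(c(0.05, 0.3, 0.1, 0.15), n_time = 200, seed = 15)
  met <- rsn_metrics(dat, fd = fd)
  expect_identical(met$excluded_subjects, 2L)
  expect_equal(nrow(met$integrity), 3)
  expect_length(met$segregation, 3)
  expect_true(all(is.finite(met$integrity)))
})
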