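# Steering vectors, Capon weights, DTW/SQI, and the azimuth search.

test_that("steering vector closed forms hold", {
  expect_equal(steering_vector(0, 8), rep(1 + 0i, 8))
  # m = 1, d/lambda = 0.5, sin 30 = 0.5 -> phase -2*pi*0.5*0.5 = -pi/2
  expect_equal(steering_vector(30, 8, 0.5)[2], exp(-1i * pi / 2))
  th <- 37
  expect_equal(steering_vector(-th, 8), Conj(steering_vector(th, 8)))
  expect_equal(Mod(steering_vector(55, 8)), rep(1, 8))
})

test_that("snapshot covariance is Hermitian and converges to identity on noise", {
  set.seed(1)
  X1 <- matrix(rnorm(8) + 1i * rnorm(8), ncol = 1)
  R1 <- snapshot_covariance(X1, loading = 0)$R
  expect_equal(R1, Conj(t(R1)))
  ev <- eigen(R1, only.values = TRUE)$values
  expect_equal(sum(abs(ev) > 1e-10 * max(abs(ev))), 1L)
  N <- 1e5
  Xn <- matrix((rnorm(4 * N) + 1i * rnorm(4 * N)) / sqrt(2), nrow = 4)
  Rn <- snapshot_covariance(Xn, loading = 0)$R
  expect_lt(max(Mod(Rn - diag(4))), 3 / sqrt(N) * 4)
})

test_that("Capon weights satisfy the distortionless constraint", {
  # identity covariance: w = a / M
  a <- steering_vector(20, 8)
  w <- capon_weights(diag(8) + 0i, a)
  expect_equal(w, a / 8)
  # random loaded covariance, all grid angles
  set.seed(2)
  X <- matrix(rnorm(8 * 500) + 1i * rnorm(8 * 500), nrow = 8)
  R <- snapshot_covariance(X)
  for (th in seq(-60, 60, by = 5)) {
    ath <- steering_vector(th, 8)
    wth <- capon_weights(R, ath)
    expect_lt(Mod(sum(Conj(wth) * ath) - 1), 1e-8)
  }
  expect_error(capon_weights(matrix(0 + 0i, 8, 8), a), "singular")
})

test_that("Capon rejects a strong interferer while passing the look direction", {
  set.seed(3)
  N <- 2000
  a_s <- steering_vector(-10, 8)
  a_i <- steering_vector(25, 8)
  s <- rnorm(N) + 1i * rnorm(N)
  i_sig <- 20 * (rnorm(N) + 1i * rnorm(N))
  X <- a_s %*% t(s) + a_i %*% t(i_sig) +
    0.1 * matrix(rnorm(8 * N) + 1i * rnorm(8 * N), nrow = 8)
  w <- capon_weights(snapshot_covariance(X), a_s)
  expect_lt(Mod(sum(Conj(w) * a_i)), 0.05)
  expect_equal(Mod(sum(Conj(w) * a_s)), 1, tolerance = 1e-8)
})

test_that("spatial spectrum peaks at the source azimuth", {
  set.seed(4)
  N <- 4000
  a_s <- steering_vector(20, 8)
  X <- a_s %*% t(10 * (rnorm(N) + 1i * rnorm(N))) +
    matrix(rnorm(8 * N) + 1i * rnorm(8 * N), nrow = 8)
  sp <- spatial_spectrum(snapshot_covariance(X), seq(-60, 60, by = 1))
  expect_lt(abs(sp$angle_deg[which.max(sp$power)] - 20), 1.01)
  expect_true(all(sp$power > 0))
  flat <- spatial_spectrum(diag(8) + 0i, seq(-60, 60, by = 10))
  expect_lt(diff(range(flat$power)), 1e-10)
})

test_that("beamformer output is the weighted antenna sum", {
  set.seed(5)
  X <- matrix(rnorm(8 * 100) + 1i * rnorm(8 * 100), nrow = 8)
  e0 <- c(1, rep(0, 7)) + 0i
  expect_equal(beamform_output(e0, X), X[1, ])
  w <- steering_vector(10, 8) / 8
  expect_equal(beamform_output(w, 2.5 * X), 2.5 * beamform_output(w, X))
  # distortionless recovery of a noise-free source
  s <- rnorm(100) + 1i * rnorm(100)
  Xs <- steering_vector(-30, 8) %*% t(s)
  ws <- capon_weights(snapshot_covariance(Xs, loading = 1e-6),
                      steering_vector(-30, 8))
  expect_equal(beamform_output(ws, Xs), s, tolerance = 1e-6)
})

test_that("z-normalization follows the population convention", {
  expect_equal(znormalize(c(1, 2, 3)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(6)
  x <- rnorm(100)
  expect_equal(znormalize(5 * x + 3), znormalize(x))
  z <- znormalize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-12)
  expect_error(znormalize(rep(2, 10)), "constant")
})

test_that("DTW equals the brute-force dynamic program on short sequences", {
  expect_equal(dtw_distance(c(0, 1, 0), c(0, 0, 1, 1, 0)),
               dtw_oracle(c(0, 1, 0), c(0, 0, 1, 1, 0)))
  set.seed(7)
  for (k in 1:60) {
    n <- sample(1:10, 1); m <- sample(1:10, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(0:3, m, replace = TRUE)
    expect_identical(dtw_distance(x, y), dtw_oracle(x, y))
    expect_identical(dtw_distance(x, y), dtw_distance(y, x))
  }
  x <- rnorm(50)
  expect_equal(dtw_distance(x, x), 0)
  expect_error(dtw_distance(numeric(0), 1:3), "empty")
})

test_that("path-normalized DTW is bounded by the raw distance", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(55)
  expect_lte(dtw_distance(x, y, normalize_path = TRUE),
             dtw_distance(x, y) / max(length(x), length(y)) * 2)
  expect_gt(dtw_distance(x, y, normalize_path = TRUE), 0)
})

test_that("SQI is the guarded reciprocal of the DTW distance and ranks quality", {
  tpl <- znormalize(sin(2 * pi * (0:399) / 40))
  expect_equal(sqi(tpl, tpl), 1e12)
  set.seed(9)
  noisy_copy <- znormalize(sin(2 * pi * (0:399) / 40) +
                             sqrt(0.1) * rnorm(400))   # ~10 dB
  noise <- znormalize(rnorm(400))
  expect_gt(sqi(noisy_copy, tpl), sqi(noise, tpl))
  # monotone in the distance by construction
  expect_gt(sqi(noisy_copy, tpl), 0)
})

test_that("the SQI azimuth search scans 121 angles and finds the heart", {
  ch <- test_chirp()
  sc <- scene_config(duration_s = 21, snr_db = 20, heart_azimuth_deg = -10,
                     torso_azimuth_deg = 15, seed = 7)
  sn <- select_target_bin(remove_static_clutter(
    range_fft(simulate_scene(sc, ch)$cube)))
  prof <- search_heart_azimuth(sn)
  expect_length(prof$angles_deg, 121L)
  expect_length(prof$sqi, 121L)
  expect_identical(prof$angles_deg, seq(-60, 60, by = 1))
  expect_lte(abs(prof$best_angle_deg - (-10)), 2)
  # frozen weights satisfy the distortionless constraint at the best angle
  a_best <- steering_vector(prof$best_angle_deg, 8)
  expect_lt(Mod(sum(Conj(prof$weights_opt) * a_best) - 1), 1e-8)
})

test_that("the search requires a full window and validates the template", {
  ch <- test_chirp()
  sc <- scene_config(duration_s = 5, seed = 1)
  sn <- select_target_bin(remove_static_clutter(
    range_fft(simulate_scene(sc, ch)$cube)))
  expect_error(search_heart_azimuth(sn), "at least 20")
  expect_error(search_heart_azimuth(sn, template = rep(1, 4000),
                                    window_s = 4), "constant")
})
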