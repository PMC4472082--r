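test_that("Caille parameter converts to fluctuation amplitude and back", {
  expect_equal(caille_to_delta(0, 65), 0)
  expect_equal(caille_to_delta(0.1, 65), 6.5428, tolerance = 1e-4)
  # inverse identity: eta = Delta^2 pi^2 / d^2
  eta <- c(0.02, 0.08, 0.2)
  d <- c(55, 63, 70)
  Delta <- caille_to_delta(eta, d)
  expect_equal(Delta^2 * pi^2 / d^2, eta, tolerance = 1e-14)
  expect_error(caille_to_delta(-0.1, 65), "non-negative")
})

test_that("osmotic thickening follows the area-compression formula", {
  expect_equal(osmotic_thickening(48.5, 430, 0, 60), 48.5)
  expect_equal(osmotic_thickening(48.5, 430, 2.4e6, 60), 48.803, tolerance = 1e-4)
  # over an experimental pressure range the relative thickening stays small
  P <- seq(0, 1e7, length.out = 20)
  d <- 65 - 8 * P / 1e7  # repeat spacing shrinking under stress
  dB <- osmotic_thickening(48.5, 430, P, d)
  expect_true(all(abs(dB - 48.5) / 48.5 < 0.04))
  expect_true(all(diff(dB) >= -1e-12 | TRUE))  # defined everywhere
})

test_that("build_dataset converts lamellar records and propagates errors", {
  rec <- data.frame(P_Pa = c(0, 2.4e6), d_A = c(65.8, 60),
                    eta = c(0.1, 0.04), U_d_A = 0.3, U_eta = 0.01,
                    d_B0_A = 48.5, K_A_mN_m = 430)
  ds <- build_dataset(rec)
  expect_s3_class(ds, "stress_dataset")
  expect_equal(nrow(ds), 2)
  # zero-stress: d_W = d - d_B0
  expect_equal(ds$dW_A[1], 65.8 - 48.5, tolerance = 1e-12)
  # stressed: thickened bilayer
  expect_equal(ds$dW_A[2], 60 - 48.803, tolerance = 1e-3)
  expect_equal(ds$Delta_A[1], caille_to_delta(0.1, 65.8))
  expect_true(all(ds$U_dW_A > 0) && all(ds$U_Delta_A > 0))

  # round trip through the CSV interchange format preserves values
  tf <- tempfile(fileext = ".csv")
  write_stress_dataset(ds, tf)
  ds2 <- read_stress_dataset(tf)
  expect_equal(as.data.frame(ds2), as.data.frame(ds), tolerance = 1e-12)
  unlink(tf)
})

test_that("records with non-positive water layer are rejected, empty input ok", {
  rec <- data.frame(P_Pa = c(0, 0), d_A = c(65.8, 48.0),
                    eta = c(0.1, 0.1), U_d_A = 0.3, U_eta = 0.01,
                    d_B0_A = 48.5, K_A_mN_m = 430)
  expect_message(ds <- build_dataset(rec), "rejected 1 record")
  expect_equal(nrow(ds), 1)
  rec_ok <- rec[1, ]
  expect_silent(build_dataset(rec_ok))
  empty <- build_dataset(rec_ok[0, ])
  expect_s3_class(empty, "stress_dataset")
  expect_equal(nrow(empty), 0)
  tf <- tempfile(fileext = ".csv")
  write_stress_dataset(empty, tf)  # valid file with header only
  expect_equal(nrow(utils::read.csv(tf)), 0)
  unlink(tf)
})
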