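test_that("storage files round-trip and de-duplicate repeated stamps", {
  x <- list(knee_angle = time_series(seq(0, 0.4, 0.1), c(1, 2, 3, 4, 5) / 7),
            grf = time_series(seq(0, 0.4, 0.1), sin(1:5)))
  path <- withr::local_tempfile(fileext = ".sto")
  write_storage(x, path, meta = list(name = "toy"))
  y <- read_storage(path)
  expect_named(y, c("knee_angle", "grf"))
  expect_equal(y$knee_angle$v, x$knee_angle$v, tolerance = 1e-12)
  expect_equal(y$grf$v, x$grf$v, tolerance = 1e-12)

  # plain TSV dialect, 3 columns x 5 rows -> 2 series of length 5
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\ta\tb", paste(1:5, 11:15, 21:25, sep = "\t")), tsv)
  z <- read_storage(tsv)
  expect_length(z, 2)
  expect_length(z$a$v, 5)

  # duplicated final time stamp: last duplicate dropped
  dup <- withr::local_tempfile()
  writeLines(c("time\ta", "0\t1", "0.1\t2", "0.2\t3", "0.2\t4"), dup)
  d <- read_storage(dup)
  expect_length(d$a$v, 3)
  expect_equal(d$a$v, c(1, 2, 3))
})

test_that("malformed storage tables raise parse errors naming the row", {
  bad <- withr::local_tempfile()
  writeLines(c("time\ta\tb\tc", "0\t1\t2", "1\t1\t2\t3"), bad)
  expect_error(read_storage(bad), "row 1")
  expect_error(read_storage(withr::local_tempfile(fileext = ".x")), "not found")
})

test_that("EMG envelope of a sinusoid is near-constant with max 1", {
  fs <- 1200
  t <- seq(0, 2, by = 1 / fs)
  rec <- emg_record(fs, sin(2 * pi * 50 * t), "vaslat")
  env <- emg_envelope(rec, band = c(20, 450), lp = 6)
  expect_equal(max(env$v), 1)
  mid <- env$v[seq(round(0.25 * length(t)), round(0.75 * length(t)))]
  expect_lt(stats::sd(mid) / mean(mid), 0.02)   # flat away from edges
  expect_true(all(env$v >= 0 & env$v <= 1))
})

test_that("EMG envelope handles zero input and is amplitude-equivariant", {
  fs <- 1000
  rec0 <- emg_record(fs, rep(0, 2000))
  expect_equal(emg_envelope(rec0)$v, rep(0, 2000))

  # amplitude-modulated burst peaks inside the burst window
  t <- seq(0, 2, by = 1 / fs)
  burst <- exp(-((t - 1.2) / 0.15)^2)
  x <- burst * sin(2 * pi * 80 * t)
  env <- emg_envelope(emg_record(fs, x), band = c(20, 400), lp = 6)
  expect_gt(t[which.max(env$v)], 1.0)
  expect_lt(t[which.max(env$v)], 1.4)

  # pre-normalization equivariance: scale raw by c, envelope scales by c
  e1 <- emg_envelope(emg_record(fs, 0.1 * x), band = c(20, 400), lp = 6,
                     norm = "supplied-max", max_value = 1)
  e2 <- emg_envelope(emg_record(fs, 0.3 * x), band = c(20, 400), lp = 6,
                     norm = "supplied-max", max_value = 1)
  expect_equal(e2$v, 3 * e1$v, tolerance = 1e-10)

  expect_error(emg_envelope(emg_record(100, rnorm(500))), "configuration")
})

test_that("synthetic gait is reproducible and shows the stance signature", {
  t1 <- synth_gait(seed = 7)
  t2 <- synth_gait(seed = 7)
  expect_identical(t1, t2)

  t3 <- synth_gait(list(noise_sd = 0), seed = 1)
  t4 <- synth_gait(list(noise_sd = 0), seed = 99)
  expect_identical(t3, t4)             # seed-invariant without noise

  # two local maxima in the vertical load magnitude
  v <- -t3$residual_force[, 2]
  locmax <- which(diff(sign(diff(v))) == -2) + 1
  expect_equal(length(locmax), 2)

  # early-stance flexion peak and pre-toe-off rise
  fl <- t3$flexion_deg
  n <- length(fl)
  expect_gt(max(fl[1:40]), fl[1])
  expect_gt(fl[n], fl[round(n / 2)])

  # peak flexion parameter pass-through
  t5 <- synth_gait(list(peak_flexion_deg = 20, noise_sd = 0), seed = 1)
  expect_equal(max(t5$flexion_deg), 20, tolerance = 1e-9)

  env <- t3$muscle_drive[!is.na(t3$muscle_drive)]
  expect_true(all(env >= 0 & env <= 1))
  expect_error(synth_gait(list(bodyweight_n = -1)), "configuration")
})

test_that("gait trial invariants are enforced", {
  tr <- synth_gait(seed = 1)
  expect_error(gait_trial(c(0, 0, 1), tr$flexion_deg[1:3],
                          tr$flexion_moment_nm[1:3], tr$muscle_drive[1:3, ],
                          "envelope", tr$residual_force[1:3, ],
                          tr$adduction_moment_nm[1:3],
                          tr$rotation_moment_nm[1:3], 765, tr$muscles),
               "strictly increasing")
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 101)
  p <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(tr, p)
  back <- utils::read.csv(p)
  expect_equal(back$flexion_deg, tr$flexion_deg, tolerance = 1e-9)
})
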