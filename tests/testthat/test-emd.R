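test_that("find_extrema locates interior extrema, plateaus and edge cases", {
  ex <- find_extrema(c(0, 1, 0, -1, 0))
  expect_equal(ex$maxima, 2L)
  expect_equal(ex$minima, 4L)

  ex <- find_extrema(c(1, 2, 3, 4))
  expect_length(ex$maxima, 0)
  expect_length(ex$minima, 0)

  # plateau of equal values: one extremum at the midpoint, rounding down
  ex <- find_extrema(c(0, 1, 1, 1, 1, 0))
  expect_equal(ex$maxima, 3L)
  ex <- find_extrema(c(0, -2, -2, 0))
  expect_equal(ex$minima, 2L)

  expect_error(find_extrema(c(1, 2)), class = "fhrscreen_input_error")

  # 0.5 Hz sinusoid sampled at 4 Hz over 10 s: brute-force scan agrees
  x <- sin(2 * pi * 0.5 * (0:39) / 4)
  ex <- find_extrema(x)
  brute_max <- which(vapply(2:39, function(i)
    x[i] > x[i - 1] && x[i] > x[i + 1], TRUE)) + 1L
  brute_min <- which(vapply(2:39, function(i)
    x[i] < x[i - 1] && x[i] < x[i + 1], TRUE)) + 1L
  expect_equal(ex$maxima, brute_max)
  expect_equal(ex$minima, brute_min)
  expect_length(ex$maxima, 5)
  expect_length(ex$minima, 5)
})

test_that("R and C++ extrema/zero-crossing scans agree on random signals", {
  for (seed in 1:20) {
    x <- random_trace_signal(n = 400, seed = seed) - 130
    ex_r <- find_extrema(x)
    ex_c <- fhrscreen:::.find_extrema_cpp(x)
    expect_equal(ex_r$maxima, as.integer(ex_c$maxima))
    expect_equal(ex_r$minima, as.integer(ex_c$minima))
    expect_equal(count_zero_crossings(x), fhrscreen:::.zero_crossings_cpp(x))
  }
})

test_that("envelope mean tracks the signal's slow level", {
  t <- (0:479) / 4
  A <- 2
  x <- A * sin(2 * pi * 0.5 * t)
  env <- build_envelopes(x)
  interior <- seq(floor(0.1 * length(x)), ceiling(0.9 * length(x)))
  expect_lt(max(abs(env$mean[interior])), 0.05 * A)

  x2 <- 7 + A * sin(2 * pi * 0.5 * t)
  env2 <- build_envelopes(x2)
  expect_lt(max(abs(env2$mean[interior] - 7)), 0.05 * A)

  # interpolation is exact at the knots
  ex <- find_extrema(x2)
  expect_equal(env2$upper[ex$maxima], x2[ex$maxima])
  expect_equal(env2$lower[ex$minima], x2[ex$minima])

  expect_error(build_envelopes(seq(0, 1, length.out = 50)),
               class = "fhrscreen_monotonic")
})

test_that("sum-of-difference criterion matches direct arithmetic", {
  q <- rnorm(100)
  expect_equal(sd_criterion(q, q), 0)
  expect_equal(sd_criterion(c(1, 1), c(0.9, 1.1)), 0.02)
  expect_identical(sd_criterion(c(0, 0), c(1, 1)), Inf)

  withr::with_seed(11, {
    q_prev <- rnorm(200)
    q_curr <- q_prev + rnorm(200, sd = 0.1)
  })
  loop_sum <- 0
  for (i in seq_along(q_prev))
    if (q_prev[i]^2 >= 1e-12)
      loop_sum <- loop_sum + (q_prev[i] - q_curr[i])^2 / q_prev[i]^2
  expect_equal(sd_criterion(q_prev, q_curr), loop_sum, tolerance = 1e-12)
})

test_that("sifting isolates the fast tone of a two-tone mixture", {
  tt <- two_tone()
  out <- sift_imf(tt$fast + tt$slow)
  expect_gt(cor(out$imf, tt$fast), 0.9)
  expect_true(is_imf(out$imf))
  expect_equal(out$imf + out$residual, tt$fast + tt$slow)

  expect_error(sift_imf(seq_len(64)), class = "fhrscreen_monotonic")
})

test_that("decomposition reconstructs the signal and orders modes fast to slow", {
  x <- random_trace_signal(n = 1024, seed = 3)
  dec <- emd(x)
  expect_gt(n_imfs(dec), 2)
  expect_lt(max(abs(emd_reconstruct(dec) - x)), 1e-8 * max(abs(x)))
  expect_equal(dec$n_imfs_total, n_imfs(dec) + 1L)
  for (j in seq_len(n_imfs(dec)))
    expect_true(is_imf(dec$imfs[, j]))
  zc <- apply(dec$imfs, 2, count_zero_crossings)
  expect_true(all(diff(zc) <= 0))

  # constant signal: no extrema, nothing to extract
  dec0 <- emd(rep(5, 64))
  expect_equal(n_imfs(dec0), 0)
  expect_equal(dec0$residue, rep(5, 64))

  expect_error(emd(c(1, 2, 3)), class = "fhrscreen_input_error")
  expect_error(emd(c(rnorm(50), NA, rnorm(50))),
               class = "fhrscreen_input_error")
})

test_that("IMF table round-trips through delimited text", {
  dec <- emd(random_trace_signal(n = 256, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_imf_table(dec, path, config = fhr_config())
  back <- read_imf_table(path)
  expect_equal(n_imfs(back), n_imfs(dec))
  expect_equal(unname(back$imfs), unname(dec$imfs), tolerance = 1e-12)
  expect_equal(back$residue, dec$residue, tolerance = 1e-12)
})

test_that("tidy and glance summarise a decomposition", {
  dec <- emd(fhr_trace(random_trace_signal(n = 256, seed = 5)))
  td <- tidy(dec)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 256 * dec$n_imfs_total)
  g <- glance(dec)
  expect_equal(g$n_imfs, n_imfs(dec))
  expect_lt(g$max_reconstruction_error, 1e-8)
})
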