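test_that("read_profile parses text, drops bad rows, synthesizes sigma", {
  lines3 <- sprintf("%.3f %.2f %.2f", seq(0.01, 0.08, by = 0.01),
                    100 - seq_len(8), 1)
  p <- read_profile(lines3)
  expect_s3_class(p, "scattering_profile")
  expect_length(p, 8L)
  expect_equal(p$q[1], 0.01)

  # headers + NaN rows are filtered with a warning
  body <- sprintf("%.4f %.4f %.4f", seq(0.01, 1, length.out = 100),
                  exp(-seq(0.01, 1, length.out = 100)), 0.01)
  body[c(10, 50, 90)] <- "0.5 NaN 0.01"
  lines <- c("# comment", "q I sigma", body)
  expect_warning(p2 <- read_profile(lines), "3 rows")
  expect_length(p2, 97L)

  # 2-column input: sigma synthesized as 0.02 * I
  lines2 <- sprintf("%.3f %.2f", seq(0.01, 0.10, by = 0.01), 50 + 1:10)
  p3 <- read_profile(lines2)
  expect_equal(p3$sigma / p3$intensity, rep(0.02, 10))

  expect_error(read_profile(lines3[1:4]), "fewer than 8")
  dup <- c(lines3, lines3[3])
  expect_error(read_profile(dup), "duplicate-q")
})

test_that("profile validation rejects bad q grids and sigmas", {
  q <- seq(0.01, 0.1, by = 0.01)
  expect_error(scattering_profile(q, rep(1, 10), rep(0, 10)), "sigma")
  expect_error(scattering_profile(rev(q), rep(1, 10), rep(1, 10)),
               "increasing")
  expect_error(scattering_profile(q[1:5], rep(1, 5), rep(1, 5)),
               "at least 8")
})

test_that("write/read round-trips bit-identically", {
  set.seed(4)
  q <- sort(runif(30, 0.01, 0.4))
  p <- scattering_profile(q, rnorm(30, 100, 5), runif(30, 0.5, 2),
                          label = "roundtrip")
  path <- tempfile(fileext = ".dat")
  write_profile(p, path)
  p2 <- read_profile(path)
  expect_identical(p2$q, p$q)
  expect_identical(p2$intensity, p$intensity)
  expect_identical(p2$sigma, p$sigma)
})

test_that("buffer subtraction is exact, linear, and flags negatives", {
  q <- seq(0.01, 0.2, length.out = 20)
  Ib <- 10 + q
  b <- scattering_profile(q, Ib, rep(1, 20))
  s <- scattering_profile(q, 2 * Ib, rep(1, 20))
  d <- subtract_buffer(s, b)
  expect_equal(d$intensity, Ib)
  expect_equal(d$sigma, rep(sqrt(2), 20))
  expect_false(attr(d, "mostly_negative"))

  self <- subtract_buffer(s, s)
  expect_equal(self$intensity, rep(0, 20))

  half <- subtract_buffer(scattering_profile(q, rep(10, 20), rep(1, 20)),
                          scattering_profile(q, rep(4, 20), rep(1, 20)),
                          scale = 0.5)
  expect_equal(half$intensity, rep(8, 20))

  # linearity: (a + b) - b == a within 1e-12 relative
  a <- scattering_profile(q, 5 * exp(-q), rep(0.5, 20))
  ab <- scattering_profile(q, a$intensity + b$intensity, rep(1, 20))
  lin <- subtract_buffer(ab, b)
  expect_equal(lin$intensity, a$intensity, tolerance = 1e-12)

  neg <- subtract_buffer(b, s)  # mostly negative
  expect_true(attr(neg, "mostly_negative"))

  q2 <- q + 0.001
  b2 <- scattering_profile(q2, Ib, rep(1, 20))
  expect_error(subtract_buffer(s, b2), "grid-mismatch")
})

test_that("frame averaging: identity, outlier exclusion, permutation invariance", {
  q <- seq(0.01, 0.3, length.out = 40)
  I <- 100 * exp(-q * 3)
  base <- scattering_profile(q, I, rep(1, 40))
  frames <- replicate(50, base, simplify = FALSE)
  avg <- average_frames(frames)
  expect_equal(avg$intensity, I)
  expect_equal(avg$sigma, rep(1 / sqrt(50), 40))

  # one frame scaled x10 is excluded at the default cut
  set.seed(1)
  noisy <- lapply(1:10, function(i)
    scattering_profile(q, I + rnorm(40, 0, 1), rep(1, 40)))
  noisy[[7]] <- scattering_profile(q, 10 * I, rep(1, 40))
  avg2 <- average_frames(noisy)
  expect_identical(attr(avg2, "excluded"), 7L)

  # permutation invariance of the result
  perm <- noisy[c(3, 7, 1, 10, 5, 2, 9, 4, 8, 6)]
  avg3 <- average_frames(perm)
  expect_equal(avg3$intensity, avg2$intensity)

  two <- list(scattering_profile(q, rep(1, 40), rep(1, 40)),
              scattering_profile(q, rep(3, 40), rep(1, 40)))
  expect_equal(average_frames(two)$intensity, rep(2, 40))
})

test_that("time series enforces common grid and increasing times", {
  q <- seq(0.01, 0.3, length.out = 40)
  ps <- lapply(1:3, function(i)
    scattering_profile(q, 100 * exp(-q * i), rep(1, 40)))
  ts <- time_series(ps, c(0.18, 0.36, 0.54))
  expect_length(ts, 3L)
  expect_error(time_series(ps, c(0.5, 0.4, 0.3)), "increasing")

  # cropping to the common q range
  p_wide <- scattering_profile(c(0.005, q), c(110, ps[[1]]$intensity),
                               rep(1, 41))
  ts2 <- time_series(list(p_wide, ps[[2]]), c(0, 1))
  expect_equal(ts2$profiles[[1]]$q, q)
})
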