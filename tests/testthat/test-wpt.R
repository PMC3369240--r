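test_that("a 1 s 16 kHz signal at level 5 yields 32 bands of 250 Hz", {
  x <- test_signal(16000)
  tr <- wpt_decompose(x, fs = 16000, wavelet = "db4", max_level = 5)
  td <- tidy(tr)
  l5 <- td[td$level == 5, ]
  expect_equal(nrow(l5), 32L)
  expect_true(all(l5$band_hi - l5$band_lo == 250))
  expect_equal(sort(l5$band_lo), seq(0, 7750, by = 250))
  expect_equal(max(l5$band_hi), 8000)
})

test_that("bands at every level tile [0, fs/2) without gaps or overlaps", {
  x <- test_signal(2048)
  tr <- wpt_decompose(x, fs = 16000, wavelet = "db6", max_level = 5)
  td <- tidy(tr)
  for (j in 1:5) {
    lj <- dplyr::arrange(td[td$level == j, ], band_lo)
    width <- 16000 / 2^(j + 1)
    expect_equal(nrow(lj), 2L^j)
    expect_equal(lj$band_lo, (0:(2^j - 1)) * width)
    expect_equal(lj$band_hi, lj$band_lo + width)
    expect_equal(sort(lj$freq_index), 0:(2^j - 1))
  }
})

test_that("zero signals give zero coefficients and impulses conserve energy", {
  tr0 <- wpt_decompose(numeric(1024), fs = 8000, wavelet = "db8", max_level = 3)
  expect_true(all(vapply(unlist(tr0$nodes, recursive = FALSE),
                         function(v) all(v == 0), logical(1))))
  expect_equal(wpt_reconstruct(tr0, 3), numeric(1024))

  imp <- c(1, numeric(63))
  tr <- wpt_decompose(imp, fs = 16000, wavelet = "db4", max_level = 2)
  e2 <- sum(vapply(tr$nodes[[2]], function(v) sum(v^2), numeric(1)))
  expect_equal(e2, 1, tolerance = 1e-10)
})

test_that("perfect reconstruction and energy conservation hold for all wavelets and levels", {
  set.seed(99)
  n_sig <- 25  # per wavelet; 100 signals across the four filters
  for (wv in c("db4", "db6", "db8", "db10")) {
    for (s in seq_len(n_sig)) {
      x <- rnorm(4096)
      tr <- wpt_decompose(x, fs = 16000, wavelet = wv, max_level = 5)
      ex <- sum(x^2)
      for (L in 1:5) {
        expect_lt(max(abs(x - wpt_reconstruct(tr, L))), 1e-8)
        eL <- sum(vapply(tr$nodes[[L]], function(v) sum(v^2), numeric(1)))
        expect_lt(abs(eL - ex) / ex, 1e-6)
      }
    }
  }
})

test_that("reconstruction of structured input is exact and odd lengths round-trip", {
  fs <- 16000
  x <- sin(2 * pi * 1000 * (0:15999) / fs)
  tr <- wpt_decompose(x, fs = fs, wavelet = "db4", max_level = 3)
  expect_lt(max(abs(x - wpt_reconstruct(tr, 3))), 1e-8)

  xo <- test_signal(5001)  # odd length exercises the pad-and-trim path
  tro <- wpt_decompose(xo, fs = fs, wavelet = "db10", max_level = 5)
  expect_lt(max(abs(xo - wpt_reconstruct(tro, 5))), 1e-8)
})

test_that("frequency ordering is the sequency permutation", {
  expect_equal(wpt_freq_order(1, 0:1), 0:1)
  expect_equal(wpt_freq_order(2, 3), 2)
  expect_equal(sort(wpt_freq_order(3, 0:7)), 0:7)
  expect_error(wpt_freq_order(2, 4), "out of range")

  # brute force: a pure sine in each level-2 band must land in the node
  # whose frequency-ordered band contains it
  fs <- 16000
  for (b in 0:3) {
    f <- (b + 0.5) * 2000
    s <- sin(2 * pi * f * (0:8191) / fs)
    td <- tidy(wpt_decompose(s, fs = fs, wavelet = "db10", max_level = 2))
    l2 <- td[td$level == 2, ]
    expect_equal(l2$freq_index[which.max(l2$energy)], b)
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(wpt_decompose(numeric(16), fs = 16000, max_level = 5),
               "too short")
  expect_error(wpt_decompose(c(1, NA, 3, 4), fs = 16000, max_level = 1),
               "NaN/Inf")
  tr <- wpt_decompose(test_signal(256), fs = 16000, max_level = 2)
  expect_error(wpt_reconstruct(tr, 3), "not populated")
})
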