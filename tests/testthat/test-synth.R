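test_that("synthesis is fully determined by the seed and leaves the RNG alone", {
  sp <- voice_spec(f0 = 150, seed = 77)
  a <- generate_voice(sp)
  set.seed(123)
  before <- .Random.seed
  b <- generate_voice(sp)
  expect_identical(before, .Random.seed)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples,
                         generate_voice(voice_spec(f0 = 150, seed = 78))$samples))
})

test_that("the noise-free limit is exactly periodic", {
  sp <- voice_spec(f0 = 160, noise_level = 0, jitter_pct = 0,
                   shimmer_pct = 0, seed = 1)
  x <- generate_voice(sp)$samples
  lag <- 16000 / 160  # integer period
  x1 <- x[1:(length(x) - lag)]
  x2 <- x[(lag + 1):length(x)]
  expect_gt(cor(x1, x2), 0.99)
})

test_that("generated vowels carry spectral peaks at the configured formants", {
  for (f0 in c(120, 180)) {
    sig <- generate_voice(voice_spec(f0 = f0, noise_level = 0.01,
                                     jitter_pct = 0.3, shimmer_pct = 1,
                                     seed = 7))
    sp <- Mod(stats::fft(sig$samples))^2
    freq <- (seq_along(sp) - 1) * sig$fs / length(sp)
    for (fm in c(730, 1090)) {
      inband <- mean(sp[freq >= fm - 80 & freq <= fm + 80])
      above <- mean(sp[freq >= fm + 150 & freq <= fm + 310])
      expect_gt(inband, 1.5 * above)
    }
  }
})

test_that("aspiration noise raises level-5 subband entropy nearly everywhere", {
  n_higher <- matrix(0, nrow = 10, ncol = 32)
  for (s in 1:10) {
    f_lo <- extract_features(generate_voice(
      voice_spec(f0 = 150, noise_level = 0, seed = 600 + s)))
    f_hi <- extract_features(generate_voice(
      voice_spec(f0 = 150, noise_level = 0.3, seed = 600 + s)))
    n_higher[s, ] <- (f_hi$sampen > f_lo$sampen)[f_hi$level == 5]
  }
  expect_gte(sum(colMeans(n_higher) > 0.5), 28)
})

test_that("corpus generation honours composition, determinism and labels", {
  co <- generate_corpus(c(healthy = 3, qi_deficiency = 2, yin_deficiency = 1),
                        seed = 9, duration_s = 0.3)
  expect_equal(nrow(co), 6L)
  expect_equal(as.integer(table(co$group)[c("healthy", "qi_deficiency",
                                            "yin_deficiency")]),
               c(3L, 2L, 1L))
  expect_equal(co$subject_id, sprintf("S%03d", 1:6))

  co2 <- generate_corpus(c(healthy = 3, qi_deficiency = 2, yin_deficiency = 1),
                         seed = 9, duration_s = 0.3)
  expect_identical(purrr::map(co$signal, "samples"),
                   purrr::map(co2$signal, "samples"))

  expect_error(generate_corpus(c(martian = 2), seed = 1), "no profile")
  expect_error(generate_corpus(c(2, 3), seed = 1), "named")
})

test_that("effect size zero collapses the three group profiles", {
  p0 <- group_profiles(0)
  expect_equal(length(unique(p0$noise_mean)), 1L)
  expect_equal(length(unique(p0$jitter_mean)), 1L)
  p1 <- group_profiles(1)
  expect_gt(p1$noise_mean[p1$group == "healthy"],
            p1$noise_mean[p1$group == "qi_deficiency"])
})

test_that("group-mean entropy ordering healthy above deficient holds at level 4", {
  ft <- small_features()
  b4 <- feature_bands(ft)
  b4 <- b4[parse_band_key(b4)$level == 4]
  gm <- ft |>
    dplyr::group_by(group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(b4), mean))
  h <- as.numeric(gm[gm$group == "healthy", -1])
  q <- as.numeric(gm[gm$group == "qi_deficiency", -1])
  y <- as.numeric(gm[gm$group == "yin_deficiency", -1])
  expect_gt(sum(h > q), 8)
  expect_gt(sum(h > y), 8)
})

test_that("invalid voice specifications are rejected", {
  expect_error(voice_spec(f0 = 5000), "f0")
  expect_error(voice_spec(formants = list(c(9000, 100))), "Nyquist")
  expect_error(voice_spec(noise_level = -1), "noise_level")
})
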