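test_that("summary ANOVA matches a full ANOVA on synthetically expanded data", {
  # expansion oracle: build a sample of size n with exact mean and SD,
  # run the standard one-way ANOVA on the raw values
  expand <- function(n, m, s) {
    z <- as.numeric(scale(seq_len(n)))
    m + s * z
  }
  oracle <- function(ns, means, sds) {
    vals <- unlist(purrr::pmap(list(ns, means, sds), expand))
    grp <- factor(rep(seq_along(ns), times = ns))
    fit <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
    c(unname(fit$statistic), unname(fit$p.value))
  }
  # the published cohort row for the 5.25-5.50 kHz band
  ref <- anova_from_summary(c(116, 38, 27), c(1.631, 1.642, 1.897),
                            c(0.300, 0.355, 0.216))
  orc <- oracle(c(116, 38, 27), c(1.631, 1.642, 1.897),
                c(0.300, 0.355, 0.216))
  expect_equal(ref$statistic, orc[1], tolerance = 1e-10)
  expect_equal(ref$p_value, orc[2], tolerance = 1e-10)

  set.seed(42)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    ns <- sample(5:40, k, replace = TRUE)
    means <- rnorm(k)
    sds <- runif(k, 0.2, 2)
    ref <- anova_from_summary(ns, means, sds)
    orc <- oracle(ns, means, sds)
    expect_equal(ref$statistic, orc[1], tolerance = 1e-10)
    expect_equal(ref$p_value, orc[2], tolerance = 1e-10)
  }
})

test_that("summary ANOVA degenerate and algebraic identities hold", {
  eq <- anova_from_summary(c(10, 10), c(1, 1), c(0.3, 0.3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # k = 2: F equals the square of the pooled-variance t statistic
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  y <- c(2.0, 1.7, 2.4, 2.2)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  ref <- anova_from_summary(c(length(x), length(y)), c(mean(x), mean(y)),
                            c(sd(x), sd(y)))
  expect_equal(ref$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(ref$p_value, tt$p.value, tolerance = 1e-12)

  # invariance under common rescaling of means and sds
  a <- anova_from_summary(c(8, 9, 10), c(1, 2, 3), c(0.5, 0.6, 0.7))
  b <- anova_from_summary(c(8, 9, 10), 10 * c(1, 2, 3), 10 * c(0.5, 0.6, 0.7))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  expect_error(anova_from_summary(c(1, 10), c(0, 0), c(1, 1)), "n >= 2")
  expect_error(anova_from_summary(c(5, 5), c(0, 0), c(-1, 1)), "negative")
  expect_error(anova_from_summary(c(5), c(0), c(1)), "two groups")
})

test_that("raw-data comparison agrees with its own summaries", {
  ft <- small_features()
  st <- compare_groups(ft)
  for (bk in sample(st$band, 8)) {
    row <- st[st$band == bk, ]
    ns <- c(row$n_healthy, row$n_qi_deficiency, row$n_yin_deficiency)
    means <- c(row$mean_healthy, row$mean_qi_deficiency,
               row$mean_yin_deficiency)
    sds <- c(row$sd_healthy, row$sd_qi_deficiency, row$sd_yin_deficiency)
    ref <- anova_from_summary(ns, means, sds)
    expect_equal(row$p_value, ref$p_value, tolerance = 1e-10)
    expect_equal(row$statistic, ref$statistic, tolerance = 1e-10)
  }
})

test_that("null features reject at roughly the nominal rate", {
  ft <- null_feature_table(c(a = 10, b = 10, c = 10), n_bands = 300, seed = 3)
  st <- compare_groups(ft)
  frac <- mean(st$p_value < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.008)
  expect_lt(frac, 0.092)
})

test_that("constructed effects are detected and degenerate variance reported as NA", {
  ft <- null_feature_table(c(a = 15, b = 15, c = 15), n_bands = 30, seed = 11)
  shifted <- feature_bands(ft)[1:10]
  ft[ft$group == "c", shifted] <- ft[ft$group == "c", shifted] + 2
  sel <- select_features(compare_groups(ft), alpha = 0.05)
  expect_true(all(shifted %in% sel$selected$band))

  const <- tibble::tibble(
    subject_id = sprintf("X%02d", 1:9),
    group = rep(c("a", "b", "c"), each = 3),
    L5_00000_00250 = rep(c(1, 1, 2), each = 3),      # zero within-group var
    L5_00250_00500 = c(rnorm(6), rnorm(3) + 3)        # ordinary band
  )
  st <- compare_groups(const)
  expect_true(is.na(st$p_value[st$band == "L5_00000_00250"]))
  expect_lt(st$p_value[st$band == "L5_00250_00500"], 0.05)
})

test_that("band selection respects alpha, ordering and correction", {
  ft <- null_feature_table(c(a = 8, b = 8, c = 8), n_bands = 40, seed = 2)
  st <- compare_groups(ft)

  none <- select_features(st, alpha = 1.0, correction = "none")
  expect_equal(none$n_selected, sum(!is.na(st$p_value)))

  fake <- st
  fake$p_value <- rep(0.5, nrow(st))
  expect_equal(select_features(fake, 0.05)$n_selected, 0L)

  bh <- select_features(st, alpha = 0.05, correction = "bh")
  raw <- select_features(st, alpha = 0.05, correction = "none")
  expect_true(all(bh$selected$band %in% raw$selected$band))

  sel <- tidy(raw)
  if (nrow(sel) > 1) {
    expect_true(!is.unsorted(sel$level))
  }
})

test_that("single-group input is refused", {
  ft <- null_feature_table(c(solo = 10), n_bands = 5)
  expect_error(compare_groups(ft), "two groups")
})

test_that("the shipped clinical reference table has the documented census", {
  cl <- clinical_band_summaries()
  expect_equal(nrow(cl), 47L)
  expect_equal(as.integer(table(cl$level)), c(1L, 2L, 5L, 13L, 26L))
  expect_true(all(cl$p_value < 0.05))
  expect_true(all(cl$band_hi_khz > cl$band_lo_khz))
  # band widths match the level geometry (kHz)
  expect_true(all(abs((cl$band_hi_khz - cl$band_lo_khz) - 8 / 2^cl$level) < 1e-9))
  sizes <- clinical_cohort_sizes()
  expect_equal(sum(sizes), 181L)
})
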