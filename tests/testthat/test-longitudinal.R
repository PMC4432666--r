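test_that("annual percentage change follows its definition", {
  expect_equal(annual_pct_change(0.40, 0.40, 3.6), 0)
  expect_equal(annual_pct_change(0.40, 0.36, 3.6), -100 / 36, tolerance = 1e-12)
  expect_equal(annual_pct_change(0.40, 0.44, 2.0), 5.0)
  expect_true(is.na(annual_pct_change(0, 0.4, 1)))
  expect_error(annual_pct_change(0.4, 0.4, 0), "interval")
  # vectorized
  expect_equal(annual_pct_change(c(0.4, 0.4), c(0.36, 0.44), c(3.6, 2)),
               c(-100 / 36, 5), tolerance = 1e-12)
})

test_that("the 2.5-SD outlier rule is single-pass and n-1 based", {
  expect_equal(exclude_outliers(rep(1, 10))$m, 0)  # zero variance
  v <- c(rep(0, 40), 100)
  ex <- exclude_outliers(v)
  expect_equal(ex$m, 1L)
  expect_false(ex$keep[41])
  # z computed directly: at n = 5 the max attainable z is below 2.5
  v5 <- c(0, 0, 0, 0, 10)
  z <- abs(v5 - mean(v5)) / sd(v5)
  expect_lt(max(z), 2.5)
  expect_equal(exclude_outliers(v5)$m, 0)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("paired t matches the textbook formula and conventions", {
  # no change: t = 0, p = 1 by convention
  r0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)
  # differences {1,2,3}: t = mean/ (sd/sqrt(n)) = 2 / (1/sqrt(3))
  r <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0742)
  # constant non-zero difference: degenerate, p = 0
  rc <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_true(rc$degenerate)
  expect_equal(rc$p, 0)
  expect_error(paired_t(1, 2), "at least 2")
  # pairwise deletion of incomplete pairs
  rp <- paired_t(c(1, 2, NA, 4), c(2, 4, 5, NA))
  expect_equal(rp$n, 2)
})

test_that("repeated-measures ANOVA matches a brute-force SS decomposition", {
  # identical columns: no wave effect
  m0 <- matrix(rep(c(1, 2, 3, 4), 3), 4)
  r0 <- rm_anova(m0)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # two-wave RM-ANOVA is the squared paired t
  set.seed(8)
  m2 <- cbind(rnorm(10, 0.4, 0.03), rnorm(10, 0.38, 0.03))
  r2 <- rm_anova(m2)
  t2 <- paired_t(m2[, 1], m2[, 2])
  expect_equal(r2$F, t2$t^2, tolerance = 1e-9)
  expect_equal(r2$p, t2$p, tolerance = 1e-9)
  # small integer worked table against hand-computed sums of squares
  m <- rbind(c(5, 3, 2), c(6, 4, 3), c(7, 6, 4), c(4, 2, 2))
  s <- nrow(m); w <- ncol(m)
  grand <- mean(m)
  ss_wave <- s * sum((colMeans(m) - grand)^2)
  ss_subj <- w * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_wave - ss_subj
  F_oracle <- (ss_wave / (w - 1)) / (ss_err / ((w - 1) * (s - 1)))
  r <- rm_anova(m)
  expect_equal(r$F, F_oracle, tolerance = 1e-9)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 6)
  expect_equal(r$p, pf(F_oracle, 2, 6, lower.tail = FALSE), tolerance = 1e-9)
  expect_error(rm_anova(m[1:2, ]), "insufficient")
})

test_that("Bonferroni alphas reproduce the study's corrected levels", {
  expect_equal(bonferroni_alpha(0.05, 22), 0.0023)
  expect_equal(bonferroni_alpha(0.05, 100), 0.0005)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "count")
})

test_that("age-change correlation behaves at the extremes", {
  age <- c(50, 55, 60, 65, 70)
  r1 <- pearson_age_change(age, 2 * age - 7)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-6)
  expect_error(pearson_age_change(age, rep(1, 5)), "zero variance")
  expect_error(pearson_age_change(age[1:2], c(1, 2)), "at least 3")
})

test_that("connection change tables follow the averaging and exclusion rules", {
  # hand-built 2-wave cohort: 5 subjects, known per-subject rates
  fa1 <- c(0.40, 0.42, 0.38, 0.41, 0.40)
  fa2 <- c(0.38, 0.41, 0.37, 0.40, 0.395)
  intv <- c(3.5, 3.6, 3.7, 3.6, 3.6)
  co <- cohort_table(subject = rep(1:5, 2), wave = rep(1:2, each = 5),
                     connection = "c1", mean_fa = c(fa1, fa2),
                     age = rep(60, 10), interval = c(rep(NA, 5), intv))
  ct <- connection_change_table(co)
  rates <- 100 * (fa2 - fa1) / fa1 / intv
  expect_equal(ct$pct_change_per_year, mean(rates), tolerance = 1e-12)
  expect_equal(ct$p_value, paired_t(fa1, fa2)$p, tolerance = 1e-12)
  expect_equal(ct$n, 5)
  expect_equal(ct$w1_mean, mean(fa1))
  expect_equal(ct$w1_sd, sd(fa1))
  expect_equal(attr(ct, "alpha_corrected"), 0.05)

  # a wild rate is excluded by the 2.5-SD rule and drops out of everything
  # (10 subjects: at n = 5 the max attainable z is below 2.5 by construction)
  fa1w <- rep(fa1, 2)
  fa2w <- c(fa2, fa2 + 0.003)
  fa2w[10] <- 0.2
  intw <- rep(intv, 2)
  cob <- cohort_table(subject = rep(1:10, 2), wave = rep(1:2, each = 10),
                      connection = "c1", mean_fa = c(fa1w, fa2w),
                      age = rep(60, 20), interval = c(rep(NA, 10), intw))
  ctb <- connection_change_table(cob)
  expect_equal(ctb$m_excluded, 1L)
  expect_equal(ctb$n, 9)
  expect_equal(ctb$p_value, paired_t(fa1w[1:9], fa2w[1:9])$p,
               tolerance = 1e-12)

  # three waves route through RM-ANOVA with per-interval rates
  co3 <- cohort_table(subject = rep(1:4, 3), wave = rep(1:3, each = 4),
                      connection = "c1",
                      mean_fa = c(0.40, 0.41, 0.39, 0.42,
                                  0.39, 0.40, 0.38, 0.41,
                                  0.38, 0.40, 0.37, 0.40),
                      age = 60,
                      interval = c(rep(NA, 4), rep(3.6, 8)))
  ct3 <- connection_change_table(co3)
  m3 <- matrix(co3$mean_fa, 4)
  expect_equal(ct3$p_value, rm_anova(m3)$p, tolerance = 1e-12)
  r12 <- 100 * (m3[, 2] - m3[, 1]) / m3[, 1] / 3.6
  r23 <- 100 * (m3[, 3] - m3[, 2]) / m3[, 2] / 3.6
  expect_equal(ct3$pct_change_per_year, mean((r12 + r23) / 2),
               tolerance = 1e-12)
  # overall-rate convention as the config alternative
  ct3o <- connection_change_table(co3, three_wave_rate = "overall")
  r13 <- 100 * (m3[, 3] - m3[, 1]) / m3[, 1] / 7.2
  expect_equal(ct3o$pct_change_per_year, mean(r13), tolerance = 1e-12)
  # absent connection warns and is skipped
  expect_warning(connection_change_table(co, connections = c("c1", "nope")),
                 "absent")
})

test_that("segment-wise tests localize change and respect the null", {
  set.seed(13)
  ns <- 30; nseg <- 100
  base <- 0.4 + 0.05 * sin(seq(0, pi, length.out = nseg))
  arr <- array(NA_real_, c(ns, 2, nseg))
  decline <- rep(0, nseg); decline[10:30] <- 0.04
  for (s in seq_len(ns)) {
    arr[s, 1, ] <- base + rnorm(nseg, 0, 0.005)
    arr[s, 2, ] <- base - decline + rnorm(nseg, 0, 0.005)
  }
  st <- segmentwise_longitudinal_test(arr, intervals = 3.6)
  expect_equal(attr(st, "alpha_corrected"), 0.0005)
  expect_true(all(which(st$significant) >= 8 & which(st$significant) <= 32))
  expect_gt(sum(st$significant[10:30]), 15)
  # per-segment rates reflect the generative decline
  expect_equal(mean(st$pct_change_per_year[15:25]),
               mean(100 * -decline[15:25] / base[15:25] / 3.6),
               tolerance = 0.5)
  # identical profiles across waves: nothing significant
  arr0 <- array(rep(base, each = ns * 2), c(ns, 2, nseg))
  st0 <- segmentwise_longitudinal_test(arr0)
  expect_equal(sum(st0$significant), 0L)
})

test_that("long profile tables reshape into subject x wave x segment arrays", {
  df <- expand.grid(subject = 1:3, wave = 1:2, segment = 1:4)
  df$mean_fa <- df$subject + 10 * df$wave + 100 * df$segment
  arr <- profiles_to_array(df)
  expect_equal(dim(arr), c(3, 2, 4))
  expect_equal(arr[2, 1, 3], 2 + 10 + 300)
  expect_equal(arr[3, 2, 4], 3 + 20 + 400)
})
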