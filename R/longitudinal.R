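#' Annual percentage FA change
#'
#' \code{100 * (fa_b - fa_a) / fa_a / interval}: percent change per year
#' relative to the earlier measurement. Negative values are decline.
#'
#' @param fa_a,fa_b FA at the earlier and later wave (vectorized).
#' @param interval elapsed time in years (> 0).
#' @return percent per year; NA (masked) where \code{fa_a} is not positive.
#' @export
annual_pct_change <- function(fa_a, fa_b, interval) {
  if (any(interval <= 0, na.rm = TRUE)) stop("interval must be positive")
  out <- 100 * (fa_b - fa_a) / fa_a / interval
  out[!is.na(fa_a) & fa_a <= 0] <- NA_real_
  out
}

#' Sample-wide outlier exclusion (2.5-SD rule)
#'
#' Single-pass rule: values deviating from the sample mean by more than
#' \code{z_threshold} sample standard deviations (n - 1 denominator) are
#' excluded; no re-iteration after exclusion. Zero-variance samples exclude
#' nothing.
#'
#' @param values numeric vector (>= 3 non-missing values required).
#' @param z_threshold deviation threshold in SD units, default 2.5.
#' @return list with \code{keep} (logical mask, NA values are
#'   \code{FALSE}) and \code{m} (number of non-missing values excluded).
#' @export
exclude_outliers <- function(values, z_threshold = 2.5) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("outlier rule needs at least 3 values")
  mu <- mean(values[ok])
  s <- sd(values[ok])
  keep <- ok
  if (is.finite(s) && s > 0) keep <- ok & abs(values - mu) <= z_threshold * s
  keep[is.na(keep)] <- FALSE
  list(keep = keep, m = sum(ok) - sum(keep[ok]))
}

#' Paired t-test between two waves
#'
#' Classical paired t on the within-subject differences (wave 2 minus wave
#' 1), two-sided, df = n - 1, with pairwise deletion of subjects missing
#' either wave. Zero-variance differences are degenerate: all-zero
#' differences give t = 0 and p = 1 by convention; constant non-zero
#' differences give an infinite t and p = 0, flagged.
#'
#' @param x_w1,x_w2 paired measurements.
#' @return list with \code{t}, \code{df}, \code{p}, \code{n},
#'   \code{degenerate}.
#' @export
paired_t <- function(x_w1, x_w2) {
  ok <- !is.na(x_w1) & !is.na(x_w2)
  x1 <- x_w1[ok]; x2 <- x_w2[ok]
  n <- length(x1)
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs")
  d <- x2 - x1
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1L, p = 1, n = n, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0, n = n,
                degenerate = TRUE))
  }
  res <- t.test(x2, x1, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, n = n, degenerate = FALSE)
}

#' One-way repeated-measures ANOVA across waves
#'
#' Within-subject ANOVA with wave as the repeated factor, listwise deletion
#' of incomplete subjects, df1 = waves - 1, df2 = (waves - 1)(subjects - 1),
#' no sphericity correction. Identical columns give F = 0, p = 1.
#'
#' @param mat subjects x waves matrix of the measure.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}, \code{n}
#'   (complete subjects used).
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  s <- nrow(mat); w <- ncol(mat)
  if (w < 2L) stop("repeated-measures ANOVA needs at least 2 waves")
  if (s < 3L) stop("insufficient data: need at least 3 complete subjects")
  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(seq_len(s), w)),
                   wave = factor(rep(seq_len(w), each = s)))
  fit <- aov(y ~ wave + Error(subject / wave), data = df)
  tab <- summary(fit)[["Error: subject:wave"]][[1]]
  Fv <- tab["wave", "F value"]
  p <- tab["wave", "Pr(>F)"]
  if (!is.finite(Fv)) { Fv <- 0; p <- 1 }  # zero error variance
  ss_tot <- sum((df$y - mean(df$y))^2)
  if (tab["wave", "Sum Sq"] <= 1e-12 * max(ss_tot, 1e-300)) {
    Fv <- 0; p <- 1  # no wave effect beyond floating-point residue
  }
  list(F = unname(Fv), df1 = w - 1L, df2 = (w - 1L) * (s - 1L),
       p = unname(p), n = s)
}

#' Bonferroni-corrected alpha level
#'
#' Family-wise error control by dividing the alpha level by the number of
#' comparisons; reported rounded to 4 decimals (so 0.05/22 = 0.0023 and
#' 0.05/100 = 0.0005).
#'
#' @param alpha nominal alpha, default 0.05.
#' @param m number of comparisons (>= 1).
#' @param digits rounding of the reported level, default 4.
#' @return corrected alpha.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m, digits = 4L) {
  if (missing(m) || length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a count >= 1")
  round(alpha / m, digits)
}

#' Pearson correlation between baseline age and yearly FA change
#'
#' Classical Pearson r with the two-sided t-based p-value; complete pairs
#' only. Zero variance in either variable is undefined and raises an error.
#'
#' @param age_w1 age at the first wave (years).
#' @param yearly_change annual FA change (any consistent units).
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearson_age_change <- function(age_w1, yearly_change) {
  ok <- !is.na(age_w1) & !is.na(yearly_change)
  a <- age_w1[ok]; y <- yearly_change[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(y) == 0)
    stop("correlation undefined: a variable has zero variance")
  res <- cor.test(a, y)
  list(r = unname(res$estimate), p = res$p.value, n = length(a))
}

#' Build a long cohort table
#'
#' Canonical long format consumed by the change statistics: one row per
#' (subject, wave, connection).
#'
#' @param subject,wave,connection,mean_fa equal-length vectors.
#' @param age age at scan (years).
#' @param interval years since the previous wave (NA at wave 1).
#' @return data.frame of class \code{cohort_table}.
#' @export
cohort_table <- function(subject, wave, connection, mean_fa, age = NA_real_,
                         interval = NA_real_) {
  df <- data.frame(subject = subject, wave = as.integer(wave),
                   connection = connection, mean_fa = mean_fa,
                   age = age, interval = interval)
  if (anyDuplicated(df[c("subject", "wave", "connection")]))
    stop("(subject, wave, connection) rows must be unique")
  class(df) <- c("cohort_table", "data.frame")
  df
}

# per-subject annualized percent change across the waves of a wide FA matrix
subject_rates <- function(famat, intervals, fallback_interval = 3.6,
                          three_wave_rate = "per-interval") {
  w <- ncol(famat)
  ints <- intervals
  ints[is.na(ints)] <- fallback_interval
  if (w == 2L) {
    annual_pct_change(famat[, 1], famat[, 2], ints[, 1])
  } else if (three_wave_rate == "overall") {
    annual_pct_change(famat[, 1], famat[, w], rowSums(ints))
  } else {
    per <- sapply(seq_len(w - 1L), function(k)
      annual_pct_change(famat[, k], famat[, k + 1L], ints[, k]))
    rowMeans(rbind(per))
  }
}

#' Per-connection longitudinal change table
#'
#' For each connection: per-wave mean and SD of tract mean FA, the test of
#' longitudinal change (paired t for two waves, repeated-measures ANOVA for
#' three), the cohort mean annual percentage FA change (first computed per
#' subject over that subject's own inter-scan intervals, then averaged),
#' and the number of excluded outliers. For two-wave analyses subjects are
#' included pairwise-complete and the 2.5-SD outlier rule is applied to the
#' per-subject annual rates before all statistics; three-wave analyses use
#' listwise deletion and no outlier exclusion.
#'
#' @param cohort a [cohort_table()] (or plain data.frame with the same
#'   columns).
#' @param connections connections to analyse; default all present.
#' @param waves waves to analyse; default all present (2 or 3).
#' @param alpha nominal alpha for the Bonferroni-corrected significance
#'   flag, default 0.05.
#' @param m_comparisons number of comparisons for the correction; default
#'   the number of analysed connections.
#' @param exclude add the 2.5-SD outlier exclusion (two-wave analyses
#'   only), default TRUE.
#' @param z_threshold outlier threshold in SD units.
#' @param fallback_interval interval (years) used for subjects with a
#'   missing inter-scan interval, default 3.6.
#' @param three_wave_rate "per-interval" (mean of the per-interval annual
#'   rates, default) or "overall" (wave-1 to final-wave rate).
#' @return data.frame of class \code{change_table}: connection, per-wave
#'   \code{wX_mean}/\code{wX_sd}, \code{p_value}, \code{n},
#'   \code{pct_change_per_year}, \code{m_excluded}, \code{significant};
#'   attribute \code{alpha_corrected}.
#' @export
connection_change_table <- function(cohort, connections = NULL, waves = NULL,
                                    alpha = 0.05, m_comparisons = NULL,
                                    exclude = TRUE, z_threshold = 2.5,
                                    fallback_interval = 3.6,
                                    three_wave_rate = c("per-interval",
                                                        "overall")) {
  three_wave_rate <- match.arg(three_wave_rate)
  waves <- waves %||% sort(unique(cohort$wave))
  if (length(waves) < 2L) stop("need at least 2 waves")
  connections <- connections %||% unique(cohort$connection)
  m <- m_comparisons %||% length(connections)
  alpha_c <- bonferroni_alpha(alpha, m)
  rows <- list()
  for (cn in connections) {
    sub <- cohort[cohort$connection == cn & cohort$wave %in% waves, ]
    if (nrow(sub) == 0L) {
      warning(sprintf("connection %s absent from cohort table; skipped", cn))
      next
    }
    subjects <- sort(unique(sub$subject))
    famat <- matrix(NA_real_, length(subjects), length(waves),
                    dimnames = list(subjects, waves))
    ints <- matrix(NA_real_, length(subjects), length(waves) - 1L)
    for (wi in seq_along(waves)) {
      rws <- sub[sub$wave == waves[wi], ]
      famat[match(rws$subject, subjects), wi] <- rws$mean_fa
      if (wi > 1L) ints[match(rws$subject, subjects), wi - 1L] <- rws$interval
    }
    complete <- complete.cases(famat)
    if (length(waves) > 2L) famat[!complete, ] <- NA_real_  # listwise
    rates <- subject_rates(famat, ints, fallback_interval, three_wave_rate)
    m_excl <- 0L
    use <- !is.na(rates)
    if (exclude && length(waves) == 2L && sum(use) >= 3L) {
      ex <- exclude_outliers(rates, z_threshold)
      use <- ex$keep
      m_excl <- ex$m
    }
    fam_use <- famat[use, , drop = FALSE]
    stat <- if (length(waves) == 2L) {
      pt <- paired_t(fam_use[, 1], fam_use[, 2])
      list(p = pt$p, n = pt$n)
    } else {
      ra <- rm_anova(fam_use)
      list(p = ra$p, n = ra$n)
    }
    row <- data.frame(connection = cn, stringsAsFactors = FALSE)
    for (wi in seq_along(waves)) {
      row[[sprintf("w%d_mean", waves[wi])]] <- mean(fam_use[, wi], na.rm = TRUE)
      row[[sprintf("w%d_sd", waves[wi])]] <- sd(fam_use[, wi][!is.na(fam_use[, wi])])
    }
    row$p_value <- stat$p
    row$n <- stat$n
    row$pct_change_per_year <- mean(rates[use])
    row$m_excluded <- m_excl
    row$significant <- stat$p < alpha_c
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha_corrected") <- alpha_c
  class(out) <- c("change_table", "data.frame")
  out
}

#' @export
print.change_table <- function(x, digits = 3, ...) {
  cat(sprintf("Longitudinal FA change, %d connection(s); corrected alpha = %.4g\n",
              nrow(x), attr(x, "alpha_corrected")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Segment-wise longitudinal along-tract test
#'
#' Per along-tract segment: the longitudinal test across subjects (paired t
#' for two waves, repeated-measures ANOVA for three), the mean annual
#' percentage FA change (per subject from the first to the last wave over
#' that subject's elapsed years, then averaged), and a significance flag at
#' the Bonferroni level for \code{n} segments.
#'
#' @param profiles 3D array \[subject, wave, segment\] of per-subject
#'   segment mean FA (use [profiles_to_array()] to build it from a long
#'   table).
#' @param intervals per-subject elapsed years between the first and last
#'   analysed wave; a single number is recycled. Default 3.6 per wave gap.
#' @param alpha nominal alpha, default 0.05.
#' @param m_comparisons comparisons for the Bonferroni correction; default
#'   the number of segments.
#' @return data.frame of class \code{segment_test}: segment, per-wave mean
#'   FA and SE (across subjects), pct_change_per_year, p_value,
#'   significant; attribute \code{alpha_corrected}. Segments without
#'   enough data are masked (NA, not significant).
#' @export
segmentwise_longitudinal_test <- function(profiles, intervals = NULL,
                                          alpha = 0.05,
                                          m_comparisons = NULL) {
  stopifnot(length(dim(profiles)) == 3L)
  ns <- dim(profiles)[1]; nw <- dim(profiles)[2]; nseg <- dim(profiles)[3]
  if (nw < 2L) stop("need at least 2 waves")
  intervals <- intervals %||% (3.6 * (nw - 1L))
  intervals <- rep_len(intervals, ns)
  m <- m_comparisons %||% nseg
  alpha_c <- bonferroni_alpha(alpha, m)
  out <- data.frame(segment = seq_len(nseg))
  for (w in seq_len(nw)) {
    x <- profiles[, w, , drop = FALSE]
    out[[sprintf("w%d_mean", w)]] <- apply(x, 3, mean, na.rm = TRUE)
    out[[sprintf("w%d_se", w)]] <- apply(x, 3, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      sd(v) / sqrt(length(v))
    })
  }
  pvals <- rep(NA_real_, nseg)
  pct <- rep(NA_real_, nseg)
  for (k in seq_len(nseg)) {
    mat <- profiles[, , k, drop = TRUE]
    mat <- matrix(mat, ns, nw)
    cc <- complete.cases(mat)
    rates <- annual_pct_change(mat[, 1], mat[, nw], intervals)
    pct[k] <- mean(rates[cc], na.rm = TRUE)
    res <- tryCatch({
      if (nw == 2L) paired_t(mat[, 1], mat[, 2]) else rm_anova(mat)
    }, error = function(e) NULL)
    if (!is.null(res)) pvals[k] <- res$p
  }
  out$pct_change_per_year <- pct
  out$p_value <- pvals
  out$significant <- !is.na(pvals) & pvals < alpha_c
  attr(out, "alpha_corrected") <- alpha_c
  class(out) <- c("segment_test", "data.frame")
  out
}

#' Arrange long per-subject profiles into a subject x wave x segment array
#'
#' @param df data.frame with columns \code{subject}, \code{wave},
#'   \code{segment}, \code{mean_fa}.
#' @return 3D array indexed \[subject, wave, segment\].
#' @export
profiles_to_array <- function(df) {
  subjects <- sort(unique(df$subject))
  waves <- sort(unique(df$wave))
  segs <- sort(unique(df$segment))
  arr <- array(NA_real_, c(length(subjects), length(waves), length(segs)),
               dimnames = list(subjects, waves, segs))
  arr[cbind(match(df$subject, subjects), match(df$wave, waves),
            match(df$segment, segs))] <- df$mean_fa
  arr
}

#' @export
print.segment_test <- function(x, ...) {
  cat(sprintf("Segment-wise longitudinal test: %d segments, %d significant at corrected alpha %.4g\n",
              nrow(x), sum(x$significant), attr(x, "alpha_corrected")))
  invisible(x)
}

#' Plot a segment-wise longitudinal test
#'
#' Three stacked panels in the style of along-tract change figures:
#' per-wave mean FA profiles, annual percent change per segment, and
#' -log10(p) with significant segments emphasised.
#'
#' @param x a \code{segment_test}.
#' @param ... ignored.
#' @export
plot.segment_test <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  wcols <- grep("^w\\d+_mean$", names(x), value = TRUE)
  graphics::matplot(x$segment, as.matrix(x[wcols]), type = "l", lty = 1:3,
                    col = 1, xlab = "", ylab = "mean FA")
  graphics::plot(x$segment, x$pct_change_per_year, type = "l", xlab = "",
                 ylab = "% change / year")
  graphics::abline(h = 0, lty = 3)
  lp <- -log10(pmax(x$p_value, 1e-300))
  graphics::plot(x$segment, lp, type = "l", xlab = "segment",
                 ylab = "-log10(p)")
  if (any(x$significant))
    graphics::points(x$segment[x$significant], lp[x$significant], pch = 16)
  invisible(x)
}
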