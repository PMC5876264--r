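#' Score-outcome correlation
#'
#' Pearson's r on the raw values, Spearman's rho as Pearson on mid-ranks
#' (tie-corrected), two-sided p-values (Spearman via the asymptotic t
#' approximation, appropriate with ties), and the variance explained,
#' `100 * r^2`, in percent.
#'
#' @param score integer score vector.
#' @param rts numeric outcome vector (days), same length, `n >= 3`.
#' @return named list: `n`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `variance_explained_pct`.
#' @export
#' @examples
#' correlate(c(1, 2, 3), c(10, 20, 30))$pearson_r  # 1
correlate <- function(score, rts) {
  ok <- !is.na(score) & !is.na(rts)
  score <- score[ok]; rts <- rts[ok]
  n <- length(score)
  if (n != length(rts)) {
    abort_hamscore("score and rts must have equal length",
                   "hamscore_validation_error")
  }
  if (n < 3) {
    abort_hamscore("need n >= 3 pairs", "hamscore_validation_error")
  }
  if (stats::sd(score) == 0 || stats::sd(rts) == 0) {
    abort_hamscore("zero variance in score or rts: correlation undefined",
                   "hamscore_degenerate_error")
  }
  pe <- stats::cor.test(score, rts, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(score, rts, method = "spearman", exact = FALSE)
  )
  r <- unname(pe$estimate)
  list(
    n = n,
    pearson_r = r,
    pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate),
    spearman_p = sp$p.value,
    variance_explained_pct = 100 * r^2
  )
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal distribution whose mean and SD
#' are estimated from the data, with the p-value from the Dallal-Wilkinson
#' (1986) approximation (the correction required because the parameters are
#' estimated; the uncorrected KS p would be grossly conservative).
#'
#' @param x numeric vector, `n >= 5`, non-constant.
#' @return named list: `n`, `statistic` (in `[0, 1]`), `p`.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5) {
    abort_hamscore("need n >= 5", "hamscore_validation_error")
  }
  if (stats::sd(x) == 0) {
    abort_hamscore("constant vector: normality test undefined",
                   "hamscore_degenerate_error")
  }
  z <- stats::pnorm(sort(x), mean = mean(x), sd = stats::sd(x))
  i <- seq_len(n)
  D <- max(i / n - z, z - (i - 1) / n)

  # Dallal & Wilkinson (1986) approximation, as used by the standard
  # Lilliefors implementations
  if (n <= 100) {
    Kd <- D
    nd <- n
  } else {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) -
             0.122119 + 0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) {
      1
    } else if (KK <= 0.5) {
      2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4
    } else if (KK <= 0.9) {
      -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
    } else if (KK <= 1.31) {
      6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
    } else {
      0
    }
  }
  list(n = n, statistic = D, p = min(max(p, 0), 1))
}

#' Dichotomize by score threshold and compare RTS between groups
#'
#' Splits the cohort into score `< threshold` vs `>= threshold` (the
#' partition is always exhaustive and exclusive), and when both groups are
#' non-empty compares RTS: mean difference (high minus low group), Welch 95%
#' CI and two-sided p, and Cohen's d with the pooled SD. With zero pooled SD,
#' `d` is `NA` with a warning (never a silent infinity); with a group of
#' fewer than 2 observations the Welch CI is `NA`.
#'
#' @param score integer score vector.
#' @param rts numeric outcome vector (days), same length.
#' @param threshold integer cut point; default 10.
#' @return named list: `threshold`; `group_low` and `group_high`, each
#'   `(n, mean_rts, median_rts, sd_rts)` (the latter three `NA` for an empty
#'   group); and, when both groups are non-empty, `comparison` with
#'   `mean_difference_days`, `ci95`, `welch_p`, `effect_size_d`. `comparison`
#'   is `NULL` when a group is empty.
#' @export
dichotomize_and_compare <- function(score, rts, threshold = 10L) {
  if (length(score) != length(rts)) {
    abort_hamscore("score and rts must have equal length",
                   "hamscore_validation_error")
  }
  ok <- !is.na(score) & !is.na(rts)
  score <- score[ok]; rts <- rts[ok]
  hi <- score >= threshold
  grp <- function(v) {
    if (length(v) == 0) {
      list(n = 0L, mean_rts = NA_real_, median_rts = NA_real_,
           sd_rts = NA_real_)
    } else {
      list(n = length(v), mean_rts = mean(v), median_rts = stats::median(v),
           sd_rts = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
  }
  lo_g <- grp(rts[!hi])
  hi_g <- grp(rts[hi])

  comparison <- NULL
  if (lo_g$n > 0 && hi_g$n > 0) {
    diff <- hi_g$mean_rts - lo_g$mean_rts
    n1 <- hi_g$n; n2 <- lo_g$n
    s1 <- hi_g$sd_rts; s2 <- lo_g$sd_rts
    pooled <- if (n1 + n2 > 2 && !is.na(s1) && !is.na(s2)) {
      sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    } else {
      NA_real_
    }
    d <- if (is.na(pooled)) {
      NA_real_
    } else if (pooled == 0) {
      if (diff == 0) 0 else {
        warning(structure(
          class = c("hamscore_degenerate_warning", "warning", "condition"),
          list(message = "zero pooled SD: Cohen's d undefined, returning NA",
               call = sys.call(-1))
        ))
        NA_real_
      }
    } else {
      diff / pooled
    }
    ci <- c(NA_real_, NA_real_); p <- NA_real_
    if (n1 > 1 && n2 > 1 && (s1 > 0 || s2 > 0)) {
      tt <- stats::t.test(rts[hi], rts[!hi])  # Welch
      ci <- unname(tt$conf.int)
      p <- tt$p.value
    }
    comparison <- list(
      mean_difference_days = diff, ci95 = ci, welch_p = p, effect_size_d = d
    )
  }
  list(threshold = as.integer(threshold), group_low = lo_g,
       group_high = hi_g, comparison = comparison)
}

#' Full statistical evaluation of score against RTS
#'
#' The standard validation analysis for a prognostic severity score: scores
#' the MRI-positive records with RTS recorded, tests both variables for
#' normality ([ks_normality()]), reports Pearson and Spearman correlations
#' side by side with the variance explained ([correlate()]), and the
#' dichotomized group comparison ([dichotomize_and_compare()]). Also emits
#' per-muscle-count RTS means (descriptive only).
#'
#' @param records cohort data frame; rows must have `rts_days`.
#' @param rubric scoring rubric.
#' @param threshold dichotomization cut point (default 10).
#' @return object of class `evaluation_result`: list with `n`, `normality`
#'   (per variable), `correlation`, `groups`
#'   (from [dichotomize_and_compare()]), `by_n_muscles`
#'   (n/mean/sd of RTS per muscle count), and `scored` (the per-record
#'   score/RTS pairs used).
#' @export
evaluate_cohort <- function(records, rubric = default_rubric(),
                            threshold = 10L) {
  validate_records(records)
  rec <- records[records$mri_positive & !is.na(records$rts_days), , drop = FALSE]
  if (nrow(rec) < 3) {
    abort_hamscore("need >= 3 MRI-positive records with recorded RTS",
                   "hamscore_validation_error")
  }
  sc <- score_records(rec, rubric)
  total <- sc$total
  rts <- as.numeric(rec$rts_days)

  by_m <- lapply(split(rts, rec$n_muscles), function(v) {
    list(n = length(v), mean_rts = mean(v),
         sd_rts = if (length(v) > 1) stats::sd(v) else NA_real_)
  })

  structure(
    list(
      n = nrow(rec),
      normality = list(
        total_score = ks_normality(total),
        rts_days = ks_normality(rts)
      ),
      correlation = correlate(total, rts),
      groups = dichotomize_and_compare(total, rts, threshold),
      by_n_muscles = by_m,
      scored = data.frame(athlete_id = rec$athlete_id, total = total,
                          rts_days = rts, stringsAsFactors = FALSE)
    ),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  co <- x$correlation
  cat(sprintf("Evaluation of %d scored injuries\n", x$n))
  cat(sprintf("  Pearson r = %.3f (p = %.3f); Spearman rho = %.3f (p = %.3f)\n",
              co$pearson_r, co$pearson_p, co$spearman_rho, co$spearman_p))
  cat(sprintf("  Variance explained: %.1f%%\n", co$variance_explained_pct))
  g <- x$groups
  cat(sprintf("  Score < %d: n = %d, mean RTS %.1f d; score >= %d: n = %d, mean RTS %.1f d\n",
              g$threshold, g$group_low$n, g$group_low$mean_rts,
              g$threshold, g$group_high$n, g$group_high$mean_rts))
  if (!is.null(g$comparison)) {
    cat(sprintf("  Difference %.1f d (95%% CI %.1f to %.1f), Cohen's d = %.2f\n",
                g$comparison$mean_difference_days, g$comparison$ci95[1],
                g$comparison$ci95[2], g$comparison$effect_size_d))
  }
  invisible(x)
}
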