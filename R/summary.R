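#' Categorical frequency table with percentages
#'
#' Percentages are computed against the supplied counts' own total (the
#' function never assumes a fixed cohort size, since per-variable
#' denominators in clinical reports routinely disagree with the headline N)
#' and rendered half-up to one decimal.
#'
#' @param counts named non-negative numeric vector (names are categories), or
#'   a two-column data frame `(category, count)`.
#' @return data frame with `category`, `count`, `percent` (one decimal).
#' @export
#' @examples
#' summarize_categorical(c(`1 muscle` = 89, `2 muscles` = 21, `3 muscles` = 1))
summarize_categorical <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts[[2]], as.character(counts[[1]]))
  }
  if (any(counts < 0) || anyNA(counts)) {
    abort_hamscore("counts must be non-negative", "hamscore_validation_error")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort_hamscore("all counts are zero", "hamscore_validation_error")
  }
  data.frame(
    category = names(counts),
    count = as.numeric(counts),
    percent = round_half_up(100 * as.numeric(counts) / total, 1),
    stringsAsFactors = FALSE
  )
}

#' Continuous-variable summary
#'
#' Mean with its 95% t-interval, median, IQR (Q3 - Q1 with type-7 linear
#' interpolation), sample SD (n - 1 denominator), minimum and maximum.
#'
#' @param x numeric vector, `n >= 2`, `NA`s removed.
#' @return named list: `n`, `mean`, `ci95` (length-2), `median`, `iqr`, `sd`,
#'   `min`, `max`.
#' @export
summarize_continuous <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) {
    abort_hamscore("need at least 2 non-missing values",
                   "hamscore_validation_error")
  }
  m <- mean(x)
  s <- stats::sd(x)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  list(
    n = n, mean = m, ci95 = c(m - half, m + half),
    median = stats::median(x), iqr = q[2] - q[1],
    sd = s, min = min(x), max = max(x)
  )
}

#' Describe a scored cohort
#'
#' Builds the standard cohort description: per-variable category frequency
#' tables (muscle count, primary muscle, injury location, transverse and
#' sagittal bins — binned with the supplied rubric's own cut points) and
#' continuous summaries of the total score and of RTS days. MRI-negative
#' records are excluded first and their count reported.
#'
#' @param records cohort data frame (see [injury-records]).
#' @param rubric rubric used to bin the continuous MRI variables and score
#'   the totals.
#' @return object of class `cohort_summary`: list with `n_input`,
#'   `n_mri_negative`, `n_analyzed`, `categorical` (named list of
#'   [summarize_categorical()] tables) and `continuous` (named list of
#'   [summarize_continuous()] summaries; `rts_days` present only when any RTS
#'   is recorded).
#' @export
cohort_summary <- function(records, rubric = default_rubric()) {
  validate_records(records)
  neg <- sum(!records$mri_positive)
  rec <- records[records$mri_positive, , drop = FALSE]
  if (nrow(rec) == 0) {
    abort_hamscore("no MRI-positive records to summarize",
                   "hamscore_validation_error")
  }
  sc <- score_records(rec, rubric)

  bin_label <- function(b, unit) {
    lo <- b$lower
    hi <- b$upper
    if (lo == hi) return(paste0(lo, unit))
    if (!is.finite(hi)) {
      return(paste0(if (b$lower_closed) "≥" else ">", lo, unit))
    }
    paste0(if (b$lower_closed) "" else ">", lo, "-<", hi, unit)
  }
  bin_table <- function(comp, values, unit) {
    labs <- vapply(comp$bins, bin_label, character(1), unit = unit)
    counts <- vapply(comp$bins, function(b) sum(bin_contains(b, values)),
                     numeric(1))
    # degenerate zero bins (e.g. sagittal exactly 0) are omitted when empty
    keep <- counts > 0 | vapply(comp$bins, function(b) b$lower != b$upper,
                                logical(1))
    summarize_categorical(stats::setNames(counts[keep], labs[keep]))
  }
  tab <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    summarize_categorical(stats::setNames(as.numeric(cnt), names(cnt)))
  }

  categorical <- list(
    n_muscles = tab(rec$n_muscles, sort(unique(rec$n_muscles))),
    primary_muscle = tab(rec$primary_muscle, MUSCLES),
    location = tab(rec$location, LOCATIONS),
    transverse_pct = bin_table(rubric$transverse_pct, rec$transverse_pct, "%"),
    sagittal_cm = bin_table(rubric$sagittal_cm, rec$sagittal_extent_cm, " cm")
  )
  continuous <- list(total_score = summarize_continuous(sc$total))
  if (any(!is.na(rec$rts_days))) {
    continuous$rts_days <- summarize_continuous(rec$rts_days)
  }
  structure(
    list(
      n_input = nrow(records), n_mri_negative = neg, n_analyzed = nrow(rec),
      categorical = categorical, continuous = continuous
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(format_summary_md(x), sep = "\n")
  invisible(x)
}

#' Render a cohort summary as Markdown
#'
#' @param summary a `cohort_summary`.
#' @return character vector of Markdown lines (one table per variable and a
#'   continuous-summary table with Mean (95% CI), Median (IQR), SD, Minimum,
#'   Maximum rows).
#' @export
format_summary_md <- function(summary) {
  f1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)
  lines <- c(
    "# Cohort summary",
    "",
    sprintf("Records: %d input, %d MRI-negative excluded, %d analyzed.",
            summary$n_input, summary$n_mri_negative, summary$n_analyzed),
    ""
  )
  for (nm in names(summary$categorical)) {
    tb <- summary$categorical[[nm]]
    lines <- c(
      lines, paste0("## ", nm), "",
      "| category | n | % |", "|---|---|---|",
      sprintf("| %s | %g | %s |", tb$category, tb$count, f1(tb$percent)), ""
    )
  }
  cont <- summary$continuous
  hdr <- paste0("| statistic | ", paste(names(cont), collapse = " | "), " |")
  row <- function(label, fn) {
    paste0("| ", label, " | ",
           paste(vapply(cont, fn, character(1)), collapse = " | "), " |")
  }
  lines <- c(
    lines, "## Continuous", "", hdr,
    paste0("|", paste(rep("---|", length(cont) + 1), collapse = "")),
    row("Mean (95% CI)", function(s)
      sprintf("%s (%s-%s)", f1(s$mean), f1(s$ci95[1]), f1(s$ci95[2]))),
    row("Median (IQR)", function(s) sprintf("%g (%g)", s$median, s$iqr)),
    row("SD", function(s) formatC(round_half_up(s$sd, 2), format = "f", digits = 2)),
    row("Minimum", function(s) sprintf("%g", s$min)),
    row("Maximum", function(s) sprintf("%g", s$max))
  )
  lines
}
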