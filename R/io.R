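#' Read injury records from CSV
#'
#' The CSV dialect is UTF-8, comma-separated, mandatory header row, columns
#' as documented in [injury-records] (any column order; missing values as
#' empty cells). Empty `insertion_involved` and `retraction_cm` cells default
#' to no/0 (the usual case: complete ruptures are excluded at enrolment).
#' Rows violating the record invariants are excluded, not fatal: the
#' returned data frame carries an `exclusions` attribute
#' (`row`, `athlete_id`, `reason`) and one message is logged per exclusion.
#'
#' @param path CSV file path.
#' @param quiet suppress per-exclusion messages.
#' @return validated cohort data frame with attribute `exclusions`.
#' @export
read_records <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort_hamscore(paste0("file not found: ", path), "hamscore_schema_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), encoding = "UTF-8")
  miss <- setdiff(RECORD_COLUMNS, names(df))
  if (length(miss)) {
    abort_hamscore(
      paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")),
      "hamscore_schema_error"
    )
  }
  df <- df[RECORD_COLUMNS]
  df$athlete_id <- as.character(df$athlete_id)
  for (col in c("age", "transverse_pct", "retraction_cm",
                "sagittal_extent_cm")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$n_muscles <- suppressWarnings(as.integer(df$n_muscles))
  df$rts_days <- suppressWarnings(as.integer(df$rts_days))
  to_logical <- function(x) {
    if (is.logical(x)) return(x)
    tolower(as.character(x)) %in% c("true", "t", "yes", "y", "1")
  }
  df$mri_positive <- to_logical(df$mri_positive)
  df$insertion_involved[is.na(df$insertion_involved)] <- FALSE
  df$insertion_involved <- to_logical(df$insertion_involved)
  df$retraction_cm[is.na(df$retraction_cm) & df$mri_positive] <- 0

  neg <- !df$mri_positive
  df$n_muscles[neg & is.na(df$n_muscles)] <- 0L
  df$transverse_pct[neg] <- 0
  df$retraction_cm[neg] <- 0
  df$sagittal_extent_cm[neg & is.na(df$sagittal_extent_cm)] <- 0

  reason <- record_problems(df)
  bad <- which(!is.na(reason))
  exclusions <- data.frame(
    row = bad, athlete_id = df$athlete_id[bad], reason = reason[bad],
    stringsAsFactors = FALSE
  )
  if (!quiet) {
    for (i in seq_len(nrow(exclusions))) {
      message(sprintf("excluded row %d (%s): %s", exclusions$row[i],
                      exclusions$athlete_id[i], exclusions$reason[i]))
    }
    if (any(neg[is.na(reason)])) {
      message(sprintf("note: %d MRI-negative record(s) retained; they are excluded from evaluation",
                      sum(neg[is.na(reason)])))
    }
  }
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

#' Write injury records to CSV
#'
#' @param records cohort data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records[RECORD_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

evaluation_to_list <- function(ev) {
  g <- ev$groups
  list(
    n = ev$n,
    normality = ev$normality,
    correlation = ev$correlation,
    groups = list(
      threshold = g$threshold,
      group_low = g$group_low,
      group_high = g$group_high,
      comparison = g$comparison
    ),
    by_n_muscles = ev$by_n_muscles
  )
}

summary_to_list <- function(sm) {
  list(
    n_input = sm$n_input, n_mri_negative = sm$n_mri_negative,
    n_analyzed = sm$n_analyzed,
    categorical = sm$categorical,
    continuous = sm$continuous
  )
}

#' Run the full score-summarize-evaluate pipeline
#'
#' Ties the modules together: read (or accept) a cohort, score it, describe
#' it, evaluate score against RTS, and write a report bundle. Deterministic
#' given the input; no stage mutates its input file.
#'
#' Files written to `out_dir`: `scored_records.csv` (records joined with
#' component scores), `summary.json` + `summary.md` (cohort description),
#' `evaluation.json`, and plot-data tables `plot_scatter.csv` (per-record
#' score/RTS with least-squares fit and 95% confidence band),
#' `plot_groups.csv` (per-record points labelled by dichotomized group, with
#' group mean/SD), `plot_muscles.csv` (RTS mean/SD by muscle count).
#'
#' @param input cohort data frame or path to a records CSV.
#' @param out_dir output directory (created if needed); `NULL` writes nothing.
#' @param rubric scoring rubric, or path to a rubric JSON config.
#' @param threshold dichotomization cut point (default 10).
#' @param quiet suppress stage logging.
#' @return invisibly, a list: `records`, `scores`, `summary`, `evaluation`,
#'   `exclusions`, `files` (paths written).
#' @export
run_pipeline <- function(input, out_dir = NULL, rubric = default_rubric(),
                         threshold = 10L, quiet = FALSE) {
  if (is.character(rubric)) rubric <- read_rubric(rubric)
  if (threshold < 1) {
    abort_hamscore("threshold must be >= 1", "hamscore_validation_error")
  }
  log_msg <- function(...) if (!quiet) message(sprintf(...))

  if (is.character(input)) {
    records <- read_records(input, quiet = quiet)
  } else {
    records <- validate_records(input)
  }
  exclusions <- attr(records, "exclusions") %||%
    data.frame(row = integer(), athlete_id = character(),
               reason = character())
  log_msg("stage score: %d records (%d excluded at read)",
          nrow(records), nrow(exclusions))

  scores <- tryCatch(
    score_records(records, rubric),
    error = function(e) stop("stage score: ", conditionMessage(e), call. = FALSE)
  )
  sm <- tryCatch(
    cohort_summary(records, rubric),
    error = function(e) stop("stage summarize: ", conditionMessage(e), call. = FALSE)
  )
  log_msg("stage summarize: %d MRI-positive analyzed, %d MRI-negative excluded",
          sm$n_analyzed, sm$n_mri_negative)
  n_rts <- sum(records$mri_positive & !is.na(records$rts_days))
  ev <- NULL
  if (n_rts >= 3) {
    ev <- tryCatch(
      evaluate_cohort(records, rubric, threshold),
      error = function(e) stop("stage evaluate: ", conditionMessage(e), call. = FALSE)
    )
    log_msg("stage evaluate: n = %d, Pearson r = %.3f", ev$n,
            ev$correlation$pearson_r)
  } else {
    log_msg("stage evaluate: skipped (only %d record(s) with recorded RTS)",
            n_rts)
  }

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wj <- function(x, name) {
      p <- file.path(out_dir, name)
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
      p
    }
    p_scored <- file.path(out_dir, "scored_records.csv")
    utils::write.csv(cbind(records, scores[-1]), p_scored, row.names = FALSE,
                     na = "")
    p_md <- file.path(out_dir, "summary.md")
    writeLines(format_summary_md(sm), p_md)

    files <- c(
      scored = p_scored,
      summary_json = wj(summary_to_list(sm), "summary.json"),
      summary_md = p_md
    )
    if (!is.null(ev)) {
      sc <- ev$scored
      fit <- stats::lm(rts_days ~ total, data = sc)
      pr <- stats::predict(fit, newdata = sc, interval = "confidence")
      p_scatter <- file.path(out_dir, "plot_scatter.csv")
      utils::write.csv(
        data.frame(sc, fit = pr[, "fit"], ci_lower = pr[, "lwr"],
                   ci_upper = pr[, "upr"]),
        p_scatter, row.names = FALSE
      )
      grp <- ifelse(sc$total >= threshold, "high", "low")
      gstat <- function(g, f) vapply(split(sc$rts_days, grp), f, numeric(1))[g]
      p_groups <- file.path(out_dir, "plot_groups.csv")
      utils::write.csv(
        data.frame(sc, group = grp,
                   group_mean = gstat(grp, mean),
                   group_sd = gstat(grp, stats::sd)),
        p_groups, row.names = FALSE
      )
      p_muscles <- file.path(out_dir, "plot_muscles.csv")
      bm <- ev$by_n_muscles
      utils::write.csv(
        data.frame(n_muscles = names(bm),
                   n = vapply(bm, `[[`, numeric(1), "n"),
                   mean_rts = vapply(bm, `[[`, numeric(1), "mean_rts"),
                   sd_rts = vapply(bm, `[[`, numeric(1), "sd_rts")),
        p_muscles, row.names = FALSE
      )
      files <- c(
        files,
        evaluation = wj(evaluation_to_list(ev), "evaluation.json"),
        scatter = p_scatter, groups = p_groups, muscles = p_muscles
      )
    }
  }
  invisible(list(records = records, scores = scores, summary = sm,
                 evaluation = ev, exclusions = exclusions, files = files))
}
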