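#' @title Injury records
#'
#' @description
#' A cohort is a plain `data.frame` with one row per injury and the columns
#' below; `injury_records()` builds and validates one, [read_records()] reads
#' one from CSV. The columns mirror a structured radiology reading plus the
#' outcome:
#'
#' * `athlete_id` — opaque identifier (character).
#' * `age` — athlete age in whole years, 18--50 (study eligibility).
#' * `mri_positive` — logical; `FALSE` rows carry no injury descriptors.
#' * `n_muscles` — number of hamstring muscles involved, 0--4.
#' * `primary_muscle` — most severely injured muscle:
#'   `biceps_femoris_long_head`, `biceps_femoris_short_head`,
#'   `semimembranosus`, `semitendinosus`; `NA` when MRI-negative.
#' * `location` — `proximal`, `middle` or `distal` along the muscle;
#'   `NA` when MRI-negative.
#' * `insertion_involved` — logical, insertional involvement.
#' * `transverse_pct` — percentage (0--100) of cross-sectional area involved.
#' * `retraction_cm` — tendon/muscle retraction in cm (non-negative).
#' * `sagittal_extent_cm` — craniocaudal extent of hyperintense signal in cm;
#'   strictly positive when MRI-positive.
#' * `rts_days` — days from injury to clearance for full training
#'   (positive integer), or `NA` when unknown at scoring time.
#'
#' @name injury-records
NULL

MUSCLES <- c("biceps_femoris_long_head", "biceps_femoris_short_head",
             "semimembranosus", "semitendinosus")
LOCATIONS <- c("proximal", "middle", "distal")

RECORD_COLUMNS <- c(
  "athlete_id", "age", "mri_positive", "n_muscles", "primary_muscle",
  "location", "insertion_involved", "transverse_pct", "retraction_cm",
  "sagittal_extent_cm", "rts_days"
)

#' Build a validated cohort data frame
#'
#' @param athlete_id character ids (defaults to `a1, a2, ...`).
#' @param age integer years, 18--50.
#' @param mri_positive logical.
#' @param n_muscles integer 0--4.
#' @param primary_muscle,location character or `NA` (see [injury-records]).
#' @param insertion_involved logical.
#' @param transverse_pct,retraction_cm,sagittal_extent_cm numeric.
#' @param rts_days positive integer or `NA`.
#' @return a `data.frame` passing [validate_records()].
#' @export
injury_records <- function(age, mri_positive = TRUE, n_muscles = 1L,
                           primary_muscle = "biceps_femoris_long_head",
                           location = "middle", insertion_involved = FALSE,
                           transverse_pct = 0, retraction_cm = 0,
                           sagittal_extent_cm = 1, rts_days = NA_integer_,
                           athlete_id = NULL) {
  n <- length(age)
  df <- data.frame(
    athlete_id = athlete_id %||% paste0("a", seq_len(n)),
    age = as.numeric(age),
    mri_positive = rep_len(mri_positive, n),
    n_muscles = rep_len(as.integer(n_muscles), n),
    primary_muscle = rep_len(as.character(primary_muscle), n),
    location = rep_len(as.character(location), n),
    insertion_involved = rep_len(insertion_involved, n),
    transverse_pct = rep_len(as.numeric(transverse_pct), n),
    retraction_cm = rep_len(as.numeric(retraction_cm), n),
    sagittal_extent_cm = rep_len(as.numeric(sagittal_extent_cm), n),
    rts_days = rep_len(as.integer(rts_days), n),
    stringsAsFactors = FALSE
  )
  neg <- !df$mri_positive
  df$n_muscles[neg] <- 0L
  df$primary_muscle[neg] <- NA_character_
  df$location[neg] <- NA_character_
  df$insertion_involved[neg] <- FALSE
  df$transverse_pct[neg] <- 0
  df$retraction_cm[neg] <- 0
  df$sagittal_extent_cm[neg] <- 0
  validate_records(df)
  df
}

#' Row-level validation of a cohort data frame
#'
#' Applies the record invariants and returns a character vector with one
#' element per row: `NA` for a valid row, otherwise the (first) reason the
#' row is invalid. Used by [read_records()] to reject rows with row-numbered
#' messages and by `validate_records()` to stop on any invalid row.
#'
#' @param df data frame with the [injury-records] columns.
#' @return character vector of length `nrow(df)`.
#' @export
record_problems <- function(df) {
  miss <- setdiff(RECORD_COLUMNS, names(df))
  if (length(miss)) {
    abort_hamscore(
      paste0("missing column(s): ", paste(miss, collapse = ", ")),
      "hamscore_schema_error"
    )
  }
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  set <- function(cond, msg) reason[is.na(reason) & cond] <<- msg

  set(!is.finite(df$age), "missing age")
  set(is.finite(df$age) & (df$age < 18 | df$age > 50),
      "age outside study eligibility 18-50")
  set(is.na(df$mri_positive), "missing mri_positive flag")
  pos <- !is.na(df$mri_positive) & df$mri_positive
  neg <- !is.na(df$mri_positive) & !df$mri_positive

  set(pos & is.na(df$transverse_pct), "missing cross-sectional area")
  set(!is.na(df$transverse_pct) &
        (df$transverse_pct < 0 | df$transverse_pct > 100),
      "transverse_pct outside [0,100]")
  set(pos & (is.na(df$n_muscles) | df$n_muscles < 1),
      "MRI-positive but no muscle involved")
  set(!is.na(df$n_muscles) & (df$n_muscles < 0 | df$n_muscles > 4),
      "n_muscles outside 0-4")
  set(pos & (is.na(df$primary_muscle) | !(df$primary_muscle %in% MUSCLES)),
      "missing or unknown primary muscle")
  set(pos & (is.na(df$location) | !(df$location %in% LOCATIONS)),
      "missing or unknown location")
  set(pos & (is.na(df$sagittal_extent_cm) | df$sagittal_extent_cm <= 0),
      "MRI-positive requires sagittal extent > 0")
  set(!is.na(df$retraction_cm) & df$retraction_cm < 0, "negative retraction")
  set(neg & (df$n_muscles != 0 | df$sagittal_extent_cm != 0 |
               df$transverse_pct != 0 | df$retraction_cm != 0 |
               df$insertion_involved),
      "MRI-negative row carries injury findings")
  set(!is.na(df$rts_days) & df$rts_days < 1, "rts_days must be >= 1")
  reason
}

#' @rdname record_problems
#' @return `validate_records()` returns `df` invisibly or stops with a
#'   row-numbered `hamscore_validation_error`.
#' @export
validate_records <- function(df) {
  reason <- record_problems(df)
  bad <- which(!is.na(reason))
  if (length(bad)) {
    msgs <- paste0("row ", bad, ": ", reason[bad])
    abort_hamscore(
      paste0("invalid record(s):\n  ", paste(msgs, collapse = "\n  ")),
      "hamscore_validation_error"
    )
  }
  invisible(df)
}
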