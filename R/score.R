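#' Score a cohort of injury records
#'
#' Applies the rubric to every row: each component's value is looked up in its
#' scoring bin and the awarded points are summed into the total. MRI-negative
#' records score 0 on every injury component and retain only the age
#' component. Non-integer ages are floored to whole years before binning.
#'
#' @param records cohort data frame (see [injury-records]).
#' @param rubric a `cohen_rubric`; defaults to [default_rubric()].
#' @return a `data.frame` with `athlete_id`, the seven component scores
#'   (`age_score`, `muscles_score`, `location_score`, `insertion_score`,
#'   `transverse_score`, `retraction_score`, `sagittal_score`) and `total`.
#' @export
#' @examples
#' rec <- injury_records(age = 24, n_muscles = 1, location = "middle",
#'                       transverse_pct = 30, sagittal_extent_cm = 12)
#' score_records(rec)$total  # 8
score_records <- function(records, rubric = default_rubric()) {
  validate_rubric(rubric)
  validate_records(records)

  pos <- records$mri_positive
  zero <- function(x) ifelse(pos, x, 0L)

  age_score <- lookup_numeric(rubric$age_years, floor(records$age))
  muscles_score <- zero(lookup_numeric(rubric$n_muscles, records$n_muscles))
  loc <- ifelse(pos, records$location, "none")
  location_score <- ifelse(
    pos, lookup_categorical(rubric$location, loc), 0L
  )
  ins <- ifelse(records$insertion_involved, "yes", "no")
  insertion_score <- zero(lookup_categorical(rubric$insertion, ins))
  transverse_score <- zero(lookup_numeric(rubric$transverse_pct,
                                          records$transverse_pct))
  retraction_score <- zero(lookup_numeric(rubric$retraction_cm,
                                          records$retraction_cm))
  sagittal_score <- zero(lookup_numeric(rubric$sagittal_cm,
                                        records$sagittal_extent_cm))

  out <- data.frame(
    athlete_id = records$athlete_id,
    age_score = as.integer(age_score),
    muscles_score = as.integer(muscles_score),
    location_score = as.integer(location_score),
    insertion_score = as.integer(insertion_score),
    transverse_score = as.integer(transverse_score),
    retraction_score = as.integer(retraction_score),
    sagittal_score = as.integer(sagittal_score),
    stringsAsFactors = FALSE
  )
  comp <- out[, -1, drop = FALSE]
  if (anyNA(comp)) {
    abort_hamscore("a component value fell outside every rubric bin",
                   "hamscore_validation_error")
  }
  out$total <- as.integer(rowSums(comp))
  out
}

#' Score a single injury record
#'
#' Convenience wrapper around [score_records()] for one record supplied as
#' individual fields.
#'
#' @inheritParams injury_records
#' @inheritParams score_records
#' @return a one-row component-score data frame (see [score_records()]).
#' @export
#' @examples
#' score_injury(age = 20, mri_positive = FALSE)$total  # 1
score_injury <- function(age, mri_positive = TRUE, n_muscles = 1L,
                         primary_muscle = "biceps_femoris_long_head",
                         location = "middle", insertion_involved = FALSE,
                         transverse_pct = 0, retraction_cm = 0,
                         sagittal_extent_cm = 1, rubric = default_rubric()) {
  rec <- injury_records(
    age = age, mri_positive = mri_positive, n_muscles = n_muscles,
    primary_muscle = primary_muscle, location = location,
    insertion_involved = insertion_involved, transverse_pct = transverse_pct,
    retraction_cm = retraction_cm, sagittal_extent_cm = sagittal_extent_cm
  )
  score_records(rec, rubric)
}

# one representative value inside each numeric bin, restricted to [lo_dom, hi_dom]
bin_representatives <- function(comp, lo_dom = 0, hi_dom = Inf) {
  reps <- lapply(comp$bins, function(b) {
    lo <- max(b$lower, lo_dom)
    hi <- min(b$upper, hi_dom)
    if (lo > hi) return(NULL)
    if (lo == hi) {
      if ((lo > b$lower || b$lower_closed) && (hi < b$upper || b$upper_closed)) {
        return(lo)
      }
      return(NULL)
    }
    x <- if (is.finite(hi)) (lo + hi) / 2 else lo + 1
    if (!bin_contains(b, x)) x <- lo + min(0.5, (hi - lo) / 2)
    if (bin_contains(b, x) && x >= lo_dom && x <= hi_dom) x else NULL
  })
  unlist(reps)
}

#' Achievable score range by exhaustive enumeration
#'
#' Brute-forces the rubric: takes one representative value per bin for every
#' component, subject to the record invariants for the given `mri_positive`
#' flag (age within eligibility 18--50; an MRI-positive injury forces at
#' least one muscle, a location, and a positive sagittal extent; an
#' MRI-negative record zeroes every injury component), scores every
#' combination through [score_records()], and returns the achievable minimum
#' and maximum total. This settles structurally what the score's floor and
#' ceiling are under a given rubric parsing, rather than hard-coding either.
#'
#' @param rubric a `cohen_rubric`.
#' @param mri_positive logical scalar: enumerate MRI-positive or MRI-negative
#'   records.
#' @return list with `min_total`, `max_total`, and `n_enumerated` (number of
#'   bin combinations scored).
#' @export
#' @examples
#' enumerate_score_range(default_rubric(), mri_positive = FALSE)$min_total # 1
#' enumerate_score_range(default_rubric(), mri_positive = TRUE)$min_total  # 4
enumerate_score_range <- function(rubric = default_rubric(), mri_positive = TRUE) {
  validate_rubric(rubric)
  ages <- bin_representatives(rubric$age_years, 18, 50)

  if (!mri_positive) {
    grid <- expand.grid(age = ages)
    recs <- injury_records(age = floor(grid$age), mri_positive = FALSE)
  } else {
    muscles <- bin_representatives(rubric$n_muscles, 1, 4)
    locs <- setdiff(names(rubric$location$levels), "none")
    ins <- names(rubric$insertion$levels)
    tv <- bin_representatives(rubric$transverse_pct, 0, 100)
    rt <- bin_representatives(rubric$retraction_cm, 0, Inf)
    sg <- bin_representatives(rubric$sagittal_cm, 0, Inf)
    sg <- sg[sg > 0]
    grid <- expand.grid(
      age = ages, n_muscles = muscles, location = locs, insertion = ins,
      transverse = tv, retraction = rt, sagittal = sg,
      stringsAsFactors = FALSE
    )
    recs <- injury_records(
      age = floor(grid$age), mri_positive = TRUE,
      n_muscles = floor(grid$n_muscles), location = grid$location,
      insertion_involved = grid$insertion == "yes",
      transverse_pct = grid$transverse, retraction_cm = grid$retraction,
      sagittal_extent_cm = grid$sagittal
    )
  }
  totals <- score_records(recs, rubric)$total
  list(
    min_total = min(totals),
    max_total = max(totals),
    n_enumerated = nrow(grid)
  )
}
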