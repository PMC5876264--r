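#' @title The Cohen MRI scoring rubric as data
#'
#' @description
#' The rubric is a declarative table of scoring bins, not code: each of the
#' seven components (athlete age, number of muscles involved, injury location,
#' insertional involvement, transverse cross-sectional percentage, retraction,
#' craniocaudal sagittal extent) carries an ordered list of bins, each bin
#' awarding an integer number of points in 0--3. Keeping the rubric as data
#' lets variant parsings (e.g. the original absolute-percentage reading of the
#' cross-sectional variable) be swapped in from a JSON config for sensitivity
#' analysis without touching the scorer.
#'
#' Numeric bins are intervals with explicit open/closed ends; categorical
#' components map labels to points. A valid rubric's bins are pairwise
#' disjoint and cover the component's domain.
#'
#' @name rubric
NULL

RUBRIC_COMPONENTS <- c(
  "age_years", "n_muscles", "location", "insertion",
  "transverse_pct", "retraction_cm", "sagittal_cm"
)

num_bin <- function(lower, upper, points, lower_closed = TRUE, upper_closed = FALSE) {
  list(
    lower = lower, upper = upper, points = as.integer(points),
    lower_closed = lower_closed, upper_closed = upper_closed
  )
}

#' Default scoring rubric
#'
#' Builds the standard seven-component rubric. Bin conventions: numeric bins
#' are lower-inclusive half-open intervals (`[25, 50)` etc.); the zero bins of
#' retraction and sagittal extent are the degenerate interval `[0, 0]`
#' (absence scores zero, any positive measurement scores at least 1).
#' Component maxima: age 3, muscles 3, location 3, insertion 2, transverse 3,
#' retraction 2, sagittal 3 (sum 19).
#'
#' @return An object of class `cohen_rubric`: a named list of components,
#'   each either `type = "numeric"` with a `bins` list or `type = "categorical"`
#'   with a named `levels` vector of points.
#' @seealso [read_rubric()], [write_rubric()], [score_injury()],
#'   [enumerate_score_range()]
#' @export
#' @examples
#' r <- default_rubric()
#' rubric_max_points(r)          # per-component maxima
#' sum(rubric_max_points(r))     # 19
default_rubric <- function() {
  rub <- list(
    age_years = list(type = "numeric", bins = list(
      num_bin(0, 26, 1),
      num_bin(26, 32, 2),
      num_bin(32, Inf, 3)
    )),
    n_muscles = list(type = "numeric", bins = list(
      num_bin(0, 1, 0),
      num_bin(1, 2, 1),
      num_bin(2, 3, 2),
      num_bin(3, Inf, 3)
    )),
    location = list(type = "categorical", levels = c(
      none = 0L, proximal = 1L, middle = 2L, distal = 3L
    )),
    insertion = list(type = "categorical", levels = c(no = 0L, yes = 2L)),
    transverse_pct = list(type = "numeric", bins = list(
      num_bin(0, 25, 0),
      num_bin(25, 50, 1),
      num_bin(50, 75, 2),
      num_bin(75, Inf, 3)
    )),
    retraction_cm = list(type = "numeric", bins = list(
      num_bin(0, 0, 0, upper_closed = TRUE),
      num_bin(0, 2, 1, lower_closed = FALSE),
      num_bin(2, Inf, 2)
    )),
    sagittal_cm = list(type = "numeric", bins = list(
      num_bin(0, 0, 0, upper_closed = TRUE),
      num_bin(0, 5, 1, lower_closed = FALSE),
      num_bin(5, 10, 2),
      num_bin(10, Inf, 3)
    ))
  )
  structure(rub, class = "cohen_rubric")
}

#' Absolute-percentage rubric variant
#'
#' A sensitivity-analysis variant in which the transverse cross-sectional
#' variable is read as the nearest of the absolute anchors 0, 25, 50, >=75%
#' (bin edges at the midpoints 12.5, 37.5, 62.5) instead of the quartile
#' bands of the default rubric. All other components are unchanged.
#'
#' @return A `cohen_rubric`.
#' @export
absolute_pct_rubric <- function() {
  rub <- default_rubric()
  rub$transverse_pct$bins <- list(
    num_bin(0, 12.5, 0),
    num_bin(12.5, 37.5, 1),
    num_bin(37.5, 62.5, 2),
    num_bin(62.5, Inf, 3)
  )
  rub
}

#' Per-component maximum points
#'
#' @param rubric a `cohen_rubric`.
#' @return named integer vector of each component's maximum awardable points.
#' @export
rubric_max_points <- function(rubric) {
  validate_rubric(rubric)
  vapply(rubric, function(comp) {
    if (comp$type == "numeric") {
      max(vapply(comp$bins, function(b) b$points, integer(1)))
    } else {
      max(comp$levels)
    }
  }, integer(1))
}

#' Validate a rubric
#'
#' Checks structural invariants: all seven components present; points are
#' integers in 0--3; numeric bins are pairwise disjoint and jointly cover the
#' non-negative reals (checked on a dense probe grid including all bin
#' endpoints and near-endpoint values).
#'
#' @param rubric object to validate.
#' @return `rubric`, invisibly, if valid; otherwise an error of class
#'   `hamscore_rubric_error`.
#' @export
validate_rubric <- function(rubric) {
  if (!inherits(rubric, "cohen_rubric")) {
    abort_hamscore("not a 'cohen_rubric' object", "hamscore_rubric_error")
  }
  missing <- setdiff(RUBRIC_COMPONENTS, names(rubric))
  if (length(missing)) {
    abort_hamscore(
      paste0("rubric missing component(s): ", paste(missing, collapse = ", ")),
      "hamscore_rubric_error"
    )
  }
  for (nm in RUBRIC_COMPONENTS) {
    comp <- rubric[[nm]]
    pts <- if (comp$type == "numeric") {
      vapply(comp$bins, function(b) b$points, integer(1))
    } else {
      as.integer(comp$levels)
    }
    if (any(pts < 0L | pts > 3L)) {
      abort_hamscore(
        paste0("component '", nm, "': points must be integers in 0..3"),
        "hamscore_rubric_error"
      )
    }
    if (comp$type == "numeric") {
      probes <- unlist(lapply(comp$bins, function(b) {
        c(b$lower, b$upper, b$lower + 1e-9, b$upper - 1e-9,
          if (is.finite(b$upper)) (b$lower + b$upper) / 2 else b$lower + 1)
      }))
      probes <- probes[is.finite(probes) & probes >= 0]
      for (x in unique(probes)) {
        hits <- sum(vapply(comp$bins, function(b) bin_contains(b, x), logical(1)))
        if (hits != 1L) {
          abort_hamscore(
            sprintf("component '%s': value %g matched by %d bins (must be exactly 1)",
                    nm, x, hits),
            "hamscore_rubric_error"
          )
        }
      }
    }
  }
  invisible(rubric)
}

bin_contains <- function(b, x) {
  lo <- if (b$lower_closed) x >= b$lower else x > b$lower
  hi <- if (b$upper_closed) x <= b$upper else x < b$upper
  lo & hi
}

# vectorized bin lookup: points for each x (NA where no bin matches)
lookup_numeric <- function(comp, x) {
  pts <- rep(NA_integer_, length(x))
  for (b in comp$bins) {
    pts[bin_contains(b, x)] <- b$points
  }
  pts
}

lookup_categorical <- function(comp, labels) {
  idx <- match(labels, names(comp$levels))
  as.integer(comp$levels[idx])
}

#' Read / write a rubric config
#'
#' Rubric configs are JSON: one entry per component; numeric bins carry
#' `lower`/`upper` (with `null` meaning unbounded above) and open/closed
#' flags; categorical components carry a label-to-points map. The shipped
#' default config (`system.file("extdata", "rubric_default.json",
#' package = "hamscore")`) reproduces [default_rubric()] bit-exactly.
#'
#' @param path file path of the JSON config.
#' @return `read_rubric()` returns a validated `cohen_rubric`;
#'   `write_rubric()` returns `path` invisibly.
#' @export
read_rubric <- function(path) {
  raw <- jsonlite::read_json(path)
  rub <- lapply(raw, function(comp) {
    if (identical(comp$type, "numeric")) {
      list(type = "numeric", bins = lapply(comp$bins, function(b) {
        num_bin(
          lower = b$lower,
          upper = if (is.null(b$upper)) Inf else b$upper,
          points = b$points,
          lower_closed = b$lower_closed %||% TRUE,
          upper_closed = b$upper_closed %||% FALSE
        )
      }))
    } else {
      list(type = "categorical",
           levels = vapply(comp$levels, as.integer, integer(1)))
    }
  })
  rub <- structure(rub[RUBRIC_COMPONENTS], class = "cohen_rubric")
  validate_rubric(rub)
  rub
}

#' @rdname read_rubric
#' @param rubric a `cohen_rubric` to serialize.
#' @export
write_rubric <- function(rubric, path) {
  validate_rubric(rubric)
  out <- lapply(rubric, function(comp) {
    if (comp$type == "numeric") {
      list(type = "numeric", bins = lapply(comp$bins, function(b) {
        list(
          lower = b$lower,
          upper = if (is.finite(b$upper)) b$upper else NULL,
          points = b$points,
          lower_closed = b$lower_closed,
          upper_closed = b$upper_closed
        )
      }))
    } else {
      list(type = "categorical", levels = as.list(comp$levels))
    }
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.cohen_rubric <- function(x, ...) {
  cat("<cohen_rubric> 7 components, per-component maxima:\n")
  print(rubric_max_points(x))
  invisible(x)
}
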