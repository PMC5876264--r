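test_that("default rubric encodes the published grid", {
  r <- default_rubric()
  expect_s3_class(r, "cohen_rubric")
  expect_silent(validate_rubric(r))

  # age band edges: 25 -> 1, 26 -> 2, 31 -> 2, 32 -> 3
  expect_identical(
    unname(vapply(c(25, 26, 31, 32), function(a)
      score_injury(age = a, mri_positive = FALSE)$age_score, integer(1))),
    c(1L, 2L, 2L, 3L)
  )
  # absence of insertional involvement scores zero
  expect_identical(score_injury(age = 20)$insertion_score, 0L)

  maxima <- rubric_max_points(r)
  expect_identical(
    maxima[c("age_years", "n_muscles", "location", "insertion",
             "transverse_pct", "retraction_cm", "sagittal_cm")],
    c(age_years = 3L, n_muscles = 3L, location = 3L, insertion = 2L,
      transverse_pct = 3L, retraction_cm = 2L, sagittal_cm = 3L)
  )
  expect_identical(sum(maxima), 19L)
})

test_that("worked scoring examples", {
  # hand-applied grid: age 24->1, 1 muscle->1, middle->2, no insertion->0,
  # 30% transverse->1, 0 cm retraction->0, 12 cm sagittal->3; total 8
  sc <- score_injury(age = 24, n_muscles = 1, location = "middle",
                     transverse_pct = 30, retraction_cm = 0,
                     sagittal_extent_cm = 12)
  expect_identical(
    unlist(sc[c("age_score", "muscles_score", "location_score",
                "insertion_score", "transverse_score", "retraction_score",
                "sagittal_score")], use.names = FALSE),
    c(1L, 1L, 2L, 0L, 1L, 0L, 3L)
  )
  expect_identical(sc$total, 8L)

  # MRI-negative athlete keeps only the age component
  expect_identical(score_injury(age = 20, mri_positive = FALSE)$total, 1L)

  # every component at its top bin reaches the enumeration maximum
  top <- score_injury(age = 39, n_muscles = 3, location = "distal",
                      insertion_involved = TRUE, transverse_pct = 80,
                      retraction_cm = 3, sagittal_extent_cm = 15)
  expect_identical(top$total,
                   enumerate_score_range(default_rubric(), TRUE)$max_total)
})

test_that("validation rejects out-of-domain fields by name", {
  expect_error(score_injury(age = 17), "age")
  expect_error(score_injury(age = 51), "age")
  expect_error(score_injury(age = 30, transverse_pct = 150), "transverse_pct")
  expect_error(
    injury_records(age = 30, mri_positive = TRUE, sagittal_extent_cm = 0),
    "sagittal"
  )
})

test_that("score range enumeration settles the structural bounds", {
  r <- default_rubric()
  neg <- enumerate_score_range(r, mri_positive = FALSE)
  pos <- enumerate_score_range(r, mri_positive = TRUE)
  expect_identical(neg$min_total, 1L)  # an MRI-negative athlete can score 1
  expect_identical(neg$max_total, 3L)
  expect_identical(pos$min_total, 4L)  # consistent with the observed range 4-12
  expect_identical(pos$max_total, 19L)
  expect_gt(pos$n_enumerated, 1000)

  # the absolute-percentage variant shifts bins, not the achievable bounds
  alt <- enumerate_score_range(absolute_pct_rubric(), TRUE)
  expect_identical(alt$min_total, 4L)
  expect_identical(alt$max_total, 19L)
})

test_that("rubric JSON round-trip is bit-exact and shipped config matches", {
  r <- default_rubric()
  path <- withr::local_tempfile(fileext = ".json")
  write_rubric(r, path)
  expect_equal(read_rubric(path), r)

  shipped <- system.file("extdata", "rubric_default.json",
                         package = "hamscore")
  expect_equal(read_rubric(shipped), r)
  shipped_alt <- system.file("extdata", "rubric_absolute_pct.json",
                             package = "hamscore")
  expect_equal(read_rubric(shipped_alt), absolute_pct_rubric())
})

test_that("malformed rubrics are rejected", {
  r <- default_rubric()
  r$age_years <- NULL
  expect_error(validate_rubric(r), "missing component")

  r2 <- default_rubric()
  r2$transverse_pct$bins[[2]]$lower <- 20  # overlaps bin 1
  expect_error(validate_rubric(r2), "matched by 2 bins")

  r3 <- default_rubric()
  r3$age_years$bins[[1]]$points <- 7L
  expect_error(validate_rubric(r3), "points")
})

test_that("bin lookup is consistent across each component's domain", {
  r <- default_rubric()
  sweep_expect <- function(values, field, expected, ...) {
    got <- vapply(values, function(v) {
      args <- list(age = 30, ...)
      args[[field]] <- v
      do.call(score_injury, args)[[1, paste0(sub("_.*", "", field), "_score")]]
    }, integer(1))
    expect_identical(got, as.integer(expected))
  }
  # transverse: one probe per percent
  tv <- 0:100
  sweep_expect(tv, "transverse_pct",
               ifelse(tv < 25, 0, ifelse(tv < 50, 1, ifelse(tv < 75, 2, 3))))
  # sagittal: absence 0, then (0,5) -> 1, [5,10) -> 2, >=10 -> 3
  sg <- c(0.01, 0.5, 4.99, 5, 9.99, 10, 19)
  got_sg <- vapply(sg, function(v)
    score_injury(age = 30, sagittal_extent_cm = v)$sagittal_score, integer(1))
  expect_identical(got_sg, c(1L, 1L, 1L, 2L, 2L, 3L, 3L))
  # retraction: exactly zero scores 0, any positive below 2 scores 1
  rt <- c(0, 0.01, 1.99, 2, 5)
  got_rt <- vapply(rt, function(v)
    score_injury(age = 30, retraction_cm = v)$retraction_score, integer(1))
  expect_identical(got_rt, c(0L, 1L, 1L, 2L, 2L))
})

test_that("monotonicity: worsening any graded finding never lowers the total", {
  rec <- random_records(300, seed = 11)
  base <- score_records(rec)$total
  bump <- function(field, delta, cap = Inf) {
    worse <- rec
    worse[[field]] <- pmin(worse[[field]] + delta, cap)
    score_records(worse)$total
  }
  expect_true(all(bump("transverse_pct", 25, cap = 100) >= base))
  expect_true(all(bump("retraction_cm", 2) >= base))
  expect_true(all(bump("sagittal_extent_cm", 5) >= base))
  worse <- rec; worse$n_muscles <- pmin(worse$n_muscles + 1L, 4L)
  expect_true(all(score_records(worse)$total >= base))
})

test_that("scoring is deterministic and bounded by the enumerated range", {
  rec <- random_records(500, seed = 12, p_negative = 0.2)
  s1 <- score_records(rec)
  s2 <- score_records(rec)
  expect_identical(s1, s2)

  rng_pos <- enumerate_score_range(default_rubric(), TRUE)
  rng_neg <- enumerate_score_range(default_rubric(), FALSE)
  pos <- rec$mri_positive
  expect_true(all(s1$total[pos] >= rng_pos$min_total &
                    s1$total[pos] <= rng_pos$max_total))
  expect_true(all(s1$total[!pos] >= rng_neg$min_total &
                    s1$total[!pos] <= rng_neg$max_total))
})
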