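# shared helpers: random-record generation and naive statistical oracles

MUSCLE_LEVELS <- c("biceps_femoris_long_head", "biceps_femoris_short_head",
                   "semimembranosus", "semitendinosus")

# random valid records spanning the full domain (not the cohort marginals)
random_records <- function(n, seed, p_negative = 0) {
  set.seed(seed)
  neg <- stats::runif(n) < p_negative
  rec <- injury_records(
    age = sample(18:50, n, replace = TRUE),
    mri_positive = !neg,
    n_muscles = sample(1:4, n, replace = TRUE),
    primary_muscle = sample(MUSCLE_LEVELS, n, replace = TRUE),
    location = sample(c("proximal", "middle", "distal"), n, replace = TRUE),
    insertion_involved = stats::runif(n) < 0.2,
    transverse_pct = stats::runif(n, 0, 100),
    retraction_cm = ifelse(stats::runif(n) < 0.5, 0, stats::runif(n, 0, 4)),
    sagittal_extent_cm = stats::runif(n, 0.01, 20)
  )
  rec
}

# naive textbook formulas used as the independent oracle route
naive_mean <- function(x) sum(x) / length(x)
naive_sd <- function(x) {
  m <- naive_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
naive_pearson <- function(x, y) {
  mx <- naive_mean(x); my <- naive_mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
naive_midranks <- function(x) {
  # mid-rank of tied values via pairwise comparison counts
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}
naive_spearman <- function(x, y) {
  naive_pearson(naive_midranks(x), naive_midranks(y))
}
naive_cohens_d <- function(hi, lo) {
  sp <- sqrt(((length(hi) - 1) * naive_sd(hi)^2 +
                (length(lo) - 1) * naive_sd(lo)^2) /
               (length(hi) + length(lo) - 2))
  (naive_mean(hi) - naive_mean(lo)) / sp
}
# type-7 quantile by its defining formula
naive_q7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
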