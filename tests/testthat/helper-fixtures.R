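## Shared fixtures: cohorts are expensive, build each once per test run.

.fixture_env <- new.env(parent = emptyenv())

tug_cohort <- function(distance_m, seed = 7, n_subjects = 16,
                       trials_per_subject = 2) {
  key <- paste0("cohort_", distance_m, "_", seed, "_", n_subjects, "_",
                trials_per_subject)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulateCohort(n_subjects, trials_per_subject,
                                          distance_m, seed = seed)
  }
  .fixture_env[[key]]
}

tug_classifications <- function(distance_m, seed = 7) {
  key <- paste0("cls_", distance_m, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cohort <- tug_cohort(distance_m, seed)
    .fixture_env[[key]] <- lapply(cohort, function(s)
      classifyTrial(s$recording))
  }
  .fixture_env[[key]]
}

tug_trial <- function(seed = 42, ...) {
  key <- paste0("trial_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulateTug(tugParams(seed = seed, ...))
  }
  .fixture_env[[key]]
}

## minimal single-channel recording from a numeric vector
vector_recording <- function(x, site = "trunk", quantity = "acceleration",
                             axis = "z", rate_hz = 60) {
  TugRecording(matrix(x, nrow = 1),
               data.frame(site = site, quantity = quantity, axis = axis),
               rate_hz = rate_hz, distance_m = 10)
}

## brute-force oracle: nearest local extremum of the requested kind on the
## requested side of a peak index, via exhaustive enumeration of all
## extrema (plateaus credited to their earliest sample)
brute_first_extremum <- function(x, peak_idx, kind, side, rate_hz = 60) {
  n <- length(x)
  keep <- c(TRUE, x[-1] != x[-n])
  starts <- which(keep)
  v <- x[starts]
  m <- length(v)
  idx <- integer()
  if (m >= 3) {
    j <- 2:(m - 1)
    if (kind == "min") idx <- starts[j][v[j] < v[j - 1] & v[j] < v[j + 1]]
    else idx <- starts[j][v[j] > v[j - 1] & v[j] > v[j + 1]]
  }
  cand <- if (side == "left") idx[idx < peak_idx] else idx[idx > peak_idx]
  if (length(cand) == 0L)
    return(if (side == "left") 0 else (n - 1) / rate_hz)
  j <- if (side == "left") max(cand) else min(cand)
  (j - 1) / rate_hz
}
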