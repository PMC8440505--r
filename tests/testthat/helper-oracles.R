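## Independent oracles and shared fixtures.

library(data.table)

## Expand (values, integer weights) into the explicit multiset.
expand_multiset <- function(values, weights) {
  rep(values, times = weights)
}

## Exhaustive optimal 2-partition of the rows of X by total within-cluster
## sum of squares. Feasible for n <= ~12.
brute_force_kmeans2 <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  ss <- function(M) {
    if (nrow(M) == 0L) return(0)
    sum(sweep(M, 2L, colMeans(M), "-")^2)
  }
  best <- Inf
  best_assign <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {     # fix row 1 in cluster 1: halves the space
    in1 <- c(TRUE, bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    total <- ss(X[in1, , drop = FALSE]) + ss(X[!in1, , drop = FALSE])
    if (total < best) {
      best <- total
      best_assign <- in1
    }
  }
  list(inertia = best, assign = ifelse(best_assign, 1L, 2L))
}

## Three well-separated 6-D blobs for k-selection fixtures.
make_blobs <- function(n_per = 20, gap = 30, sd = 0.5, seed = 7) {
  set.seed(seed)
  centers <- rbind(rep(0, 6), rep(gap, 6), c(rep(0, 3), rep(gap, 3)))
  X <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rnorm(n_per * 6, mean = rep(centers[i, ], each = n_per), sd = sd),
           ncol = 6)
  }))
  list(X = X, labels = rep(1:3, each = n_per))
}

## Toy two-practice, two-month prescribing world with hand-computable
## series values.
make_toy_prescribing <- function() {
  months <- c("2018-04", "2018-05")
  records <- data.table(
    practice_id = rep(c("A", "B"), each = 4),
    year_month = rep(months, times = 4),
    bnf_chapter = rep(c(1L, 2L), each = 2, times = 2),
    bnf_section = 1L,
    items = c(100L, 120L, 50L, 60L,   # practice A: ch1 then ch2
              200L, 210L, 80L, 90L))  # practice B
  sizes <- data.table(
    practice_id = rep(c("A", "B"), each = 2),
    year_month = rep(months, times = 2),
    registered_patients = c(1000L, 1000L, 2000L, 2000L))
  assignments <- data.table(practice_id = c("A", "B"),
                            label = c("L1", "L2"))
  list(records = records, sizes = sizes, assignments = assignments,
       months = months)
}

## The default record-level cohort is expensive enough to share across
## test files; memoised per test run.
.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed = 42L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_records(seed = seed)
  }
  .fixture_cache[[key]]
}

default_cohort_profiles <- function(seed = 42L) {
  key <- paste0("profiles_", seed)
  if (is.null(.fixture_cache[[key]])) {
    coh <- default_cohort(seed)
    .fixture_cache[[key]] <- suppressMessages(build_practice_profiles(
      coh$dispensing, coh$sizes, load_coordinate_lookup(coh$coordinates),
      coh$areas, coh$window))
  }
  .fixture_cache[[key]]
}
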