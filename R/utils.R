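## Internal helpers: months, seeds, small numerics.

#' Canonical feature order used throughout the package
#'
#' The six practice-level clustering features, in the fixed order used by
#' every matrix-valued interface (feature matrices, centroids,
#' standardisation parameters).
#'
#' @return Character vector of the six feature names.
#' @export
feature_names <- function() {
  c("n_pharmacies", "items_per_patient", "median_distance_km",
    "sd_distance_km", "population_density", "registered_patients")
}

stop_ <- function(...) stop(..., call. = FALSE)

## --- year-month handling ("YYYY-MM" strings) ---------------------------------

check_ym <- function(x, what = "year_month") {
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", x)
  if (!all(ok)) {
    stop_(sprintf("invalid %s value(s): %s", what,
                  paste(unique(x[!ok]), collapse = ", ")))
  }
  invisible(x)
}

ym_index <- function(ym) {
  check_ym(ym)
  y <- as.integer(substr(ym, 1, 4))
  m <- as.integer(substr(ym, 6, 7))
  y * 12L + (m - 1L)
}

ym_from_index <- function(i) {
  sprintf("%04d-%02d", i %/% 12L, (i %% 12L) + 1L)
}

#' Sequence of consecutive calendar months
#'
#' @param start first month as a `"YYYY-MM"` string
#' @param n number of consecutive months
#' @return Character vector of `n` months starting at `start`.
#' @export
ym_seq <- function(start, n) {
  stopifnot(length(start) == 1, n >= 1)
  ym_from_index(ym_index(start) + seq_len(n) - 1L)
}

## A clustering window must be exactly 12 consecutive months. Accepts either
## the vector of months or a single start month.
resolve_window <- function(window) {
  if (length(window) == 1L) window <- ym_seq(window, 12L)
  check_ym(window, "window month")
  if (length(window) != 12L || !all(diff(ym_index(window)) == 1L)) {
    stop_("window must be exactly 12 consecutive months")
  }
  window
}

## --- randomness --------------------------------------------------------------

## Evaluate code under a temporary RNG state so package functions are
## deterministic given their seed argument without clobbering the caller's
## random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a sub-stream seed from a master seed
#'
#' All stochastic stages consume seeds derived from one master seed through
#' this fixed affine-mod scheme, so individual stages can be regenerated
#' independently while the whole run stays reproducible.
#'
#' @param seed master seed (integer)
#' @param stream small non-negative integer identifying the stream
#' @return An integer seed `< 2^31`.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 65011) * 33013 + stream * 7907 + 17) %% 2147483629L
}

## --- partition agreement -----------------------------------------------------

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used for cluster label-recovery checks. Equals 1 for identical partitions
#' (up to label permutation) and has expectation 0 under random labelings.
#'
#' @param a,b label vectors of equal length
#' @return A number `<= 1`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## Coerce a data.frame-ish input and check required columns.
as_table <- function(x, required, what) {
  if (!is.data.frame(x)) stop_(sprintf("%s must be a data.frame", what))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop_(sprintf("%s is missing column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  as.data.table(x)
}
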