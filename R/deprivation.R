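## Ward deprivation quartiles and the cluster-by-quartile cross-tabulation.
##
## Quartile Q1 holds the least deprived wards and Q4 the most deprived. The
## default rank convention is "1 = most deprived" (the usual multiple
## deprivation measure convention); it is configurable because published
## rankings differ.

#' Assign wards to deprivation quartiles
#'
#' Sorts wards from least to most deprived and splits them into four groups
#' whose sizes differ by at most one; when `W` is not divisible by 4 the
#' remainder goes to the lower quartile numbers (Q1 first).
#'
#' @param ward_ranks data.frame `ward_code,deprivation_rank`; ranks must be
#'   a permutation of `1..W`.
#' @param rank_direction `"most_deprived_first"` (rank 1 = most deprived,
#'   default) or `"least_deprived_first"`.
#' @return data.table `ward_code,quartile` with quartile in `"Q1".."Q4"`.
#' @export
assign_quartiles <- function(ward_ranks,
                             rank_direction = c("most_deprived_first",
                                                "least_deprived_first")) {
  rank_direction <- match.arg(rank_direction)
  ward_ranks <- as_table(ward_ranks, c("ward_code", "deprivation_rank"),
                         "ward ranks")
  W <- nrow(ward_ranks)
  r <- ward_ranks$deprivation_rank
  if (!setequal(r, seq_len(W)) || anyDuplicated(r)) {
    stop_("deprivation ranks must be a permutation of 1..W")
  }
  ## deprivation order: position 1 = least deprived ward
  least_first <- if (rank_direction == "most_deprived_first") -r else r
  pos <- rank(least_first)          # 1 = least deprived
  sizes <- rep(W %/% 4L, 4L)
  rem <- W %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  breaks <- cumsum(sizes)
  q <- findInterval(pos, c(0L, breaks), left.open = TRUE)
  out <- data.table(ward_code = ward_ranks$ward_code,
                    quartile = paste0("Q", q))
  setorder(out, ward_code)[]
}

#' Cross-tabulate cluster membership by deprivation quartile
#'
#' @param assignments data.frame `practice_id,label`.
#' @param practice_wards data.frame `practice_id,ward_code`.
#' @param quartiles data.frame `ward_code,quartile` (see
#'   [assign_quartiles()]).
#' @return data.table with one row per cluster: `label, Q1, Q2, Q3, Q4`
#'   (percentages of the cluster's practices, unrounded; each row sums to
#'   100) and `n` (cluster size).
#' @export
deprivation_crosstab <- function(assignments, practice_wards, quartiles) {
  assignments <- as_table(assignments, c("practice_id", "label"),
                          "assignments")
  practice_wards <- as_table(practice_wards, c("practice_id", "ward_code"),
                             "practice wards")
  quartiles <- as_table(quartiles, c("ward_code", "quartile"), "quartiles")
  d <- merge(assignments, practice_wards, by = "practice_id")
  if (nrow(d) < nrow(assignments)) {
    stop_(sprintf("practice(s) without a ward: %s",
                  paste(setdiff(assignments$practice_id, d$practice_id),
                        collapse = ", ")))
  }
  d <- merge(d, quartiles, by = "ward_code")
  if (nrow(d) < nrow(assignments)) stop_("ward(s) without a quartile")
  out <- d[, {
    counts <- vapply(paste0("Q", 1:4), function(q) sum(quartile == q),
                     numeric(1))
    as.list(c(100 * counts / .N, n = .N))
  }, by = label]
  setorder(out, label)[]
}

#' Size-weighted all-practices quartile row
#'
#' Combines per-cluster percentage rows into the overall row: the weighted
#' average with cluster sizes as weights, which equals the crosstab computed
#' on the pooled practice set.
#'
#' @param cluster_rows matrix or data.frame with columns `Q1..Q4`, one row
#'   per cluster (percentages).
#' @param cluster_sizes positive cluster sizes, one per row.
#' @return Named numeric vector `Q1..Q4`.
#' @export
overall_row <- function(cluster_rows, cluster_sizes) {
  M <- as.matrix(as.data.frame(cluster_rows)[, paste0("Q", 1:4)])
  if (nrow(M) != length(cluster_sizes)) {
    stop_("one size per cluster row required")
  }
  if (any(cluster_sizes <= 0)) stop_("cluster sizes must be positive")
  w <- cluster_sizes / sum(cluster_sizes)
  out <- as.numeric(t(M) %*% w)
  names(out) <- paste0("Q", 1:4)
  out
}

#' Share of a cluster in the two most-deprived quartiles
#'
#' @param cluster_row named vector or one-row data.frame with `Q1..Q4`.
#' @return `Q3 + Q4`, in percent.
#' @export
top_two_quartile_share <- function(cluster_row) {
  row <- as.list(cluster_row)
  as.numeric(row$Q3) + as.numeric(row$Q4)
}
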