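## BNF-coded prescribing analysis: cleaning, per-patient monthly series by
## cluster, RMSE comparison across chapters/sections, and Welch t-tests.
##
## Cluster-level normalisation pools items and patients: value(month) =
## sum(items of the cluster's practices) / sum(their registered patients).
## Pooling (rather than averaging per-practice ratios) keeps small practices
## from dominating and matches how list-size normalisation is done on the
## published open data.

#' Remove records lacking BNF chapter or section information
#'
#' Rows with a missing chapter or section are assigned chapter 99 and
#' excluded from all further analysis; rows already coded 99 are excluded
#' too. The excluded fraction is reported and logged.
#'
#' @param records prescribing table
#'   (`practice_id,year_month,bnf_chapter,bnf_section,items`); missing
#'   chapter/section as NA.
#' @return List with `records` (retained rows) and `excluded_fraction`.
#' @export
clean_bnf <- function(records) {
  records <- as_table(records,
                      c("practice_id", "year_month", "bnf_chapter",
                        "bnf_section", "items"),
                      "prescribing")
  n <- nrow(records)
  if (n == 0L) return(list(records = records, excluded_fraction = 0))
  bad <- is.na(records$bnf_chapter) | is.na(records$bnf_section) |
    records$bnf_chapter == 99L
  frac <- sum(bad) / n
  message(sprintf("chapter-99 cleaning: excluded %d of %d rows (%.3f%%)",
                  sum(bad), n, 100 * frac))
  list(records = records[!bad], excluded_fraction = frac)
}

## pooled registered patients per (label, month)
cluster_patient_totals <- function(sizes, assignments, months) {
  sizes <- as_table(sizes,
                    c("practice_id", "year_month", "registered_patients"),
                    "sizes")
  assignments <- as_table(assignments, c("practice_id", "label"),
                          "assignments")
  sz <- merge(sizes[year_month %in% months], assignments, by = "practice_id")
  pt <- sz[, .(patients = sum(registered_patients)),
           by = .(label, year_month)]
  full <- CJ(label = unique(assignments$label), year_month = months)
  pt <- merge(full, pt, by = c("label", "year_month"), all.x = TRUE)
  if (any(is.na(pt$patients) | pt$patients <= 0)) {
    stop_("month with zero registered patients for some cluster")
  }
  pt
}

#' Items-per-patient monthly series per cluster
#'
#' For each cluster and month, total items (optionally restricted to one BNF
#' chapter, or broken out by chapter or by section within a chapter) divided
#' by the pooled registered patients of the cluster's practices that month.
#' Months absent from the records contribute 0 items.
#'
#' @param records cleaned prescribing table.
#' @param sizes monthly list sizes.
#' @param assignments `practice_id,label` table (see [assignment_table()]).
#' @param level `"total"`, `"chapter"`, or `"section"`.
#' @param chapter required when `level = "section"`: the BNF chapter whose
#'   sections are profiled.
#' @return data.table `label[,chapter][,section],year_month,value` with a
#'   complete, aligned month grid per group.
#' @export
monthly_cluster_series <- function(records, sizes, assignments,
                                   level = c("total", "chapter", "section"),
                                   chapter = NULL) {
  level <- match.arg(level)
  records <- as_table(records,
                      c("practice_id", "year_month", "bnf_chapter",
                        "bnf_section", "items"),
                      "prescribing")
  assignments <- as_table(assignments, c("practice_id", "label"),
                          "assignments")
  unmatched <- setdiff(unique(records$practice_id), assignments$practice_id)
  if (length(unmatched)) {
    stop_(sprintf("practice(s) without a cluster label: %s",
                  paste(head(unmatched, 10L), collapse = ", ")))
  }
  months <- sort(unique(records$year_month))
  check_ym(months)
  pt <- cluster_patient_totals(sizes, assignments, months)
  rec <- merge(records, assignments, by = "practice_id")

  if (level == "section") {
    if (is.null(chapter)) stop_("level = 'section' requires a chapter")
    rec <- rec[bnf_chapter == chapter]
    grid_extra <- list(section = sort(unique(rec$bnf_section)))
    agg <- rec[, .(items = sum(items)),
               by = .(label, section = bnf_section, year_month)]
  } else if (level == "chapter") {
    grid_extra <- list(chapter = sort(unique(rec$bnf_chapter)))
    agg <- rec[, .(items = sum(items)),
               by = .(label, chapter = bnf_chapter, year_month)]
  } else {
    grid_extra <- list()
    agg <- rec[, .(items = sum(items)), by = .(label, year_month)]
  }

  grid <- do.call(CJ, c(list(label = unique(assignments$label)),
                        grid_extra, list(year_month = months)))
  out <- merge(grid, agg, by = names(grid), all.x = TRUE)
  out[is.na(items), items := 0L]
  out <- merge(out, pt, by = c("label", "year_month"))
  out[, value := items / patients]
  out[, c("items", "patients") := NULL]
  setorderv(out, c(setdiff(names(grid), "year_month"), "year_month"))
  out[]
}

#' Root-mean-square error between two aligned monthly series
#'
#' `sqrt(mean((a - b)^2))` over the common months; the month vectors must be
#' identical -- no implicit truncation or alignment.
#'
#' @param a,b either numeric vectors of equal length or data.frames with
#'   `year_month` and `value` columns.
#' @return Non-negative number.
#' @export
rmse <- function(a, b) {
  if (is.data.frame(a) || is.data.frame(b)) {
    a <- as_table(a, c("year_month", "value"), "series a")
    b <- as_table(b, c("year_month", "value"), "series b")
    if (!identical(a$year_month, b$year_month)) {
      stop_("series months are not aligned")
    }
    a <- a$value; b <- b$value
  }
  if (length(a) != length(b)) stop_("series lengths differ")
  if (length(a) == 0L) stop_("empty series")
  sqrt(mean((a - b)^2))
}

#' Rank BNF chapters by between-cluster RMSE
#'
#' Builds the per-chapter items-per-patient series for each of the two
#' clusters and ranks chapters by the RMSE between the two series,
#' descending; ties broken by chapter number.
#'
#' @inheritParams monthly_cluster_series
#' @return data.table `chapter,rmse` sorted by decreasing RMSE.
#' @export
chapter_rmse_ranking <- function(records, sizes, assignments) {
  assignments <- as_table(assignments, c("practice_id", "label"),
                          "assignments")
  labs <- sort(unique(assignments$label))
  if (length(labs) != 2L) stop_("chapter ranking requires exactly two clusters")
  ser <- monthly_cluster_series(records, sizes, assignments, "chapter")
  out <- ser[, {
    a <- value[label == labs[1L]][order(year_month[label == labs[1L]])]
    b <- value[label == labs[2L]][order(year_month[label == labs[2L]])]
    .(rmse = rmse(a, b))
  }, by = chapter]
  setorder(out, -rmse, chapter)[]
}

#' Rank sections of one chapter by between-cluster RMSE
#'
#' @inheritParams monthly_cluster_series
#' @param chapter the BNF chapter to break into sections.
#' @return data.table `section,rmse` sorted by decreasing RMSE.
#' @export
section_rmse_ranking <- function(records, sizes, assignments, chapter) {
  assignments <- as_table(assignments, c("practice_id", "label"),
                          "assignments")
  labs <- sort(unique(assignments$label))
  if (length(labs) != 2L) stop_("section ranking requires exactly two clusters")
  ser <- monthly_cluster_series(records, sizes, assignments, "section",
                                chapter = chapter)
  out <- ser[, {
    a <- value[label == labs[1L]][order(year_month[label == labs[1L]])]
    b <- value[label == labs[2L]][order(year_month[label == labs[2L]])]
    .(rmse = rmse(a, b))
  }, by = section]
  setorder(out, -rmse, section)[]
}

#' Welch t-tests comparing clusters section by section
#'
#' For each section of the given chapter, computes every practice's
#' items-per-patient over the window (window total items / mean monthly list
#' size; practices with no rows in the section count as 0) and compares the
#' two clusters with Welch's unequal-variance t-test. Raw p values are
#' reported alongside Benjamini-Hochberg adjusted ones.
#'
#' @inheritParams monthly_cluster_series
#' @param chapter BNF chapter whose sections are tested.
#' @param alpha significance level used for the `significant` flag (raw p).
#' @return data.table `section, mean_<label1>, mean_<label2>, t, p, p_adj,
#'   significant`, one row per testable section.
#' @export
section_ttests <- function(records, sizes, assignments, chapter = 4L,
                           alpha = 0.05) {
  records <- as_table(records,
                      c("practice_id", "year_month", "bnf_chapter",
                        "bnf_section", "items"),
                      "prescribing")
  sizes <- as_table(sizes,
                    c("practice_id", "year_month", "registered_patients"),
                    "sizes")
  assignments <- as_table(assignments, c("practice_id", "label"),
                          "assignments")
  labs <- sort(unique(assignments$label))
  if (length(labs) != 2L) stop_("t-tests require exactly two clusters")

  rec <- records[bnf_chapter == chapter]
  mean_size <- sizes[, .(patients = mean(registered_patients)),
                     by = practice_id]
  sections <- sort(unique(rec$bnf_section))
  base <- merge(assignments, mean_size, by = "practice_id")

  rows <- lapply(sections, function(s) {
    tot <- rec[bnf_section == s, .(items = sum(items)), by = practice_id]
    d <- merge(base, tot, by = "practice_id", all.x = TRUE)
    d[is.na(items), items := 0L]
    d[, value := items / patients]
    g1 <- d[label == labs[1L], value]
    g2 <- d[label == labs[2L], value]
    if (length(g1) < 2L || length(g2) < 2L) {
      warning(sprintf("section %s skipped: fewer than 2 practices per group", s),
              call. = FALSE)
      return(NULL)
    }
    tt <- tryCatch(t.test(g1, g2, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      warning(sprintf("section %s skipped: degenerate t-test", s),
              call. = FALSE)
      return(NULL)
    }
    data.table(section = s, mean_1 = mean(g1), mean_2 = mean(g2),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L) stop_("no testable section in chapter")
  setnames(out, c("mean_1", "mean_2"),
           paste0("mean_", gsub("[^A-Za-z0-9]+", "_", labs)))
  out[, p_adj := p.adjust(p, method = "BH")]
  out[, significant := p < alpha]
  out[]
}
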