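## Synthetic cohort generation.
##
## Two practice archetypes ("Metropolitan", "Non-Metropolitan") are defined
## by the six feature means/SDs of the published centroid table, a
## deprivation-quartile mix, a BNF chapter mix, and a pharmacy-dispersion
## target. The generator works at two levels:
##
##   * feature level -- draws the six features directly from truncated
##     per-archetype Gaussians (fast; isolates the clustering maths);
##   * record level  -- realises full monthly dispensing / prescribing /
##     list-size / coordinate / area tables whose extracted features
##     reproduce the sampled targets.
##
## Record-level geometry: each practice's pharmacies sit at uniform angles
## and log-normal radii. The radial scale is calibrated (Monte Carlo +
## bisection) so the mean pairwise pharmacy distance hits the archetype's
## dispersion target, and items are allocated to pharmacies with power-law
## distance-decay weights w ~ r^-beta, beta = log(scale)/sdlog^2. Tilting a
## log-normal by r^-beta shifts only its log-mean, so this choice makes the
## item-weighted distance distribution recover the practice's sampled median
## and SD targets while the unweighted pharmacy cloud keeps the calibrated
## dispersion -- the same mechanism (patients favour nearby pharmacies) that
## lets real practices show a short weighted median distance alongside a
## widely spread pharmacy set.

#' Construct an archetype specification
#'
#' @param label archetype name.
#' @param n_practices number of practices to generate.
#' @param feature_means,feature_sds length-6 numeric vectors in
#'   [feature_names()] order.
#' @param deprivation_mix 4 probabilities (Q1..Q4) summing to 1.
#' @param chapter_mix named numeric vector of per-chapter item shares
#'   (sums to 1).
#' @param chapter4_section_mix named numeric vector of section shares within
#'   chapter 4 (sums to 1).
#' @param dispersion_target_km target mean pairwise pharmacy distance.
#' @param missing_bnf_rate fraction of prescribing rows stripped of
#'   chapter/section information.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(label, n_practices, feature_means, feature_sds,
                           deprivation_mix, chapter_mix,
                           chapter4_section_mix, dispersion_target_km,
                           missing_bnf_rate = 0.0024) {
  stopifnot(n_practices >= 1, length(feature_means) == 6,
            length(feature_sds) == 6, all(feature_sds >= 0),
            length(deprivation_mix) == 4, all(deprivation_mix >= 0),
            dispersion_target_km > 0,
            missing_bnf_rate >= 0, missing_bnf_rate < 1)
  norm1 <- function(p) p / sum(p)
  names(feature_means) <- names(feature_sds) <- feature_names()
  structure(list(label = label, n_practices = as.integer(n_practices),
                 feature_means = feature_means, feature_sds = feature_sds,
                 deprivation_mix = norm1(deprivation_mix),
                 chapter_mix = norm1(chapter_mix),
                 chapter4_section_mix = norm1(chapter4_section_mix),
                 dispersion_target_km = dispersion_target_km,
                 missing_bnf_rate = missing_bnf_rate),
            class = "archetype_spec")
}

## Default BNF mixes. Chapter 4 carries 20% of Metropolitan items vs 16% of
## Non-Metropolitan; the excess sits in section 7 (60%) and section 3 (40%).
## Within chapter 4 the two archetypes share a base per-patient profile, with
## small opposing tilts so most sections are higher in Metropolitan practices
## but sections 6 and 9 are higher in Non-Metropolitan ones and section 10 is
## equal in absolute terms. Other chapters split the remaining share equally
## up to a fixed +-10% stylised wobble. These defaults are qualitative: they
## reproduce ordinal findings (which chapter/sections dominate), not real
## magnitudes.
default_bnf_mixes <- function() {
  chapters <- 1:13
  ipp <- c(met = 268.8, nm = 246)
  ch4_share <- c(met = 0.20, nm = 0.16)
  mix_for <- function(who, wobble) {
    other <- chapters[chapters != 4L]
    f <- 1 + 0.1 * wobble
    shares <- (1 - ch4_share[[who]]) * f / sum(f)
    out <- numeric(length(chapters))
    names(out) <- chapters
    out[as.character(other)] <- shares
    out["4"] <- ch4_share[[who]]
    out
  }
  met_chapters <- mix_for("met", sin(seq_along(chapters[-4L])))
  nm_chapters <- mix_for("nm", cos(seq_along(chapters[-4L])))

  ## chapter-4 sections, in items per patient per year
  nm_base <- c(`1` = 3.2, `2` = 1.2, `3` = 10.8, `4` = 0.7, `5` = 0.5,
               `6` = 2.2, `7` = 13.0, `8` = 2.6, `9` = 1.7, `10` = 0.9,
               `11` = 0.4)
  nm_abs <- nm_base / sum(nm_base) * ch4_share[["nm"]] * ipp[["nm"]]
  excess <- ch4_share[["met"]] * ipp[["met"]] - sum(nm_abs)
  tilt <- c(`1` = 0.25, `2` = 0.25, `3` = 0, `4` = 0.25, `5` = 0.25,
            `6` = -0.75, `7` = 0, `8` = 0.25, `9` = -0.75, `10` = 0,
            `11` = 0.25)   # sums to 0: totals stay pinned
  met_abs <- nm_abs + tilt
  met_abs[["7"]] <- met_abs[["7"]] + 0.6 * excess
  met_abs[["3"]] <- met_abs[["3"]] + 0.4 * excess
  list(met = list(chapters = met_chapters, sections = met_abs / sum(met_abs)),
       nm = list(chapters = nm_chapters, sections = nm_abs / sum(nm_abs)))
}

#' Default archetype pair
#'
#' The two archetypes parameterised by the published centroid table
#' (feature means and within-cluster SDs), the deprivation-quartile rows,
#' the dispersion figures (26.2 km / 40.4 km), and a 0.24% missing-BNF rate.
#'
#' @return List of two `archetype_spec` objects (Metropolitan first).
#' @export
default_archetypes <- function() {
  mixes <- default_bnf_mixes()
  list(
    archetype_spec(
      label = "Metropolitan", n_practices = 90,
      feature_means = c(212, 268.8, 4.6, 13.1, 5180, 5645),
      feature_sds = c(46.8, 5.8, 1.5, 3.4, 2578, 2724),
      deprivation_mix = c(23.3, 4.4, 20.0, 52.2) / 100,
      chapter_mix = mixes$met$chapters,
      chapter4_section_mix = mixes$met$sections,
      dispersion_target_km = 26.2),
    archetype_spec(
      label = "Non-Metropolitan", n_practices = 243,
      feature_means = c(98, 246, 14.8, 19.8, 1272, 6030),
      feature_sds = c(38.4, 3.4, 5.9, 5.9, 1230, 2859),
      deprivation_mix = c(25.9, 32.5, 27.8, 13.9) / 100,
      chapter_mix = mixes$nm$chapters,
      chapter4_section_mix = mixes$nm$sections,
      dispersion_target_km = 40.4)
  )
}

#' Draw a feature-level synthetic cohort
#'
#' Samples the six features for every practice independently from its
#' archetype's Gaussians, truncated to physical bounds: pharmacy counts are
#' integers `>= 1`, distances `>= 0.1` km, the distance SD `>= 5%` of the
#' median, density `>= 1`, list sizes `>= 100`.
#'
#' @param archetypes list of `archetype_spec` objects.
#' @param seed integer seed.
#' @return List with `features` (data.table `practice_id` + six features),
#'   `labels` (named character vector), `targets` (features + `label`).
#' @export
sample_feature_level <- function(archetypes = default_archetypes(),
                                 seed = 42L) {
  if (length(archetypes) < 1L) stop_("need at least one archetype")
  n_total <- sum(vapply(archetypes, `[[`, integer(1), "n_practices"))
  ids <- sprintf("P%04d", seq_len(n_total))
  rows <- with_local_seed(seed, {
    offset <- 0L
    lapply(archetypes, function(a) {
      n <- a$n_practices
      X <- vapply(feature_names(), function(f) {
        rnorm(n, a$feature_means[[f]], a$feature_sds[[f]])
      }, numeric(n))
      X <- matrix(X, nrow = n, dimnames = list(NULL, feature_names()))
      X[, "n_pharmacies"] <- pmax(1, round(X[, "n_pharmacies"]))
      X[, "items_per_patient"] <- pmax(1, X[, "items_per_patient"])
      X[, "median_distance_km"] <- pmax(0.1, X[, "median_distance_km"])
      X[, "sd_distance_km"] <- pmax(0.1, 0.05 * X[, "median_distance_km"],
                                    X[, "sd_distance_km"])
      X[, "population_density"] <- pmax(1, X[, "population_density"])
      X[, "registered_patients"] <- pmax(100, X[, "registered_patients"])
      dt <- as.data.table(X)
      dt[, practice_id := ids[offset + seq_len(n)]]
      dt[, label := a$label]
      offset <<- offset + n
      dt
    })
  })
  targets <- rbindlist(rows)
  setcolorder(targets, c("practice_id", "label", feature_names()))
  labels <- targets$label
  names(labels) <- targets$practice_id
  list(features = targets[, c("practice_id", feature_names()), with = FALSE],
       labels = labels,
       targets = targets)
}

#' Calibrate the radial scale for a pharmacy-dispersion target
#'
#' Finds the scale `s` such that pharmacies placed at angles uniform on
#' `[0, 2*pi)` and radii drawn from the given log-normal family scaled by
#' `s` have Monte-Carlo mean pairwise distance within 2% of the target.
#' The family may be a mixture over practices (`meanlog`/`sdlog` vectors);
#' pairs are always drawn within one mixture component. Solved by bisection.
#'
#' @param dispersion_target_km target mean pairwise distance (> 0).
#' @param radial_family list with numeric `meanlog` and `sdlog` vectors of
#'   equal length (log-normal radii, in km; `sdlog = 0` gives fixed radii).
#' @param mc_reps Monte-Carlo pair draws.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return The calibrated scale (a positive number).
#' @export
calibrate_radial_scale <- function(dispersion_target_km, radial_family,
                                   mc_reps = 20000L, seed = 1L) {
  if (dispersion_target_km <= 0) stop_("dispersion target must be positive")
  ml <- radial_family$meanlog; sl <- radial_family$sdlog
  if (length(ml) != length(sl) || length(ml) == 0L) {
    stop_("radial_family needs meanlog/sdlog vectors of equal length")
  }
  d1 <- with_local_seed(seed, {
    idx <- sample.int(length(ml), mc_reps, replace = TRUE)
    r1 <- rlnorm(mc_reps, ml[idx], sl[idx])
    r2 <- rlnorm(mc_reps, ml[idx], sl[idx])
    phi <- runif(mc_reps, 0, 2 * pi)
    sqrt(pmax(r1^2 + r2^2 - 2 * r1 * r2 * cos(phi), 0))
  })
  est1 <- mean(d1)   # mean pairwise distance at scale 1; scales linearly
  f <- function(s) s * est1 - dispersion_target_km
  lo <- dispersion_target_km / est1 / 16
  hi <- dispersion_target_km / est1 * 16
  if (!(f(lo) < 0 && f(hi) > 0)) {
    stop_("search interval does not bracket the dispersion target")
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) / dispersion_target_km < 0.001) break
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  mid
}

## continuous weighted quantile (lower weighted median) of radii
weighted_q50 <- function(x, w) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= 0.5)[1L]]
}

#' Generate a full record-level synthetic cohort
#'
#' Realises the five analysis input tables (dispensing, prescribing, monthly
#' list sizes, coordinates, area attributes) plus ground truth for a cohort
#' drawn from the given archetypes. See the package vignette for the
#' generative model; headline properties: extracted pharmacy counts equal
#' the sampled targets exactly, item-weighted median distances and annual
#' items-per-patient recover their targets, mean pairwise pharmacy distance
#' matches the archetype dispersion targets, and a `missing_bnf_rate`
#' fraction of prescribing rows lack chapter/section codes.
#'
#' @param archetypes list of `archetype_spec` objects.
#' @param months number of months to generate (`>= 12`).
#' @param seed master seed; all stages draw from sub-streams of it.
#' @param start_month first month (`"YYYY-MM"`).
#' @param mc_reps Monte-Carlo draws for dispersion calibration.
#' @return An object of class `synthetic_cohort`: list with the five input
#'   tables, `truth` (labels, drawn quartiles, per-practice targets),
#'   `window` (the generated months), and `seed`.
#' @export
generate_records <- function(archetypes = default_archetypes(), months = 12L,
                             seed = 42L, start_month = "2018-04",
                             mc_reps = 20000L) {
  if (months < 12L) stop_("months must be >= 12")
  window <- ym_seq(start_month, months)
  feat <- sample_feature_level(archetypes, derive_seed(seed, 1L))
  targets <- copy(feat$targets)

  ## log-normal radial parameters per practice, from its distance targets
  targets[, `:=`(meanlog = log(median_distance_km),
                 sdlog = {
                   ratio2 <- (sd_distance_km / median_distance_km)^2
                   sqrt(log((1 + sqrt(1 + 4 * ratio2)) / 2))
                 })]

  ## per-archetype radial scale hitting the dispersion target
  arch_labels <- vapply(archetypes, `[[`, character(1), "label")
  scales <- vapply(seq_along(archetypes), function(i) {
    a <- archetypes[[i]]
    fam <- targets[label == a$label]
    calibrate_radial_scale(a$dispersion_target_km,
                           list(meanlog = fam$meanlog, sdlog = fam$sdlog),
                           mc_reps = mc_reps,
                           seed = derive_seed(seed, 100L + i))
  }, numeric(1))
  names(scales) <- arch_labels
  targets[, radial_scale := scales[label]]

  arch_by_label <- archetypes
  names(arch_by_label) <- arch_labels

  gen <- with_local_seed(derive_seed(seed, 2L), {
    n_prac <- nrow(targets)
    grid_cols <- ceiling(sqrt(n_prac))
    disp_l <- presc_l <- size_l <- coord_l <- vector("list", n_prac)
    for (i in seq_len(n_prac)) {
      tg <- targets[i]
      a <- arch_by_label[[tg$label]]
      P <- as.integer(tg$n_pharmacies)
      s <- tg$radial_scale

      ## pharmacy geometry
      radii <- pmin(s * rlnorm(P, tg$meanlog, tg$sdlog), 5000)
      beta <- log(s) / tg$sdlog^2
      w <- radii^(-beta)
      w <- 0.98 * w / sum(w) + 0.02 / P   # floor keeps every pharmacy active
      radii <- radii * tg$median_distance_km / weighted_q50(radii, w)
      theta <- runif(P, 0, 2 * pi)
      cx <- 1e7 + ((i - 1L) %% grid_cols) * 1e6
      cy <- 1e7 + ((i - 1L) %/% grid_cols) * 1e6
      ph_ids <- sprintf("%s_PH%04d", tg$practice_id, seq_len(P))
      coord_l[[i]] <- data.table(
        location_code = c(tg$practice_id, ph_ids),
        easting_m = c(cx, cx + radii * 1000 * cos(theta)),
        northing_m = c(cy, cy + radii * 1000 * sin(theta)))

      ## list sizes: quarterly figures forward-filled over their 3 months
      nq <- ceiling(months / 3)
      q_vals <- round(tg$registered_patients * (1 + rnorm(nq, 0, 0.003)))
      p_t <- rep(q_vals, each = 3L)[seq_len(months)]
      size_l[[i]] <- data.table(practice_id = tg$practice_id,
                                year_month = window,
                                registered_patients = as.integer(p_t))

      ## monthly item totals: Poisson around the annualised target rate
      lambda <- tg$items_per_patient * mean(p_t) / 12
      m_t <- rpois(months, lambda * runif(months, 0.95, 1.05))

      ## dispensing: multinomial allocation with the distance-decay weights
      counts <- vapply(m_t, function(m) {
        as.vector(rmultinom(1L, m, w))
      }, integer(P))
      disp <- data.table(practice_id = tg$practice_id,
                         pharmacy_id = rep(ph_ids, times = months),
                         year_month = rep(window, each = P),
                         items = as.vector(counts))
      disp_l[[i]] <- disp[items > 0L]

      ## prescribing: chapter split, chapter 4 further split into sections
      ch_names <- as.integer(names(a$chapter_mix))
      ch_counts <- vapply(m_t, function(m) {
        as.vector(rmultinom(1L, m, a$chapter_mix))
      }, integer(length(ch_names)))
      sec_names <- as.integer(names(a$chapter4_section_mix))
      ch4_row <- which(ch_names == 4L)
      sec_counts <- vapply(ch_counts[ch4_row, ], function(m) {
        as.vector(rmultinom(1L, m, a$chapter4_section_mix))
      }, integer(length(sec_names)))
      non4 <- data.table(
        practice_id = tg$practice_id,
        year_month = rep(window, each = length(ch_names) - 1L),
        bnf_chapter = rep(ch_names[-ch4_row], times = months),
        bnf_section = 1L,
        items = as.vector(ch_counts[-ch4_row, ]))
      ch4 <- data.table(
        practice_id = tg$practice_id,
        year_month = rep(window, each = length(sec_names)),
        bnf_chapter = 4L,
        bnf_section = rep(sec_names, times = months),
        items = as.vector(sec_counts))
      presc_l[[i]] <- rbind(non4, ch4)[items > 0L]
    }

    prescribing <- rbindlist(presc_l)
    ## strip BNF codes from a small fraction of rows (missing-data path)
    rate <- vapply(arch_by_label, `[[`, numeric(1), "missing_bnf_rate")
    prescribing[, label := feat$labels[practice_id]]
    strip <- runif(nrow(prescribing)) < rate[prescribing$label]
    prescribing[strip, `:=`(bnf_chapter = NA_integer_,
                            bnf_section = NA_integer_)]
    prescribing[, label := NULL]

    ## deprivation: quartile drawn per practice, ranks consistent with it
    quart <- unlist(lapply(archetypes, function(a) {
      sample.int(4L, a$n_practices, replace = TRUE, prob = a$deprivation_mix)
    }))
    ## rank 1 = most deprived: Q4 practices get the lowest ranks
    ord <- order(-quart, runif(length(quart)))
    rank_vec <- integer(length(quart))
    rank_vec[ord] <- seq_along(quart)

    list(dispensing = rbindlist(disp_l),
         prescribing = prescribing,
         sizes = rbindlist(size_l),
         coordinates = rbindlist(coord_l),
         quartile = quart,
         rank_vec = rank_vec)
  })

  areas <- data.table(location_code = targets$practice_id,
                      population_density_km2 = targets$population_density,
                      deprivation_rank = gen$rank_vec)
  truth <- copy(targets)
  truth[, quartile := paste0("Q", gen$quartile)]

  structure(list(dispensing = gen$dispensing,
                 prescribing = gen$prescribing,
                 sizes = gen$sizes,
                 coordinates = gen$coordinates,
                 areas = areas,
                 truth = truth,
                 window = window,
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d practices, %d months (%s..%s), seed %d\n",
    nrow(x$truth), length(x$window), x$window[1L],
    x$window[length(x$window)], x$seed))
  cat(sprintf("  dispensing %d rows, prescribing %d rows\n",
              nrow(x$dispensing), nrow(x$prescribing)))
  invisible(x)
}

#' Write a synthetic cohort's tables as CSV files
#'
#' Writes the five analysis inputs plus `truth.csv` into a directory.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("dispensing", "prescribing", "sizes", "coordinates", "areas",
              "truth")
  for (tb in tables) {
    fwrite(cohort[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  invisible(dir)
}
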