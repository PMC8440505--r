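test_that("unique_pharmacy_count counts distinct pharmacies", {
  rec <- data.table(practice_id = "P1",
                    pharmacy_id = c("A", "A", "B"),
                    year_month = c("2018-01", "2018-02", "2018-01"))
  expect_equal(unique_pharmacy_count(rec), 2)

  one <- data.table(practice_id = "P1", pharmacy_id = "A",
                    year_month = sprintf("2018-%02d", 1:12))
  expect_equal(unique_pharmacy_count(one), 1)

  set.seed(3)
  many <- data.table(practice_id = "P1",
                     pharmacy_id = sample(paste0("PH", 1:7), 50, TRUE),
                     year_month = "2018-01")
  expect_equal(unique_pharmacy_count(many), length(unique(many$pharmacy_id)))

  expect_warning(n0 <- unique_pharmacy_count(many[0]), "0")
  expect_equal(n0, 0)
  expect_error(unique_pharmacy_count(
    data.table(practice_id = c("P1", "P2"), pharmacy_id = "A")),
    "more than one practice")
})

test_that("annual_items_per_patient divides window items by mean list size", {
  months <- sprintf("2018-%02d", 1:12)
  rec <- data.table(practice_id = "P1", items = rep(500L, 12))
  sz <- data.table(practice_id = "P1", year_month = months,
                   registered_patients = 1000L)
  expect_equal(annual_items_per_patient(rec, sz), 6)
  expect_equal(annual_items_per_patient(rec[items < 0], sz), 0)

  set.seed(5)
  rec2 <- data.table(practice_id = "P1", items = rpois(12, 800))
  sz2 <- data.table(practice_id = "P1", year_month = months,
                    registered_patients = sample(900:1100, 12))
  expect_equal(annual_items_per_patient(rec2, sz2),
               sum(rec2$items) / mean(sz2$registered_patients))
  expect_error(annual_items_per_patient(rec2, sz2[0]), "no registered")
})

test_that("weighted median and SD equal their multiset-expansion oracles", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 2)), 2.5)  # {1,2,3,3}
  expect_equal(weighted_median(7.5, 40), 7.5)
  expect_equal(weighted_sd(c(0, 10), c(1, 1)), 5)
  expect_equal(weighted_sd(c(4, 4, 4), c(2, 5, 1)), 0)
  expect_equal(weighted_sd(c(0, 10), c(2, 2)),
               weighted_sd(c(0, 0, 10, 10), rep(1, 4)))

  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    v <- round(rnorm(n, 0, 50), 2)
    w <- sample(1:9, n, replace = TRUE)
    exp_v <- expand_multiset(v, w)
    expect_equal(weighted_median(v, w), median(exp_v))
    if (sum(w) >= 2) {
      pop_sd <- sqrt(mean((exp_v - mean(exp_v))^2))
      expect_equal(weighted_sd(v, w), pop_sd)
    }
  }
  expect_error(weighted_median(numeric(0), integer(0)), "empty")
  expect_error(weighted_sd(1, 1), "weight")
  expect_error(weighted_median(c(1, 2), c(0.5, 1)), "integer")
})

test_that("distance_profile weights distances by items", {
  lookup <- load_coordinate_lookup(data.frame(
    location_code = c("N", "F"),
    easting_m = c(2000, 10000), northing_m = c(0, 0)))
  practice <- list(easting = 0, northing = 0)

  one <- data.table(pharmacy_id = "N", items = 37L)
  lk1 <- load_coordinate_lookup(data.frame(location_code = "N",
                                           easting_m = 3000,
                                           northing_m = 4000))
  expect_equal(unname(distance_profile(one, practice, lk1)), c(5, 0))

  two <- data.table(pharmacy_id = c("N", "F"), items = c(10L, 10L))
  prof <- distance_profile(two, practice, lookup)
  expect_equal(unname(prof), c(6, 4))   # expanded multiset {2 x10, 10 x10}

  ## integer scaling of items leaves the profile unchanged
  scaled <- data.table(pharmacy_id = c("N", "F"), items = c(30L, 30L))
  expect_equal(distance_profile(scaled, practice, lookup), prof)

  ## unit weights reduce to the plain median/SD
  expect_equal(unname(distance_profile(
    data.table(pharmacy_id = c("N", "F"), items = c(1L, 1L)),
    practice, lookup)), c(6, 4))

  expect_error(distance_profile(
    data.table(pharmacy_id = "X", items = 1L), practice, lookup), "X")
  expect_error(distance_profile(
    data.table(pharmacy_id = "N", items = 0L), practice, lookup), "zero")
})

test_that("pharmacy_dispersion is the mean over unordered pairs", {
  pts <- list(easting = c(0, 3000, 6000), northing = c(0, 4000, 8000))
  expect_equal(pharmacy_dispersion(pts), mean(c(5, 5, 10)))
  expect_equal(pharmacy_dispersion(list(easting = c(0, 7000),
                                        northing = c(0, 0))), 7)
  expect_equal(pharmacy_dispersion(list(easting = rep(5, 4),
                                        northing = rep(9, 4))), 0)
  expect_true(is.na(pharmacy_dispersion(list(easting = 1, northing = 1))))

  ## invariance under translation and rotation
  set.seed(9)
  xy <- matrix(runif(16, 0, 1e5), ncol = 2)
  base <- pharmacy_dispersion(list(easting = xy[, 1], northing = xy[, 2]))
  th <- 0.83
  rot <- xy %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(pharmacy_dispersion(list(easting = rot[, 1] + 5e4,
                                        northing = rot[, 2] + 2e4)), base)
})

test_that("cluster_dispersion_summary computes per-cluster mean and sample SD", {
  labels <- data.table(practice_id = paste0("P", 1:5),
                       label = c("A", "A", "A", "B", "B"))
  disp <- data.table(practice_id = paste0("P", 1:5),
                     dispersion_km = c(10, 20, NA, 7, 7))
  out <- cluster_dispersion_summary(labels, disp)
  expect_equal(out[label == "A", mean_km], 15)
  expect_equal(out[label == "A", sd_km], sd(c(10, 20)))
  expect_equal(out[label == "A", n_missing], 1)
  expect_equal(out[label == "B", c(mean_km, sd_km)], c(7, 0))

  single <- cluster_dispersion_summary(
    data.table(practice_id = "P1", label = "A"),
    data.table(practice_id = "P1", dispersion_km = 4))
  expect_equal(single$mean_km, 4)
  expect_true(is.na(single$sd_km))

  expect_error(cluster_dispersion_summary(
    labels, data.table(practice_id = paste0("P", 1:5),
                       dispersion_km = c(1, 1, 1, NA, NA))),
    "no valid dispersion")
})

test_that("build_practice_profiles applies the 12-month presence filter", {
  months <- ym_seq("2018-04", 12)
  lookup <- load_coordinate_lookup(data.frame(
    location_code = c("P1", "P2", "PH1", "PH2"),
    easting_m = c(0, 0, 3000, 6000), northing_m = c(0, 0, 4000, 8000)))
  areas <- data.frame(location_code = c("P1", "P2"),
                      population_density_km2 = c(100, 200),
                      deprivation_rank = 1:2)
  disp <- rbind(
    data.table(practice_id = "P1", pharmacy_id = "PH1",
               year_month = months, items = 10L),
    data.table(practice_id = "P1", pharmacy_id = "PH2",
               year_month = months, items = 10L),
    data.table(practice_id = "P2", pharmacy_id = "PH1",
               year_month = months[1:11], items = 5L))  # present 11 months
  sizes <- CJ(practice_id = c("P1", "P2"), year_month = months)
  sizes[, registered_patients := 1000L]

  expect_message(
    prof <- build_practice_profiles(disp, sizes, lookup, areas, months),
    "retained 1")
  expect_equal(prof$practice_id, "P1")
  expect_equal(prof$n_pharmacies, 2)
  expect_equal(prof$items_per_patient, 240 / 1000)
  expect_equal(prof$median_distance_km, 7.5)  # equal weight at 5 and 10 km
  expect_equal(prof$sd_distance_km, 2.5)
  expect_equal(prof$population_density, 100)
  expect_equal(prof$registered_patients, 1000)

  ## identical practices get identical profiles
  disp2 <- rbind(disp[practice_id == "P1"],
                 copy(disp[practice_id == "P1"])[, practice_id := "P2"][
                   , pharmacy_id := pharmacy_id])
  lookup2 <- load_coordinate_lookup(data.frame(
    location_code = c("P1", "P2", "PH1", "PH2"),
    easting_m = c(0, 0, 3000, 6000), northing_m = c(0, 0, 4000, 8000)))
  expect_message(prof2 <- build_practice_profiles(disp2, sizes, lookup2,
                                                  areas, months))
  cols <- setdiff(names(prof2), c("practice_id", "population_density"))
  expect_equal(as.list(prof2[1, ..cols]), as.list(prof2[2, ..cols]))
})
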