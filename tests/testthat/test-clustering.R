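make_profile_table <- function(X) {
  dt <- as.data.table(matrix(X, ncol = 6,
                             dimnames = list(NULL, feature_names())))
  dt[, practice_id := sprintf("P%02d", .I)]
  dt
}

test_that("standardise z-scores exactly and inverts exactly", {
  set.seed(21)
  X <- matrix(rnorm(60, mean = rep(c(10, 100, 5, 3, 1000, 5000), each = 10),
                    sd = rep(c(2, 30, 1, 1, 300, 900), each = 10)),
              ncol = 6)
  std <- standardise(make_profile_table(X))
  expect_lt(max(abs(colMeans(std$X))), 1e-9)
  expect_lt(max(abs(apply(std$X, 2, sd) - 1)), 1e-9)
  back <- de_standardise(std$X, std$params)
  expect_lt(max(abs(back - X)), 1e-9)

  ## two-point closed form: z = +/- 1/sqrt(2) under the sample-SD convention
  two <- make_profile_table(matrix(rep(c(1, 3), 6), ncol = 6))
  z <- standardise(two)$X
  expect_equal(abs(as.vector(z)), rep(1 / sqrt(2), 12))

  const <- make_profile_table(cbind(X[, 1:5], 7))
  expect_error(standardise(const), "registered_patients")
})

test_that("fit_kmeans solves small instances exactly", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- fit_kmeans(X, 2, seed = 1, n_init = 20)
  expect_equal(fit$inertia, 1)
  expect_equal(sort(as.vector(fit$centroids_standardised)), c(0.5, 10.5))
  expect_equal(fit$assignments[1], fit$assignments[2],
               ignore_attr = TRUE)
  expect_false(fit$assignments[1] == fit$assignments[3])

  ## k = 1: centroid = column means, inertia = total SS
  set.seed(2)
  Y <- matrix(rnorm(40), ncol = 2)
  f1 <- fit_kmeans(Y, 1, seed = 1, n_init = 5)
  expect_equal(as.vector(f1$centroids_standardised), colMeans(Y))
  expect_equal(f1$inertia, sum(sweep(Y, 2, colMeans(Y))^2))

  ## k = n: zero inertia
  fn <- fit_kmeans(Y[1:5, ], 5, seed = 1, n_init = 20)
  expect_equal(fn$inertia, 0, tolerance = 1e-12)

  expect_error(fit_kmeans(Y, 100, seed = 1), "between")
})

test_that("fit_kmeans matches the brute-force optimal 2-partition", {
  set.seed(31)
  for (trial in 1:30) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 2), ncol = 2)
    oracle <- brute_force_kmeans2(X)
    fit <- fit_kmeans(X, 2, seed = trial, n_init = 50)
    expect_equal(fit$inertia, oracle$inertia, tolerance = 1e-8)
  }
})

test_that("inertia curve is monotone and the elbow finds 3 blobs", {
  blobs <- make_blobs()
  inertias <- inertia_curve(blobs$X, 1:6, seed = 5, n_init = 20)
  expect_true(all(diff(inertias) <= 1e-8))
  expect_equal(select_k_elbow(inertias), 3)

  one <- inertia_curve(blobs$X, 1, seed = 5, n_init = 5)
  expect_length(one, 1)

  ## perfectly linear curve: every curvature ties at 0 -> smallest interior k
  lin <- setNames(seq(100, 40, by = -10), 1:7)
  expect_equal(select_k_elbow(lin), 2)
  expect_error(select_k_elbow(lin[1:3]), "at least 4")
  expect_error(select_k_elbow(lin[2:7]), "consecutive")
})

test_that("silhouette selection recovers well-separated structure", {
  blobs <- make_blobs(n_per = 4, gap = 50)
  expect_equal(select_k_silhouette(blobs$X, 2:5, seed = 3, n_init = 20), 3)
  expect_equal(select_k_silhouette(blobs$X, 2, seed = 3), 2)
  expect_error(select_k_silhouette(blobs$X, 1:3, seed = 3), "k_range")
})

test_that("pca_project matches an eigendecomposition oracle", {
  set.seed(17)
  X <- scale(matrix(rnorm(300), ncol = 6))

  p <- pca_project(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$explained, (ev / sum(ev))[1:2], tolerance = 1e-10)
  expect_equal(sum(p$loadings[, 1] * p$loadings[, 2]), 0, tolerance = 1e-10)
  expect_true(all(diff(p$explained) <= 0))
  ## sign convention: the dominant loading of each component is positive
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }

  ## rank-1 data: second component carries ~zero variance
  line <- outer(seq(-2, 2, length.out = 10), c(1, 2, 3, -1, 0.5, 2))
  pl <- pca_project(line)
  expect_lt(pl$explained[2], 1e-12)

  ## intrinsically 2-D data: projection preserves pairwise distances
  B <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  Z <- matrix(rnorm(40), ncol = 2)
  flat <- Z %*% t(B)
  pf <- pca_project(flat)
  expect_equal(as.vector(dist(pf$scores)), as.vector(dist(flat)),
               tolerance = 1e-8)

  expect_error(pca_project(X[1:2, ]), "3 rows")
})

test_that("label_clusters follows the population-density rule", {
  X <- matrix(rnorm(40 * 6), ncol = 6,
              dimnames = list(NULL, feature_names()))
  X[1:20, "population_density"] <- X[1:20, "population_density"] + 50
  X[1:20, "n_pharmacies"] <- X[1:20, "n_pharmacies"] + 20
  rownames(X) <- sprintf("P%02d", 1:40)
  std <- standardise(X)
  fit <- fit_kmeans(std$X, 2, seed = 4, n_init = 30)
  lab <- label_clusters(fit, std$params)
  C <- de_standardise(lab$centroids_standardised, std$params)
  expect_equal(lab$labels[which.max(C[, "population_density"])],
               "Metropolitan")
  expect_setequal(lab$labels, c("Metropolitan", "Non-Metropolitan"))

  ## labels follow density, not cluster index: flip the data order
  std2 <- standardise(X[40:1, ])
  fit2 <- label_clusters(fit_kmeans(std2$X, 2, seed = 4, n_init = 30),
                         std2$params)
  a1 <- assignment_table(lab)
  a2 <- assignment_table(fit2)
  m <- merge(a1, a2, by = "practice_id")
  expect_equal(m$label.x, m$label.y)

  expect_error(label_clusters(fit_kmeans(std$X, 3, seed = 1, n_init = 5),
                              std$params), "k = 2")
})

test_that("density ties break toward the larger pharmacy centroid", {
  model <- structure(list(
    k = 2L,
    assignments = setNames(c(1L, 2L), c("P1", "P2")),
    centroids_standardised = matrix(
      c(212, 98, 0, 0, 0, 0, 0, 0, 100, 100, 0, 0), nrow = 2,
      dimnames = list(NULL, feature_names())),
    inertia = 0, seed = 1L, labels = NULL), class = "cluster_model")
  params <- list(mean = setNames(rep(0, 6), feature_names()),
                 sd = setNames(rep(1, 6), feature_names()))
  lab <- label_clusters(model, params)
  expect_equal(lab$labels, c("Metropolitan", "Non-Metropolitan"))
})

test_that("centroid_summary de-standardises and reports within-cluster SDs", {
  vals <- matrix(c(1, 3, 11, 13), ncol = 1)[, rep(1, 6)]
  colnames(vals) <- feature_names()
  prof <- make_profile_table(vals)
  std <- standardise(prof)
  fit <- fit_kmeans(std$X, 2, seed = 1, n_init = 20)
  fit$labels <- c("lo", "hi")[order(order(fit$centroids_standardised[, 1]))]
  out <- centroid_summary(fit, std$params, prof)
  expect_equal(out[label == "lo" & feature == "n_pharmacies", centroid], 2)
  expect_equal(out[label == "hi" & feature == "n_pharmacies", centroid], 12)
  expect_equal(out[label == "lo" & feature == "n_pharmacies", sd],
               sd(c(1, 3)))

  ## k = n: centroids round-trip to the original rows, SDs undefined
  fitn <- fit_kmeans(std$X, 4, seed = 1, n_init = 30)
  fitn$labels <- paste0("c", 1:4)
  outn <- centroid_summary(fitn, std$params, prof)
  expect_true(all(is.na(outn$sd)))
  expect_equal(sort(outn[feature == "n_pharmacies", centroid]),
               c(1, 3, 11, 13))
})

test_that("clustering is invariant to row permutation of the features", {
  feat <- sample_feature_level(seed = 7)
  std <- standardise(feat$features)
  fit <- label_clusters(fit_kmeans(std$X, 2, seed = 2, n_init = 30),
                        std$params)
  perm <- sample(nrow(feat$features))
  stdp <- standardise(feat$features[perm])
  fitp <- label_clusters(fit_kmeans(stdp$X, 2, seed = 2, n_init = 30),
                         stdp$params)
  m <- merge(assignment_table(fit), assignment_table(fitp),
             by = "practice_id")
  expect_equal(m$label.x, m$label.y)
})

test_that("feature-level synthetic clustering recovers archetypes (ARI >= 0.9)", {
  feat <- sample_feature_level(seed = 1)
  std <- standardise(feat$features)
  fit <- fit_kmeans(std$X, 2, seed = 1, n_init = 50)
  ari <- adjusted_rand_index(fit$assignments[feat$features$practice_id],
                             feat$labels)
  expect_gte(ari, 0.9)
})

test_that("2-D PCA beats random 2-D projections on explained variance", {
  feat <- sample_feature_level(seed = 3)
  X <- standardise(feat$features)$X
  p <- pca_project(X)
  total <- sum(apply(X, 2, var))
  pca_var <- sum(p$explained) * total
  set.seed(8)
  for (i in 1:20) {
    B <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
    proj_var <- sum(apply(X %*% B, 2, var))
    expect_lte(proj_var, pca_var + 1e-8)
  }
})
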