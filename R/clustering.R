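## Standardisation, k-means with k-means++ restarts, k selection (elbow +
## silhouette), 2-D PCA projection, and cluster labelling.
##
## k-means is run on z-scored features (sample SD) because the six features
## live on wildly different scales (counts vs km vs persons/km^2). Lloyd
## iterations are implemented directly so the convergence tolerance and the
## empty-cluster policy are explicit and the solver can be checked against a
## brute-force optimal-partition oracle on small instances.

#' Z-score a feature table
#'
#' Centres and scales each feature column to mean 0 and sample SD 1, and
#' returns the parameters needed to invert the transform exactly.
#'
#' @param profiles data.frame with a `practice_id` column and the six
#'   [feature_names()] columns, or a plain numeric matrix.
#' @return List with `X` (standardised matrix, rownames = practice IDs),
#'   `params` (list of `mean` and `sd` named vectors).
#' @export
standardise <- function(profiles) {
  if (is.matrix(profiles)) {
    X <- profiles
  } else {
    profiles <- as_table(profiles, c("practice_id", feature_names()),
                         "profiles")
    X <- as.matrix(profiles[, feature_names(), with = FALSE])
    rownames(X) <- profiles$practice_id
  }
  if (nrow(X) < 2L) stop_("need at least 2 rows to standardise")
  mu <- colMeans(X)
  sigma <- apply(X, 2L, sd)
  if (any(sigma == 0)) {
    stop_(sprintf("constant feature column(s): %s",
                  paste(colnames(X)[sigma == 0], collapse = ", ")))
  }
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sigma, "/")
  list(X = Z, params = list(mean = mu, sd = sigma))
}

#' Invert a standardisation
#'
#' @param X standardised matrix (e.g. centroids).
#' @param params the `params` element returned by [standardise()].
#' @return Matrix in the original units.
#' @export
de_standardise <- function(X, params) {
  sweep(sweep(X, 2L, params$sd, "*"), 2L, params$mean, "+")
}

## squared Euclidean distance from every row of X to every row of C
dist2_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  pmax(d2, 0)
}

## k-means++ seeding: first centre uniform, later centres with probability
## proportional to squared distance from the nearest chosen centre.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
    for (j in 2:k) {
      if (sum(d2) == 0) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
    }
  }
  centers
}

lloyd <- function(X, centers, max_iter = 300L, tol = 1e-6) {
  k <- nrow(centers)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        ## empty cluster: reseed at the point farthest from its centre
        far <- which.max(d2[cbind(seq_len(nrow(X)), assign)])
        new_centers[j, ] <- X[far, ]
      } else {
        new_centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    moved <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (moved < tol) break
  }
  d2 <- dist2_to_centers(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), assign)])
  list(centers = centers, assign = assign, inertia = inertia)
}

#' Fit k-means with k-means++ restarts
#'
#' Runs Lloyd's algorithm from `n_init` k-means++ seedings and keeps the
#' lowest-inertia solution. Deterministic given `(X, k, seed, n_init)`.
#'
#' @param X standardised numeric matrix (rows = practices).
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param seed integer seed governing all restarts.
#' @param n_init number of restarts (default 50).
#' @param max_iter,tol Lloyd iteration cap and centroid-movement tolerance.
#' @return An object of class `cluster_model`: list with `k`, `assignments`
#'   (named integer vector), `centroids_standardised` (`k x p`), `inertia`,
#'   `seed`, and `labels` (NULL until [label_clusters()]).
#' @export
fit_kmeans <- function(X, k, seed = 1L, n_init = 50L, max_iter = 300L,
                       tol = 1e-6) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (k < 1L || k > nrow(X)) stop_("k must be between 1 and nrow(X)")
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd(X, kmeanspp_init(X, k), max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  ## stable cluster numbering: order clusters by first member row
  first_row <- vapply(seq_len(k), function(j) {
    m <- which(best$assign == j)
    if (length(m)) min(m) else Inf
  }, numeric(1))
  relabel <- order(order(first_row))
  assignments <- relabel[best$assign]
  centroids <- best$centers[order(first_row), , drop = FALSE]
  names(assignments) <- rownames(X)
  colnames(centroids) <- colnames(X)
  structure(list(k = as.integer(k), assignments = assignments,
                 centroids_standardised = centroids, inertia = best$inertia,
                 seed = as.integer(seed), labels = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means model: k = %d, n = %d, inertia = %.4f\n",
              x$k, length(x$assignments), x$inertia))
  if (!is.null(x$labels)) {
    cat("labels:", paste(sprintf("%d=%s", seq_along(x$labels), x$labels),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Within-cluster sum of squares across a range of k
#'
#' Fits k-means for each k and returns the inertia curve used by the elbow
#' method. The curve must be non-increasing; if a restart artefact produces
#' an increase, the whole curve is refitted once with 5x the restarts.
#'
#' @inheritParams fit_kmeans
#' @param k_range integer vector of k values (subset of `1:nrow(X)`).
#' @return Named numeric vector of inertias, names = k.
#' @export
inertia_curve <- function(X, k_range = 1:10, seed = 1L, n_init = 50L) {
  fit_all <- function(ni) {
    vapply(k_range, function(k) {
      fit_kmeans(X, k, seed = derive_seed(seed, k), n_init = ni)$inertia
    }, numeric(1))
  }
  inertias <- fit_all(n_init)
  if (is.unsorted(rev(inertias))) {
    inertias <- fit_all(n_init * 5L)
    if (is.unsorted(rev(inertias))) {
      stop_("inertia curve not monotone even after extra restarts")
    }
  }
  names(inertias) <- k_range
  inertias
}

#' Select k by the elbow rule
#'
#' Operationalises the visual elbow as the interior k maximising the
#' second-order difference `inertia(k-1) - 2 inertia(k) + inertia(k+1)`,
#' ties broken toward smaller k. Requires inertias at consecutive k starting
#' at 1, at least four of them.
#'
#' @param inertias named numeric vector from [inertia_curve()].
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(inertias) {
  ks <- as.integer(names(inertias))
  if (length(ks) < 4L || ks[1L] != 1L || !all(diff(ks) == 1L)) {
    stop_("need inertias at consecutive k = 1,2,... (at least 4 values)")
  }
  interior <- 2:(length(ks) - 1L)
  curvature <- inertias[interior - 1L] - 2 * inertias[interior] +
    inertias[interior + 1L]
  ks[interior][which.max(curvature)]   # which.max takes the first maximum
}

#' Select k by the mean silhouette coefficient
#'
#' @inheritParams fit_kmeans
#' @param k_range candidate k values, each in `[2, nrow(X) - 1]`.
#' @return The k with the highest mean silhouette width (Euclidean), ties
#'   toward smaller k.
#' @export
select_k_silhouette <- function(X, k_range = 2:10, seed = 1L, n_init = 50L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (any(k_range < 2L) || any(k_range > nrow(X) - 1L)) {
    stop_("silhouette k_range must lie in [2, nrow(X) - 1]")
  }
  if (length(k_range) == 1L) return(as.integer(k_range))
  D <- dist(X)
  widths <- vapply(k_range, function(k) {
    fit <- fit_kmeans(X, k, seed = derive_seed(seed, k), n_init = n_init)
    mean(cluster::silhouette(fit$assignments, D)[, "sil_width"])
  }, numeric(1))
  as.integer(k_range[which.max(widths)])
}

#' Two-dimensional PCA projection for visualisation
#'
#' Projects (already standardised) features onto their first two principal
#' components. Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making plots reproducible across
#' platforms.
#'
#' @param X standardised matrix with at least 3 rows.
#' @return List with `scores` (`n x 2`), `loadings` (`p x 2`), and
#'   `explained` (two variance fractions, non-increasing).
#' @export
pca_project <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 3L) stop_("PCA projection needs at least 3 rows")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  load2 <- p$rotation[, 1:2, drop = FALSE]
  scores <- p$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    flip <- sign(load2[which.max(abs(load2[, j])), j])
    if (flip < 0) {
      load2[, j] <- -load2[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- (p$sdev^2 / sum(p$sdev^2))[1:2]
  colnames(scores) <- colnames(load2) <- c("pc1", "pc2")
  list(scores = scores, loadings = load2, explained = explained)
}

#' Label a two-cluster model Metropolitan / Non-Metropolitan
#'
#' The cluster whose de-standardised population-density centroid is larger
#' is labelled `"Metropolitan"`; the other `"Non-Metropolitan"`. An exact
#' density tie is broken by the larger pharmacy-count centroid.
#'
#' @param model a `cluster_model` with `k = 2`.
#' @param params standardisation parameters from [standardise()].
#' @return The model with a `labels` character vector (index -> label).
#' @export
label_clusters <- function(model, params) {
  if (model$k != 2L) stop_("labelling is defined only for k = 2")
  C <- de_standardise(model$centroids_standardised, params)
  dens <- C[, "population_density"]
  if (dens[1L] == dens[2L]) {
    metro <- which.max(C[, "n_pharmacies"])
  } else {
    metro <- which.max(dens)
  }
  labels <- rep("Non-Metropolitan", 2L)
  labels[metro] <- "Metropolitan"
  model$labels <- labels
  model
}

#' Practice-to-label assignment table from a labelled model
#'
#' @param model labelled `cluster_model`.
#' @return data.table `practice_id, cluster_index, label`.
#' @export
assignment_table <- function(model) {
  lab <- if (is.null(model$labels)) {
    paste0("cluster_", model$assignments)
  } else {
    model$labels[model$assignments]
  }
  data.table(practice_id = names(model$assignments),
             cluster_index = as.integer(model$assignments),
             label = lab)
}

#' De-standardised centroids with within-cluster feature SDs
#'
#' Reports each cluster's archetype: the centroid expressed in original
#' units, alongside the sample SD of each feature among the cluster's
#' member practices (NA for singleton clusters).
#'
#' @param model labelled `cluster_model`.
#' @param params standardisation parameters from [standardise()].
#' @param profiles the profile table the model was fitted on.
#' @return data.table in long format: `label, feature, centroid, sd`.
#' @export
centroid_summary <- function(model, params, profiles) {
  profiles <- as_table(profiles, c("practice_id", feature_names()),
                       "profiles")
  C <- de_standardise(model$centroids_standardised, params)
  asg <- assignment_table(model)
  out <- rbindlist(lapply(seq_len(model$k), function(j) {
    members <- profiles[practice_id %in% asg[cluster_index == j, practice_id]]
    sds <- if (nrow(members) >= 2L) {
      vapply(feature_names(), function(f) sd(members[[f]]), numeric(1))
    } else {
      rep(NA_real_, length(feature_names()))
    }
    data.table(label = asg[cluster_index == j, label][1L],
               feature = feature_names(),
               centroid = as.numeric(C[j, feature_names()]),
               sd = as.numeric(sds))
  }))
  out[]
}
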