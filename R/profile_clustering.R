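#' Assemble the profile matrix used for clustering
#'
#' One row per protein; columns are the scaled values on the timepoint grid
#' for each requested condition, concatenated in the given order (the
#' combined-conditions series when two conditions are supplied). Proteins
#' with any missing timepoint in any requested condition are dropped with a
#' warning.
#'
#' @param profiles `trip_profiles` object.
#' @param conditions one or more condition labels.
#' @return numeric matrix with `condition@timepoint` column names.
#' @export
profile_matrix <- function(profiles, conditions) {
  prof <- profiles$profiles[profiles$profiles$condition %in% conditions, , drop = FALSE]
  if (!nrow(prof)) stop("no profiles for condition(s): ", paste(conditions, collapse = ", "))
  grid <- profiles$grid
  cols <- as.vector(t(outer(conditions, grid, paste, sep = "@")))
  prots <- unique(prof$protein_id)
  m <- matrix(NA_real_, length(prots), length(cols), dimnames = list(prots, cols))
  cc <- paste(prof$condition, prof$timepoint_h, sep = "@")
  m[cbind(match(prof$protein_id, prots), match(cc, cols))] <- prof$scaled
  keep <- rowSums(is.na(m)) == 0L
  if (any(!keep))
    warning(sum(!keep), " protein(s) dropped for incomplete profiles")
  m[keep, , drop = FALSE]
}

#' k-means clustering of scaled temporal profiles
#'
#' Lloyd's algorithm on Euclidean distance over the scaled profile vectors
#' (the concatenated series for a condition pair), run `n_restarts` times
#' from centers sampled among the distinct profiles and keeping the solution
#' with the lowest within-cluster sum of squares. Deterministic given
#' `seed`. Cluster labels are canonicalized by centroid peak time (cluster 1
#' peaks earliest) so labels are stable across conditions and runs.
#'
#' @param profiles `trip_profiles` object, or a numeric profile matrix as
#'   from [profile_matrix()].
#' @param conditions condition label or pair (ignored when `profiles` is a
#'   matrix).
#' @param k number of clusters.
#' @param seed integer RNG seed.
#' @param n_restarts random restarts (default 20).
#' @return object of class `trip_clusters`: `assignment` (`protein_id`,
#'   `cluster`, `distance_to_centroid`), `centroids` (k x T), `inertia`,
#'   `k`, `seed`, `conditions`, and the clustered `data` matrix.
#' @export
cluster_profiles <- function(profiles, conditions = NULL, k, seed = 1L,
                             n_restarts = 20L) {
  X <- if (is.matrix(profiles)) profiles else profile_matrix(profiles, conditions)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " exceeds the ", n, " complete profiles")
  U <- unique(X)
  if (k > 1L && nrow(U) < k)
    stop("only ", nrow(U), " distinct profiles; cannot form ", k, " clusters")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- NULL
    for (try in 1:50) {
      centers <- U[sample.int(nrow(U), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = 200L, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("k-means failed to find a valid start")
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  # canonical display order: earliest-peaking centroid first
  peak_idx <- apply(best$centers, 1L, which.max)
  ord <- order(peak_idx, -apply(best$centers, 1L, max))
  relabel <- match(seq_len(k), ord)
  cl <- relabel[best$cluster]
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  d <- sqrt(rowSums((X - centroids[cl, , drop = FALSE])^2))
  structure(list(
    assignment = data.frame(protein_id = rownames(X), cluster = cl,
                            distance_to_centroid = d, row.names = NULL,
                            stringsAsFactors = FALSE),
    centroids = centroids, inertia = best$tot.withinss, k = k,
    seed = as.integer(seed),
    conditions = if (is.matrix(profiles)) NULL else conditions,
    data = X), class = "trip_clusters")
}

#' @export
print.trip_clusters <- function(x, ...) {
  cat(sprintf("k-means profile clustering: k = %d, %d proteins, inertia %.4g\n",
              x$k, nrow(x$assignment), x$inertia))
  invisible(x)
}

# mean silhouette width for a labeled point set (Euclidean)
mean_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select k by mean silhouette
#'
#' Clusters at every k in `k_range` and selects the k maximizing the mean
#' silhouette width; the full diagnostic table is returned so the choice can
#' be overridden. A best silhouette below 0.3 is reported as weak structure
#' (no well-separated temporal classes).
#'
#' @param profiles `trip_profiles` object or profile matrix.
#' @param conditions condition label or pair.
#' @param k_range candidate k values (default 2:8).
#' @param seed integer RNG seed.
#' @param n_restarts restarts per k.
#' @return list: `selected_k`, `diagnostics` (`k`, `mean_silhouette`,
#'   `inertia`), `weak_structure`.
#' @export
choose_k <- function(profiles, conditions = NULL, k_range = 2:8, seed = 1L,
                     n_restarts = 20L) {
  X <- if (is.matrix(profiles)) profiles else profile_matrix(profiles, conditions)
  k_range <- k_range[k_range <= nrow(unique(X))]
  diag <- do.call(rbind, lapply(k_range, function(k) {
    a <- cluster_profiles(X, k = k, seed = seed, n_restarts = n_restarts)
    sil <- if (k >= 2L) mean_silhouette(X, a$assignment$cluster) else NA_real_
    data.frame(k = k, mean_silhouette = sil, inertia = a$inertia)
  }))
  sel <- diag$k[which.max(diag$mean_silhouette)]
  list(selected_k = sel, diagnostics = diag,
       weak_structure = all(diag$mean_silhouette < 0.3, na.rm = TRUE))
}

#' Per-cluster mean profiles with quartile bands
#'
#' Mean, 25th and 75th percentile of member scaled values per cluster and
#' profile coordinate, plus cluster sizes — the plot-ready form of the
#' cluster ribbon panels.
#'
#' @param a `trip_clusters` object.
#' @param profiles unused; member values are taken from the clustered matrix
#'   stored in `a` (kept for call-site symmetry).
#' @return `data.frame`: `cluster`, `series` (condition@timepoint column
#'   label), `timepoint_h`, `mean`, `q25`, `q75`, `n_proteins`.
#' @export
summarize_clusters <- function(a, profiles = NULL) {
  X <- a$data
  out <- list()
  for (cl in sort(unique(a$assignment$cluster))) {
    M <- X[a$assignment$cluster == cl, , drop = FALSE]
    qs <- apply(M, 2L, stats::quantile, probs = c(0.25, 0.75), type = 7)
    tp <- suppressWarnings(as.numeric(sub(".*@", "", colnames(X))))
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, series = colnames(X), timepoint_h = tp,
      mean = colMeans(M), q25 = qs[1L, ], q75 = qs[2L, ],
      n_proteins = nrow(M), row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cross-condition cluster flow (Sankey table)
#'
#' Contingency of cluster memberships for proteins shared between two
#' cluster assignments (e.g. wild-type vs mutant), as both a flow matrix and
#' a Sankey-ready long table. Marginals conserve the shared-protein count
#' exactly.
#'
#' @param a_A,a_B `trip_clusters` objects.
#' @return list: `matrix` (clusters A x clusters B), `long`
#'   (`source`, `target`, `count`), `n_shared`.
#' @export
cluster_flow <- function(a_A, a_B) {
  shared <- intersect(a_A$assignment$protein_id, a_B$assignment$protein_id)
  if (!length(shared)) stop("assignments share no proteins")
  ca <- a_A$assignment$cluster[match(shared, a_A$assignment$protein_id)]
  cb <- a_B$assignment$cluster[match(shared, a_B$assignment$protein_id)]
  F <- table(factor(ca, levels = seq_len(a_A$k)),
             factor(cb, levels = seq_len(a_B$k)))
  F <- matrix(as.integer(F), nrow = a_A$k,
              dimnames = list(seq_len(a_A$k), seq_len(a_B$k)))
  long <- expand.grid(source = seq_len(a_A$k), target = seq_len(a_B$k))
  long$count <- F[cbind(long$source, long$target)]
  long <- long[long$count > 0L, , drop = FALSE]
  rownames(long) <- NULL
  list(matrix = F, long = long, n_shared = length(shared))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return a single number.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}
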