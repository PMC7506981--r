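#' Silhouette coefficient with auditable intermediates
#'
#' For each point `i`, `a(i)` is its mean Euclidean distance to the other
#' points of its own cluster and `b(i)` the smallest mean distance to the
#' points of any other cluster; the per-point silhouette is
#' `(b(i) - a(i)) / max(a(i), b(i))` and the coefficient is the mean over
#' all points. Values lie in `[-1, 1]`; higher means points sit well inside
#' their own cluster. Points in singleton clusters get `s(i) = 0` (the
#' standard convention).
#'
#' @param features numeric matrix, one row per point.
#' @param labels cluster labels, one per row; at least two distinct values.
#' @return List with `sc` (the coefficient), and per-point vectors `s`,
#'   `a`, `b`.
#' @export
silhouette_report <- function(features, labels) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop_config("features contain non-finite values")
  labels <- as.vector(labels)
  if (length(labels) != nrow(features))
    stop_config("need one label per feature row")
  ulab <- unique(labels)
  if (length(ulab) < 2L)
    stop_config("silhouette undefined for a single cluster (K = 1)")
  D <- as.matrix(stats::dist(features))
  n <- nrow(D)
  idx_by <- lapply(ulab, function(l) which(labels == l))
  names(idx_by) <- as.character(ulab)
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- as.character(labels[i])
    mine <- idx_by[[own]]
    if (length(mine) == 1L) { s[i] <- 0; a[i] <- 0; b[i] <- NA_real_; next }
    a[i] <- sum(D[i, mine]) / (length(mine) - 1L)
    b[i] <- min(vapply(idx_by[setdiff(names(idx_by), own)],
                       function(others) mean(D[i, others]), numeric(1)))
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  list(sc = mean(s), s = s, a = a, b = b)
}

#' Davies-Bouldin index with auditable intermediates
#'
#' For each cluster `i` with centroid `c_i` and dispersion `sigma_i` (mean
#' Euclidean distance of its points to the centroid), the index averages,
#' over clusters, the worst-case similarity
#' `max_{j != i} (sigma_i + sigma_j) / d(c_i, c_j)`. Lower is better; the
#' optimal clustering has the smallest value.
#'
#' @inheritParams silhouette_report
#' @return List with `db` (the index), `centroids` (K x D matrix),
#'   `dispersion` (per-cluster sigma), `centroid_dist` (K x K matrix), and
#'   `worst_pair` (per-cluster index of the maximizing partner).
#' @export
davies_bouldin_report <- function(features, labels) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop_config("features contain non-finite values")
  labels <- as.vector(labels)
  if (length(labels) != nrow(features))
    stop_config("need one label per feature row")
  ulab <- sort(unique(labels))
  K <- length(ulab)
  if (K < 2L) stop_config("Davies-Bouldin undefined for a single cluster (K = 1)")
  cent <- vapply(ulab, function(l)
    colMeans(features[labels == l, , drop = FALSE]), numeric(ncol(features)))
  centroids <- if (is.matrix(cent)) t(cent) else matrix(cent, ncol = 1L)
  dispersion <- vapply(seq_len(K), function(i) {
    pts <- features[labels == ulab[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(centroids[i, ], nrow(pts), ncol(pts),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  zero_pairs <- which(cd == 0 & upper.tri(cd), arr.ind = TRUE)
  if (nrow(zero_pairs))
    stop_numeric("coincident centroids for clusters ",
                 ulab[zero_pairs[1, 1]], " and ", ulab[zero_pairs[1, 2]],
                 ": Davies-Bouldin is undefined")
  ratio <- (outer(dispersion, dispersion, `+`)) / cd
  diag(ratio) <- -Inf
  worst <- apply(ratio, 1L, which.max)
  list(db = mean(apply(ratio, 1L, max)),
       centroids = centroids, dispersion = dispersion,
       centroid_dist = cd, worst_pair = worst)
}

#' Combined cluster-quality report
#'
#' Computes both the silhouette coefficient and the Davies-Bouldin index
#' on a labelled feature matrix (for example CNN features, or raw
#' flattened windows from [flatten_segments()]), with all intermediates
#' retained for audit.
#'
#' @inheritParams silhouette_report
#' @return An object of class `cluster_report`: list with `sc`, `db`,
#'   `silhouette` (full [silhouette_report()] output), `davies_bouldin`
#'   (full [davies_bouldin_report()] output), `n`, `k`.
#' @examples
#' f <- rbind(matrix(rnorm(40), ncol = 2), matrix(rnorm(40, 5), ncol = 2))
#' cluster_report(f, rep(c("a", "b"), each = 20))
#' @export
cluster_report <- function(features, labels) {
  sil <- silhouette_report(features, labels)
  db <- davies_bouldin_report(features, labels)
  structure(list(sc = sil$sc, db = db$db, silhouette = sil,
                 davies_bouldin = db, n = length(labels),
                 k = length(unique(labels))),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> n = %d, k = %d: SC = %.4f, DB = %.4f\n",
              x$n, x$k, x$sc, x$db))
  invisible(x)
}
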