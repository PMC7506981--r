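# Shared helpers: tiny signal builders and an external reference
# implementation of the cluster metrics (scikit-learn via the system
# python), used purely as an independent oracle.

make_signal <- function(n = 100, c = 2, fs = 100, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  emg_signal(withr_seed(matrix(rnorm(n * c), ncol = c)), fs)
}

make_record <- function(n = 100, c = 2, fs = 100, seed = 1, gesture = 0,
                        repetition = 1, subject = "s1") {
  emg_record(make_signal(n, c, fs, seed), subject = subject,
             gesture = gesture, repetition = repetition)
}

signal_scale <- function(x, k) emg_signal(k * x$samples, x$fs)

# silhouette + Davies-Bouldin via scikit-learn, batched: `instances` is a
# list of list(features, labels); returns a matrix with columns sc, db,
# one row per instance, or NULL if the external oracle is unavailable
sklearn_metrics_batch <- function(instances) {
  dir <- tempfile("metrics"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    utils::write.table(cbind(inst$features, as.integer(factor(inst$labels))),
                       file.path(dir, sprintf("inst_%03d.csv", i)), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys, glob, numpy as np",
    "from sklearn.metrics import silhouette_score, davies_bouldin_score",
    "for path in sorted(glob.glob(sys.argv[1] + '/inst_*.csv')):",
    "    d = np.loadtxt(path, delimiter=',', ndmin=2)",
    "    X, y = d[:, :-1], d[:, -1]",
    "    print(repr(silhouette_score(X, y)), repr(davies_bouldin_score(X, y)))"),
    script)
  out <- suppressWarnings(system2("python", c(script, dir),
                                  stdout = TRUE, stderr = FALSE))
  if (length(out) != length(instances)) return(NULL)
  do.call(rbind, lapply(strsplit(out, " "), as.numeric))
}

sklearn_metrics <- function(features, labels) {
  res <- sklearn_metrics_batch(list(list(features = features, labels = labels)))
  if (is.null(res)) NULL else res[1, ]
}

# brute-force silhouette by direct double loops (independent of the
# package's vectorized implementation)
brute_silhouette <- function(features, labels) {
  n <- nrow(features)
  s <- numeric(n)
  d <- function(i, j) sqrt(sum((features[i, ] - features[j, ])^2))
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(vapply(same, d, numeric(1), i = i))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(vapply(which(labels == l), d, numeric(1), i = i))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
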