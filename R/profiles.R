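#' Agglomerative hierarchical clustering of a value matrix
#'
#' Standard agglomerative clustering of the rows of `m` under the chosen
#' linkage and metric, as used to arrange heat-map rows and columns
#' (cluster the transpose for columns). Merge heights are non-decreasing
#' for these linkages.
#'
#' @param m numeric matrix with >= 1 row.
#' @param linkage `"single"`, `"average"` or `"complete"`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return object of class `cluster_result`: `order` (leaf permutation of
#'   row indices), `merges` (data.frame a, b, height; negative entries are
#'   singleton rows, positive entries earlier merges — `stats::hclust`
#'   encoding) and the underlying `hclust` object (`NULL` for a single
#'   row).
#' @export
hier_cluster <- function(m, linkage = c("average", "single", "complete"),
                         metric = c("euclidean", "manhattan")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (nrow(m) == 0L) abort_value("cannot cluster an empty matrix")
  if (nrow(m) == 1L)
    return(structure(list(order = 1L,
                          merges = data.frame(a = integer(0), b = integer(0),
                                              height = numeric(0)),
                          hclust = NULL),
                     class = "cluster_result"))
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  structure(list(order = hc$order,
                 merges = data.frame(a = hc$merge[, 1L], b = hc$merge[, 2L],
                                     height = hc$height),
                 hclust = hc),
            class = "cluster_result")
}

#' Row and column orders for a heat map
#'
#' @param m gene x phenotype value matrix for one time point.
#' @inheritParams hier_cluster
#' @return list(row_order, col_order, row, col) where `row`/`col` are the
#'   full [hier_cluster()] results.
#' @export
cluster_heatmap <- function(m, linkage = "average", metric = "euclidean") {
  m0 <- as.matrix(m)
  m0[is.na(m0)] <- 0          # missing cells are neutral for ordering
  r <- hier_cluster(m0, linkage, metric)
  cl <- hier_cluster(t(m0), linkage, metric)
  list(row_order = r$order, col_order = cl$order, row = r, col = cl)
}

#' One-hot encoding of prominence profiles
#'
#' Each gene's succession profile becomes a numeric vector of n x P
#' indicators: for every time point a block of P entries with a single 1 at
#' the prominent phenotype (all zero when none is prominent). Hamming
#' distance between profiles equals half the squared Euclidean distance
#' between encodings, making the encoding a faithful metric for k-means,
#' unlike integer phenotype codes which would impose a spurious order.
#'
#' @param profiles a `prominence_profile` (or character gene x time matrix).
#' @param phenotypes phenotype universe fixing block column order; defaults
#'   to the profile's `phenotypes` attribute.
#' @return numeric gene x (n * P) matrix; columns named `t<k>:<phenotype>`.
#' @export
encode_profiles <- function(profiles, phenotypes = attr(profiles, "phenotypes")) {
  if (is.null(phenotypes)) abort_value("phenotype universe required")
  n <- ncol(profiles)
  P <- length(phenotypes)
  enc <- matrix(0, nrow(profiles), n * P,
                dimnames = list(rownames(profiles),
                                paste0("t", rep(seq_len(n), each = P), ":",
                                       rep(phenotypes, n))))
  for (t in seq_len(n)) {
    idx <- match(profiles[, t], phenotypes)
    ok <- which(!is.na(idx))
    enc[cbind(ok, (t - 1L) * P + idx[ok])] <- 1
  }
  enc
}

#' K-means classing of encoded succession profiles
#'
#' Lloyd iteration from `restarts` seeded random initializations (k distinct
#' encoded profiles each), keeping the restart with the smallest total
#' within-cluster sum of squares. Deterministic for a fixed seed.
#'
#' @param encoding matrix from [encode_profiles()].
#' @param k number of classes (default 4); must not exceed the number of
#'   distinct encoded profiles.
#' @param seed integer seed.
#' @param restarts number of random restarts (>= 1).
#' @return list: `assignments` (named integer vector), `tot_withinss`,
#'   `centers`.
#' @export
kmeans_profiles <- function(encoding, k = 4L, seed = 1L, restarts = 10L) {
  encoding <- as.matrix(encoding)
  uniq <- unique(encoding)
  if (k > nrow(uniq))
    abort_value(sprintf("k = %d exceeds the %d distinct profiles", k,
                        nrow(uniq)))
  if (restarts < 1L) abort_value("restarts must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(encoding, centers = centers, iter.max = 200L,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(assignments = stats::setNames(best$cluster, rownames(encoding)),
       tot_withinss = best$tot.withinss,
       centers = best$centers)
}

#' Two-component principal projection of encoded profiles
#'
#' Centers the encodings and projects them onto the first two principal
#' axes. Axis signs follow the convention that the first nonzero loading of
#' each axis is positive, so outputs are reproducible across platforms.
#'
#' @param encoding matrix from [encode_profiles()] with >= 2 rows.
#' @return list: `scores` (gene x 2 matrix, columns PC1/PC2),
#'   `var_explained` (length-2 fraction of total variance).
#' @export
pca2 <- function(encoding) {
  encoding <- as.matrix(encoding)
  if (nrow(encoding) < 2L) abort_value("at least 2 genes required")
  pr <- stats::prcomp(encoding, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sco <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    nz <- which(abs(rot[, j]) > 1e-12)
    if (length(nz) > 0L && rot[nz[1L], j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  if (k < 2L) {
    sco <- cbind(sco, 0)
  }
  colnames(sco) <- c("PC1", "PC2")
  tot <- sum(pr$sdev^2)
  ve <- if (tot > 0) (pr$sdev^2)[1:2] / tot else c(0, 0)
  ve[is.na(ve)] <- 0
  list(scores = sco, var_explained = ve)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
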