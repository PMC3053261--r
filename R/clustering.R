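#' Group-mean expression profiles for one response category
#'
#' Builds each probeset's 4-vector of log2 group means in the fixed order
#' control, cytokines, shRNA, shRNA+cytokines, plus a per-probeset z-scored
#' copy so clustering responds to profile shape, not absolute intensity.
#' Constant profiles get an all-zero standardized vector.
#'
#' @param records ANOVA table from [anova_two_way()] (carries the cell
#'   means), or an `ExpressionBundle`.
#' @param calls optional data.frame from [classify_probesets()] restricted by
#'   `category`.
#' @param category optional category label; only matching probesets are kept.
#' @return list with `raw` and `standardized` matrices (probesets x 4,
#'   columns `ctrl`, `cyt`, `sh`, `both`).
#' @export
build_profiles <- function(records, calls = NULL, category = NULL) {
  if (inherits(records, "ExpressionBundle")) records <- anova_two_way(records)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(category)) {
    if (is.null(calls)) stop("calls required when filtering by category")
    ids <- calls$probeset_id[calls$category == category]
    keep <- records$probeset_id %in% ids
  }
  m <- as.matrix(records[keep, c("m_ctrl", "m_cyt", "m_sh", "m_both"), drop = FALSE])
  colnames(m) <- c("ctrl", "cyt", "sh", "both")
  rownames(m) <- records$probeset_id[keep]
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))  # population sd: z has unit variance over the 4 cells
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  list(raw = m, standardized = z)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((x - matrix(x[centers[i + 1L], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of standardized profiles
#'
#' Euclidean K-means with k-means++ seeding, best of `n_restarts` runs by
#' within-cluster sum of squares (inertia), deterministic given `seed`.
#' Cluster indices are relabeled by descending cluster size (ties broken by
#' the smallest member row index) so labels are stable across runs.
#'
#' @param profiles output of [build_profiles()] or a numeric matrix (rows =
#'   probesets); the standardized matrix is used when a profile list is given.
#' @param k number of clusters (`1 <= k <=` number of profiles).
#' @param seed integer RNG seed.
#' @param n_restarts number of k-means++ restarts (default 50).
#' @return `ClusterModel` list: `category` (NA unless set by caller), `k`,
#'   `centroids` (k x 4), `assignments` (named integer vector), `inertia`,
#'   `seed`, `n_restarts`.
#' @export
kmeans_profiles <- function(profiles, k, seed = 17L, n_restarts = 50L) {
  x <- if (is.list(profiles)) profiles$standardized else profiles
  x <- as.matrix(x)
  if (k < 1L) stop("k must be >= 1")
  if (nrow(x) < k)
    stop(sprintf("cannot form %d clusters from %d profiles", k, nrow(x)))

  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (run in seq_len(n_restarts)) {
    centers <- kmeanspp_init(x, k)
    # duplicate centers can arise on degenerate data; jitter-free fallback:
    centers <- centers[!duplicated(centers), , drop = FALSE]
    while (nrow(centers) < k) {
      extra <- x[sample.int(nrow(x), 1L), , drop = FALSE]
      centers <- rbind(centers, extra)
      centers <- centers[!duplicated(centers), , drop = FALSE]
      if (nrow(unique(x)) < k) break
    }
    if (nrow(centers) < k) stop("fewer than k distinct profiles; cannot place k centers")
    fit <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L,
                                          algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12) best <- fit
  }

  # deterministic relabeling: descending size, ties by smallest member index
  sizes <- tabulate(best$cluster, nbins = k)
  first_member <- vapply(seq_len(k), function(c) {
    w <- which(best$cluster == c)
    if (length(w)) min(w) else .Machine$integer.max
  }, numeric(1L))
  ord <- order(-sizes, first_member)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignments <- stats::setNames(relabel[best$cluster], rownames(x))
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)

  structure(list(category = NA_character_, k = k, centroids = centroids,
                 assignments = assignments, inertia = best$tot.withinss,
                 seed = seed, n_restarts = n_restarts),
            class = "ClusterModel")
}

#' Default per-category cluster counts
#'
#' The fixed cluster counts used in the study design: 2 for each
#' single-factor category, 4 for the additive and 8 for the interactive
#' category.
#' @return named integer vector `c(A = 2, B = 2, C = 4, D = 8)`.
#' @export
default_k_map <- function() c(A = 2L, B = 2L, C = 4L, D = 8L)

#' Cluster every category's profiles with its configured k
#'
#' @param records ANOVA table from [anova_two_way()].
#' @param calls data.frame from [classify_probesets()].
#' @param k_map named integer vector of cluster counts per category.
#' @param seed integer RNG seed (per-category seeds are derived from it).
#' @param n_restarts restarts per category.
#' @return named list of `ClusterModel`s (categories with fewer members than
#'   `k` raise an error naming the category; empty categories are skipped).
#' @export
cluster_categories <- function(records, calls, k_map = default_k_map(),
                               seed = 17L, n_restarts = 50L) {
  models <- list()
  for (cat in names(k_map)) {
    prof <- build_profiles(records, calls, category = cat)
    n <- nrow(prof$standardized)
    if (n == 0L) next
    if (n < k_map[[cat]])
      stop(sprintf("category %s has %d members, fewer than k = %d",
                   cat, n, k_map[[cat]]))
    model <- kmeans_profiles(prof, k_map[[cat]],
                             seed = (seed + match(cat, names(k_map))) %% 2147483647L,
                             n_restarts = n_restarts)
    model$category <- cat
    models[[cat]] <- model
  }
  models
}
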