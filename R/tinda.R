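#' Tumor-in-normal contamination rescue (TiNDA-style)
#'
#' Clusters paired B-allele frequencies (control vs tumor) with a seeded
#' Gaussian-mixture model and reclassifies as somatic the germline-annotated
#' positions of clusters that sit above the identity line: a cluster is
#' called tumor-in-normal when at least `threshold` of its positions have a
#' tumor VAF exceeding the control VAF.
#'
#' @param points data frame with columns `vaf_control`, `vaf_tumor` in
#'   `[0, 1]`, `class` (`"germline"`/`"somatic"`) and optionally `common`
#'   (logical; common-variant positions are dropped before clustering).
#' @param k number of mixture components (default 9).
#' @param seed integer seed driving the deterministic initialization.
#' @param threshold minimal above-identity fraction for a tumor-in-normal
#'   cluster; compared inclusively (`>=`) by default.
#' @param strict compare the threshold strictly (`>`) instead.
#' @param merge_radius components whose fitted means lie within this
#'   Euclidean VAF distance are coalesced (single linkage) before the
#'   identity-line test; a fixed-k mixture over-segments a single BAF cloud
#'   into slivers, and an above-line sliver of a symmetric germline cloud
#'   must not masquerade as contamination. The default (0.1) is about twice
#'   the binomial VAF standard deviation at typical depth.
#' @return list with the filtered `points` (plus `cluster` and `rescued`
#'   columns), `cluster_fraction_above` per cluster and `tin_clusters`
#'   (cluster labels refer to the coalesced components).
#' @export
run_tinda <- function(points, k = 9, seed = 1, threshold = 0.75,
                      strict = FALSE, merge_radius = 0.1) {
  stopifnot(all(c("vaf_control", "vaf_tumor", "class") %in% names(points)))
  if (any(points$vaf_control < 0 | points$vaf_control > 1 |
          points$vaf_tumor < 0 | points$vaf_tumor > 1))
    stop("VAFs must lie in [0, 1]")
  if ("common" %in% names(points))
    points <- points[!points$common, , drop = FALSE]
  if (nrow(points) < k)
    stop("fewer points (", nrow(points), ") than clusters (", k,
         "); use a smaller k")
  X <- cbind(points$vaf_control, points$vaf_tumor)
  fit <- gmm_fit(X, k = k, seed = seed)
  # coalesce components sharing a density mode: single-linkage on the
  # component means at merge_radius
  occupied <- sort(unique(fit$cluster))
  group <- seq_len(k)
  for (a in occupied) for (b in occupied) if (a < b) {
    if (sqrt(sum((fit$means[a, ] - fit$means[b, ])^2)) < merge_radius) {
      ga <- group[a]; gb <- group[b]
      group[group == gb] <- ga
    }
  }
  cl <- group[fit$cluster]
  above <- points$vaf_tumor > points$vaf_control
  frac <- vapply(seq_len(k), function(j) {
    n <- sum(cl == j)
    if (n == 0) NA_real_ else sum(above[cl == j]) / n
  }, 0)
  tin <- which(!is.na(frac) &
                 (if (strict) frac > threshold else frac >= threshold))
  points$cluster <- cl
  points$rescued <- cl %in% tin & points$class == "germline"
  list(points = points,
       cluster_fraction_above = frac,
       tin_clusters = tin,
       model = fit[c("weights", "means", "loglik", "iterations")])
}

# seeded full-covariance Gaussian-mixture EM with k-means++-style
# initialization; a single restart (one pass)
gmm_fit <- function(X, k, seed, tol = 1e-6, max_iter = 500L,
                    reg = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  set.seed(as.integer(seed %% 2147483647))
  # k-means++ seeding of component means
  centers <- matrix(0, k, d)
  centers[1, ] <- X[sample.int(n, 1), ]
  mind <- rowSums((X - matrix(centers[1, ], n, d, byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    pr <- mind / sum(mind)
    if (!all(is.finite(pr)) || sum(pr) == 0) pr <- rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1, prob = pr), ]
    mind <- pmin(mind, rowSums((X - matrix(centers[j, ], n, d,
                                           byrow = TRUE))^2))
  }
  w <- rep(1 / k, k)
  mu <- centers
  sig <- replicate(k, stats::cov(X) + reg * diag(d), simplify = FALSE)
  loglik <- -Inf
  logdens <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k))
      logdens[, j] <- log(w[j]) + dmvnorm_log(X, mu[j, ], sig[[j]])
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    for (j in seq_len(k)) {
      if (nk[j] < 1e-10) { w[j] <- 0; next }  # degenerate component retires
      w[j] <- nk[j] / n
      mu[j, ] <- colSums(resp[, j] * X) / nk[j]
      Xc <- X - matrix(mu[j, ], n, d, byrow = TRUE)
      sig[[j]] <- crossprod(Xc * resp[, j], Xc) / nk[j] + reg * diag(d)
    }
    w <- w / sum(w)
    if (is.finite(loglik) && abs(ll - loglik) < tol * abs(ll)) {
      loglik <- ll; break
    }
    loglik <- ll
  }
  cluster <- max.col(logdens, ties.method = "first")
  list(cluster = cluster, weights = w, means = mu, covariances = sig,
       loglik = loglik, iterations = it)
}

# log density of a multivariate normal (d = 2 here)
dmvnorm_log <- function(X, mu, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  Xc <- X - matrix(mu, nrow(X), d, byrow = TRUE)
  z <- backsolve(ch, t(Xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Summarize rescued variants across a cohort
#'
#' @param rescue_list named list (sample id -> the `points` element of a
#'   [run_tinda()] result); an optional `effect` column per point feeds the
#'   category breakdown.
#' @return list with per-sample counts, mean, range, and the pooled effect
#'   category fractions of rescued positions.
#' @export
rescue_summary <- function(rescue_list) {
  counts <- vapply(rescue_list, function(p) sum(p$rescued), 0L)
  effs <- unlist(lapply(rescue_list, function(p)
    if ("effect" %in% names(p)) p$effect[p$rescued] else character()))
  frac <- if (length(effs)) table(effs) / length(effs) else table(character())
  list(per_sample = counts,
       mean = if (length(counts)) mean(counts) else 0,
       range = if (length(counts)) range(counts) else c(0L, 0L),
       effect_fractions = frac)
}
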