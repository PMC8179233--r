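# The eight traditional one-class detector families.
#
# Internal contract: fit_<family>(X, hp, seed) returns opaque state;
# family_score(state, X) returns ORIENTED raw scores (higher = more
# inlier; families whose native score is anomaly-high are multiplied by
# -1 here, once, at the source). All implementations are deterministic
# given the seed. No external ML library backs these: nothing equivalent
# is available in the target environment, and quantile thresholding (see
# occ-traditional.R) only needs internally consistent raw scores.

# ---- Gaussian mixture density ------------------------------------------

# EM with diagonal (default) or full component covariances;
# ridge-regularized, k-means initialization. The diagonal default with
# several components tiles the correlated inlier manifold with local
# blobs, which is markedly more robust than one anisotropic Gaussian on
# heavy-tailed pair data; full covariance is available as a
# hyperparameter.
fit_gmm <- function(X, hp, seed) {
  k <- as.integer(hp$n_components %||% 8L)
  covariance <- hp$covariance %||% "diag"
  reg <- hp$reg %||% 1e-6
  n <- nrow(X); d <- ncol(X)
  if (nrow(unique(X)) < 2L)
    oc_stop("degenerate training set (single unique row) for a density family",
            "oc_fit_error")
  k <- max(1L, min(k, nrow(unique(X))))
  mu <- with_seed(seed, {
    if (k == 1L) matrix(colMeans(X), 1L)
    else suppressWarnings(stats::kmeans(X, centers = k, nstart = 3L,
                                        iter.max = 50L))$centers
  })
  full <- identical(covariance, "full")
  ridge_v <- reg + 1e-6 * mean(apply(X, 2, stats::var))
  sigma <- if (full) rep(list(stats::cov(X) + diag(ridge_v, d)), k)
  else rep(list(apply(X, 2, stats::var) + ridge_v), k)
  w <- rep(1 / k, k)
  prev_ll <- -Inf
  for (iter in seq_len(100L)) {
    lp <- gmm_logdens(X, mu, sigma, w)           # n x k joint log densities
    m <- apply(lp, 1, max)
    ll <- sum(m + log(rowSums(exp(lp - m))))
    r <- exp(lp - m - log(rowSums(exp(lp - m)))) # responsibilities
    nk <- colSums(r) + 1e-12
    w <- nk / n
    mu <- (t(r) %*% X) / nk
    for (c in seq_len(k)) {
      xc <- sweep(X, 2, mu[c, ])
      sigma[[c]] <- if (full) crossprod(xc * r[, c], xc) / nk[c] +
        diag(ridge_v, d)
      else colSums(xc^2 * r[, c]) / nk[c] + ridge_v
    }
    if (abs(ll - prev_ll) < 1e-8 * (1 + abs(ll))) break
    prev_ll <- ll
  }
  list(mu = mu, sigma = sigma, w = w, full = full)
}

gmm_logdens <- function(X, mu, sigma, w) {
  k <- nrow(mu)
  lp <- matrix(0, nrow(X), k)
  for (c in seq_len(k)) {
    xc <- sweep(X, 2, mu[c, ])
    if (is.matrix(sigma[[c]])) {
      ch <- chol(sigma[[c]])
      maha <- colSums(forwardsolve(t(ch), t(xc))^2)
      logdet_half <- sum(log(diag(ch)))
    } else {
      maha <- rowSums(sweep(xc^2, 2, sigma[[c]], "/"))
      logdet_half <- 0.5 * sum(log(sigma[[c]]))
    }
    lp[, c] <- log(w[c]) - logdet_half -
      0.5 * ncol(X) * log(2 * pi) - 0.5 * maha
  }
  lp
}

score_gmm <- function(state, X) {
  lp <- gmm_logdens(X, state$mu, state$sigma, state$w)
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))   # log-likelihood: higher = more inlier
}

# ---- Local outlier factor ----------------------------------------------

# Training k-distances and local reachability densities use the classic
# self-excluded neighbourhoods; query points are scored against the
# training set (novelty-style LOF).
fit_lof <- function(X, hp, seed) {
  k <- max(1L, min(as.integer(hp$n_neighbors %||% 20L), nrow(X) - 1L))
  D <- cross_dist(X, X)
  diag(D) <- Inf
  nn <- t(matrix(apply(D, 1, function(r) order(r)[seq_len(k)]), nrow = k))
  k_dist <- D[cbind(seq_len(nrow(X)), nn[, k])]
  reach <- matrix(0, nrow(X), k)
  for (j in seq_len(k))
    reach[, j] <- pmax(D[cbind(seq_len(nrow(X)), nn[, j])], k_dist[nn[, j]])
  lrd <- 1 / (rowMeans(reach) + 1e-12)
  list(X = X, k = k, k_dist = k_dist, lrd = lrd)
}

score_lof <- function(state, X) {
  D <- cross_dist(X, state$X)
  k <- state$k
  lof <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    nn <- order(D[i, ])[seq_len(k)]
    reach <- pmax(D[i, nn], state$k_dist[nn])
    lrd_q <- 1 / (mean(reach) + 1e-12)
    lof[i] <- mean(state$lrd[nn]) / lrd_q
  }
  -lof   # native LOF is anomaly-high
}

# ---- kNN distance -------------------------------------------------------

fit_knn <- function(X, hp, seed) {
  list(X = X, k = max(1L, min(as.integer(hp$k %||% 5L), nrow(X))))
}

score_knn <- function(state, X) {
  D <- cross_dist(X, state$X)
  kth <- apply(D, 1, function(r) sort(r, partial = state$k)[state$k])
  -kth
}

# ---- Isolation forest ---------------------------------------------------

iforest_cn <- function(n) {
  # average unsuccessful-search path length in a BST of n points
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

iforest_build <- function(X, idx, depth, limit) {
  n <- length(idx)
  if (n <= 1L || depth >= limit)
    return(list(leaf = TRUE, size = n))
  rng <- apply(X[idx, , drop = FALSE], 2, range)
  usable <- which(rng[2, ] > rng[1, ])
  if (length(usable) == 0L)
    return(list(leaf = TRUE, size = n))
  f <- if (length(usable) == 1L) usable else sample(usable, 1L)
  s <- stats::runif(1, rng[1, f], rng[2, f])
  left <- idx[X[idx, f] < s]
  right <- idx[X[idx, f] >= s]
  if (length(left) == 0L || length(right) == 0L)
    return(list(leaf = TRUE, size = n))
  list(leaf = FALSE, feature = f, split = s,
       left = iforest_build(X, left, depth + 1L, limit),
       right = iforest_build(X, right, depth + 1L, limit))
}

fit_iforest <- function(X, hp, seed) {
  n_trees <- as.integer(hp$n_trees %||% 100L)
  psi <- min(as.integer(hp$subsample %||% 256L), nrow(X))
  limit <- ceiling(log2(max(psi, 2)))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
    idx <- if (psi < nrow(X)) sample(nrow(X), psi) else seq_len(nrow(X))
    iforest_build(X, idx, 0L, limit)
  }))
  list(trees = trees, psi = psi)
}

iforest_path <- function(node, X, idx, depth, out) {
  if (node$leaf) {
    out[idx] <- depth + iforest_cn(node$size)
    return(out)
  }
  go_left <- X[idx, node$feature] < node$split
  if (any(go_left))
    out <- iforest_path(node$left, X, idx[go_left], depth + 1, out)
  if (any(!go_left))
    out <- iforest_path(node$right, X, idx[!go_left], depth + 1, out)
  out
}

score_iforest <- function(state, X) {
  pl <- matrix(0, nrow(X), length(state$trees))
  for (t in seq_along(state$trees))
    pl[, t] <- iforest_path(state$trees[[t]], X, seq_len(nrow(X)), 0,
                            numeric(nrow(X)))
  anomaly <- 2^(-rowMeans(pl) / iforest_cn(state$psi))
  -anomaly
}

# ---- One-class SVM (nu-SVM dual, RBF kernel) ---------------------------

# min 1/2 a' K a  s.t.  0 <= a_i <= 1/(nu n), sum a = 1, solved by
# projected gradient descent with a capped-simplex projection.
project_capped_simplex <- function(v, cap) {
  lo <- min(v) - cap - 1
  hi <- max(v)
  for (it in seq_len(64L)) {
    lam <- (lo + hi) / 2
    s <- sum(pmin(pmax(v - lam, 0), cap))
    if (s > 1) lo <- lam else hi <- lam
  }
  pmin(pmax(v - (lo + hi) / 2, 0), cap)
}

fit_ocsvm <- function(X, hp, seed) {
  n <- nrow(X)
  nu <- hp$nu %||% 0.05
  gamma <- hp$gamma %||% (1 / (ncol(X) * mean(apply(X, 2, stats::var)) + 1e-12))
  cap <- 1 / (max(nu, 1 / n) * n)
  K <- exp(-gamma * cross_dist2(X, X))
  alpha <- rep(1 / n, n)
  # Lipschitz constant of the gradient is the top eigenvalue of K
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(25L)) { v <- K %*% v; v <- v / sqrt(sum(v^2)) }
  L <- max(as.numeric(t(v) %*% K %*% v), 1e-8)
  step <- 1 / L
  # FISTA (accelerated projected gradient) with objective-based restart
  y <- alpha; tk <- 1
  obj <- function(a) 0.5 * sum(a * (K %*% a))
  prev_obj <- obj(alpha); stall <- 0L
  for (it in seq_len(hp$max_iter %||% 2000L)) {
    alpha_new <- project_capped_simplex(y - step * as.numeric(K %*% y), cap)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- alpha_new + ((tk - 1) / t_new) * (alpha_new - alpha)
    alpha <- alpha_new; tk <- t_new
    if (it %% 25L == 0L) {
      cur <- obj(alpha)
      if (cur > prev_obj) { y <- alpha; tk <- 1 }           # restart
      stall <- if (prev_obj - cur < 1e-12 * (1 + abs(cur))) stall + 1L else 0L
      prev_obj <- cur
      if (stall >= 3L) break
    }
  }
  f_train <- as.numeric(K %*% alpha)
  sv <- which(alpha > 1e-8 & alpha < cap - 1e-8)
  rho <- if (length(sv) > 0) mean(f_train[sv]) else mean(f_train[alpha > 1e-8])
  list(X = X, alpha = alpha, gamma = gamma, rho = rho)
}

score_ocsvm <- function(state, X) {
  K <- exp(-state$gamma * cross_dist2(X, state$X))
  as.numeric(K %*% state$alpha) - state$rho
}

# ---- Histogram-based outlier score -------------------------------------

fit_hbos <- function(X, hp, seed) {
  nb <- as.integer(hp$n_bins %||% 10L)
  d <- ncol(X); n <- nrow(X)
  hists <- vector("list", d)
  for (j in seq_len(d)) {
    lo <- min(X[, j]); hi <- max(X[, j])
    if (hi == lo) {
      hists[[j]] <- list(constant = TRUE, value = lo)
    } else {
      breaks <- seq(lo, hi, length.out = nb + 1L)
      cnt <- tabulate(pmin(pmax(findInterval(X[, j], breaks,
                                             rightmost.closed = TRUE), 1L), nb),
                      nbins = nb)
      dens <- cnt / (n * diff(breaks))
      hists[[j]] <- list(constant = FALSE, breaks = breaks, dens = dens)
    }
  }
  list(hists = hists, eps = 1e-12)
}

score_hbos <- function(state, X) {
  out <- numeric(nrow(X))
  for (j in seq_along(state$hists)) {
    h <- state$hists[[j]]
    if (h$constant) {
      dj <- ifelse(X[, j] == h$value, 1, state$eps)
    } else {
      nb <- length(h$dens)
      idx <- findInterval(X[, j], h$breaks, rightmost.closed = TRUE)
      inside <- idx >= 1L & idx <= nb
      dj <- rep(state$eps, nrow(X))
      dj[inside] <- pmax(h$dens[idx[inside]], state$eps)
    }
    out <- out + log(dj)
  }
  out   # summed log densities: higher = more inlier
}

# ---- Cluster-based LOF --------------------------------------------------

fit_cblof <- function(X, hp, seed) {
  k <- as.integer(hp$n_clusters %||% 8L)
  alpha <- hp$alpha %||% 0.9
  beta <- hp$beta %||% 5
  k <- max(1L, min(k, nrow(unique(X))))
  km <- with_seed(seed,
                  suppressWarnings(stats::kmeans(X, centers = k, nstart = 5L,
                                                 iter.max = 50L)))
  sizes <- km$size
  ord <- order(sizes, decreasing = TRUE)
  cum <- cumsum(sizes[ord])
  n <- nrow(X)
  b <- length(ord)
  for (i in seq_along(ord)) {
    boundary <- cum[i] >= alpha * n ||
      (i < length(ord) && sizes[ord[i]] / max(sizes[ord[i + 1]], 1) >= beta)
    if (boundary) { b <- i; break }
  }
  large <- ord[seq_len(b)]
  list(centers = km$centers[large, , drop = FALSE])
}

score_cblof <- function(state, X) {
  D <- cross_dist(X, state$centers)
  -apply(D, 1, min)
}

# ---- Feature bagging (LOF base) ----------------------------------------

fit_fbag <- function(X, hp, seed) {
  m <- as.integer(hp$n_bags %||% 10L)
  d <- ncol(X)
  bags <- with_seed(seed, lapply(seq_len(m), function(b) {
    size <- if (d <= 2L) d else sample(seq(ceiling(d / 2), d), 1L)
    sort(sample(d, size))
  }))
  fits <- lapply(seq_len(m), function(b)
    fit_lof(X[, bags[[b]], drop = FALSE],
            list(n_neighbors = hp$n_neighbors %||% 20L),
            derive_seed(seed, b)))
  list(bags = bags, fits = fits)
}

score_fbag <- function(state, X) {
  s <- vapply(seq_along(state$bags), function(b)
    score_lof(state$fits[[b]], X[, state$bags[[b]], drop = FALSE]),
    numeric(nrow(X)))
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  rowMeans(s)
}

# ---- Dispatch table -----------------------------------------------------

.oc_families <- list(
  gaussian_mixture_density = list(fit = fit_gmm, score = score_gmm),
  local_outlier_factor     = list(fit = fit_lof, score = score_lof),
  knn_distance             = list(fit = fit_knn, score = score_knn),
  isolation_forest         = list(fit = fit_iforest, score = score_iforest),
  one_class_svm            = list(fit = fit_ocsvm, score = score_ocsvm),
  histogram_density        = list(fit = fit_hbos, score = score_hbos),
  cluster_based_lof        = list(fit = fit_cblof, score = score_cblof),
  feature_bagged_lof       = list(fit = fit_fbag, score = score_fbag)
)

#' Names of the eight traditional detector families
#' @return Character vector of family names.
#' @export
detector_families <- function() names(.oc_families)
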