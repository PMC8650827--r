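## t-distributed stochastic neighbour embedding of the NMF scores. The
## embedding is always computed from the k-dimensional scores, never the
## raw voxel matrix. Per-point bandwidths are calibrated by bisection so
## every conditional neighbour distribution attains the target perplexity;
## the low-dimensional kernel is Student-t with one degree of freedom, and
## the layout is optimised by momentum gradient descent with early
## exaggeration and adaptive per-coordinate gains.

## Conditional affinities: bisection on the precision beta_i so that
## 2^H(P_i) matches `perplexity` to within `tol` (absolute, on the
## perplexity scale). Returns the row-conditional matrix and the
## symmetrised joint P.
tsne_affinities <- function(X, perplexity = 30, tol = 1e-4, max_bisect = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  target_log <- log2(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (b in seq_len(max_bisect)) {
      p <- exp(-(di - min(di)) * beta)   # shift for numerical stability
      sp <- sum(p)
      p <- p / sp
      h <- -sum(ifelse(p > 0, p * log2(p), 0))
      if (abs(2^h - perplexity) <= tol) break
      if (h > target_log) {        # too entropic: sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  joint <- (P + t(P)) / (2 * n)
  joint <- pmax(joint, 1e-12)
  diag(joint) <- 0
  list(conditional = P, joint = joint)
}

#' Embed NMF scores in two dimensions by t-SNE
#'
#' @param scores n x k numeric matrix (e.g. `nmf_model$scores`); n >= 4.
#' @param perplexity target perplexity (default 30); must be below
#'   `(n - 1) / 3`.
#' @param seed RNG seed (initial layout and duplicate-row jitter).
#' @param n_iter gradient-descent iterations (default 1000; early
#'   exaggeration x12 for the first 250, learning rate `max(50, n/12)`).
#' @param filter_mu,filter_r structure-aware filtering parameters recorded
#'   for downstream use (see [saf_filter()]); not applied here.
#' @return an object of class `embedding_2d`: list with `coords` (n x 2),
#'   `perplexity`, `seed`, `n_iter`, `filter_mu`, `filter_r`.
#' @export
embed_2d <- function(scores, perplexity = 30, seed = 1, n_iter = 1000,
                     filter_mu = 0.2, filter_r = 0.1) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (n < 4) stop("t-SNE needs at least 4 points")
  if (perplexity >= (n - 1) / 3) {
    stop(sprintf("perplexity %g infeasible for n = %d (needs < (n-1)/3)",
                 perplexity, n))
  }
  co <- with_seed(seed, {
    if (any(duplicated(X))) {
      X <- X + matrix(rnorm(length(X), sd = 1e-9), nrow(X))
    }
    P <- tsne_affinities(X, perplexity)$joint
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    eta <- max(50, n / 12)
    momentum <- 0.5
    update <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exag <- 12
    Pe <- P * exag
    for (it in seq_len(n_iter)) {
      if (it == 251) { Pe <- P; momentum <- 0.8 }
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- num / sum(num)
      L <- (Pe - pmax(Q, 1e-12)) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(update), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      update <- momentum * update - eta * gains * grad
      Y <- Y + update
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
  structure(list(coords = co, perplexity = perplexity, seed = as.integer(seed),
                 n_iter = as.integer(n_iter), filter_mu = filter_mu,
                 filter_r = filter_r),
            class = "embedding_2d")
}

#' Structure-aware filtering of embedding coordinates
#'
#' Neighbourhood mean-shift regularisation: each point is displaced toward
#' the mean of its neighbours within radius `r` (expressed as a fraction of
#' the input bounding-box diagonal) by factor `mu`, for a fixed small
#' number of iterations. Sharpens cluster structure while leaving
#' well-separated groups' relative geometry untouched; `mu = 0` is the
#' identity.
#'
#' @param coords n x 2 matrix or an `embedding_2d`.
#' @param mu regularisation strength in \[0, 1\] (default 0.2).
#' @param r neighbourhood radius as a fraction of the bounding-box diagonal
#'   (default 0.1; must be > 0).
#' @param n_iter smoothing iterations (default 10).
#' @return filtered coordinate matrix (or `embedding_2d` if one was given).
#' @export
saf_filter <- function(coords, mu = 0.2, r = 0.1, n_iter = 10) {
  obj <- NULL
  if (inherits(coords, "embedding_2d")) { obj <- coords; coords <- obj$coords }
  stopifnot(mu >= 0, mu <= 1, r > 0)
  Y <- as.matrix(coords)
  if (mu > 0 && nrow(Y) > 1) {
    rng <- apply(Y, 2, range)
    diag_len <- sqrt(sum((rng[2, ] - rng[1, ])^2))
    radius <- r * diag_len
    if (radius > 0) {
      for (it in seq_len(n_iter)) {
        D <- as.matrix(dist(Y))
        A <- D <= radius
        diag(A) <- FALSE
        deg <- rowSums(A)
        has <- deg > 0
        nb_mean <- (A[has, , drop = FALSE] %*% Y) / deg[has]
        Y[has, ] <- (1 - mu) * Y[has, , drop = FALSE] + mu * nb_mean
      }
    }
  }
  if (!is.null(obj)) { obj$coords <- Y; return(obj) }
  Y
}
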