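## Non-negative matrix factorisation of the lesion matrix. A parts-based
## decomposition suits binary damage patterns: components resemble
## (smoothed) territory fragments and scores are nonnegative loadings.
## Multiplicative updates minimise the Frobenius reconstruction error;
## initialisation is deterministic NNDSVD (nonnegative double SVD) with a
## seeded uniform fallback, so the fit is reproducible.

#' Fit a nonnegative matrix factorisation
#'
#' Lee-Seung multiplicative updates for `X ~ scores %*% components` under
#' the Frobenius loss. The relative reconstruction error
#' `||X - WH||_F / ||X||_F` is recorded per iteration; under these updates
#' the trace is non-increasing. Stops when the relative improvement drops
#' below `tol` or at `max_iter`.
#'
#' @param X a `data_matrix` or nonnegative numeric matrix (n x V).
#' @param k factorisation rank (default 50).
#' @param seed RNG seed for the random fallback initialisation.
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol relative-improvement stopping tolerance.
#' @param init `"nndsvd"` (deterministic, default) or `"random"`.
#' @return an object of class `nmf_model`: list with `scores` (n x k),
#'   `components` (k x V), `k`, `seed`, `error_trace`, `tol`, `max_iter`.
#' @export
fit_nmf <- function(X, k = 50, seed = 1, max_iter = 500, tol = 1e-5,
                    init = c("nndsvd", "random")) {
  if (inherits(X, "data_matrix")) X <- X$values
  X <- as.matrix(X)
  init <- match.arg(init)
  if (any(X < 0)) stop("X must be elementwise nonnegative")
  n <- nrow(X); V <- ncol(X)
  if (k < 1 || k > min(n, V)) stop("k out of range [1, min(n, V)]")
  eps <- 1e-10
  WH <- nmf_init(X, k, seed, init)
  W <- WH$W; H <- WH$H
  x2 <- sum(X^2)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WtX <- crossprod(W, X)                     # k x V
    H <- H * WtX / (crossprod(W) %*% H + eps)
    XHt <- X %*% t(H)                          # n x k
    HHt <- tcrossprod(H)
    W <- W * XHt / (W %*% HHt + eps)
    ## ||X - WH||^2 = ||X||^2 - 2 tr(W' X H') + tr(W'W HH'), no n x V temp
    cross <- sum(XHt * W)
    wh2 <- sum(crossprod(W) * HHt)
    err <- sqrt(max(x2 - 2 * cross + wh2, 0)) / sqrt(x2)
    trace <- c(trace, err)
    if (is.finite(prev) && prev > 0 && (prev - err) / prev < tol) break
    prev <- err
  }
  structure(list(scores = W, components = H, k = as.integer(k),
                 seed = as.integer(seed), error_trace = trace,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "nmf_model")
}

## NNDSVD initialisation (Boutsidis & Gallopoulos): split each SVD pair
## into its positive and negative parts and keep the dominant one. Zeros
## are lifted to a small multiple of the matrix mean so multiplicative
## updates can move them (the "a" variant).
nmf_init <- function(X, k, seed, init) {
  n <- nrow(X); V <- ncol(X)
  if (init == "random" || k > min(n, V) - 1 || min(n, V) < 2) {
    return(with_seed(seed, list(
      W = matrix(runif(n * k, 0.1, 1), n, k) * sqrt(mean(X) / k),
      H = matrix(runif(k * V, 0.1, 1), k, V) * sqrt(mean(X) / k))))
  }
  sv <- svd(X, nu = k, nv = k)
  W <- matrix(0, n, k); H <- matrix(0, k, V)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  lift <- mean(X) / 100 + 1e-9
  W[W < lift] <- lift
  H[H < lift] <- lift
  list(W = W, H = H)
}

#' Project new rows onto fitted NMF components
#'
#' Nonnegative least-squares scores for new data against frozen
#' `components`, by multiplicative updates on the scores only.
#'
#' @param model an `nmf_model`.
#' @param X new rows (m x V), nonnegative.
#' @param n_iter update iterations.
#' @return m x k score matrix.
#' @export
nmf_transform <- function(model, X, n_iter = 200) {
  if (inherits(X, "data_matrix")) X <- X$values
  H <- model$components
  eps <- 1e-10
  W <- matrix(mean(X) + eps, nrow(X), model$k)
  HHt <- tcrossprod(H)
  XHt <- X %*% t(H)
  for (i in seq_len(n_iter)) W <- W * XHt / (W %*% HHt + eps)
  W
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("nmf_model: rank %d, %d x %d, %d iterations, final rel. error %.4g\n",
              x$k, nrow(x$scores), ncol(x$components),
              length(x$error_trace), tail(x$error_trace, 1)))
  invisible(x)
}
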