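#' Multivariate partial least squares regression (SIMPLS)
#'
#' Fits `Y ~ X B` by the SIMPLS algorithm: latent directions are extracted
#' from the cross-product matrix `S = X'Y`, which is deflated against an
#' orthonormal basis of X-loadings after each component. SIMPLS handles the
#' regime this model lives in — many collinear predictors and far fewer
#' observations (p >> m) — where ordinary least squares is singular.
#'
#' By default no column centering or scaling is applied: the downstream
#' bilinear predictor is a pure quadratic form in the feature vectors, with
#' no intercept to absorb offsets. Centering is available for
#' experimentation via `center = TRUE`.
#'
#' @param X Predictor matrix (m x p).
#' @param Y Response matrix (m x r) or vector.
#' @param ncomp Number of latent factors L (>= 1). Capped at `min(m, p)`
#'   with a warning; extraction also stops early (with a warning) when the
#'   deflated cross-product matrix is numerically zero.
#' @param center Center columns of X and Y before fitting (default `FALSE`).
#' @param tol Relative tolerance declaring a deflated cross-product exhausted.
#' @return An object of class `simpls_fit` with elements `coefficients`
#'   (p x r), `n_components` (components actually extracted), `ncomp_requested`,
#'   `weights` (p x L), `y_loadings` (r x L), `x_means`, `y_means`,
#'   `center`, and `training_dims` (m, p, r).
#' @examples
#' X <- diag(3)
#' Y <- matrix(rnorm(6), 3, 2)
#' fit <- simpls_fit(X, Y, ncomp = 3)
#' all.equal(fit$coefficients, Y, check.attributes = FALSE)
#' @export
simpls_fit <- function(X, Y, ncomp, center = FALSE, tol = 1e-12) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have the same number of rows")
  if (length(ncomp) != 1L || is.na(ncomp) || ncomp < 1) abort("ncomp must be >= 1")
  if (all(X == 0)) abort("degenerate predictor: X is all-zero")
  m <- nrow(X); p <- ncol(X); r <- ncol(Y)

  x_means <- if (center) colMeans(X) else rep(0, p)
  y_means <- if (center) colMeans(Y) else rep(0, r)
  Xc <- sweep(X, 2L, x_means)
  Yc <- sweep(Y, 2L, y_means)

  cap <- min(m, p)
  if (ncomp > cap) {
    warn(sprintf("ncomp = %d exceeds min(m, p) = %d; capping", ncomp, cap))
    ncomp <- cap
  }

  S <- crossprod(Xc, Yc)                      # p x r cross-product
  s0 <- sqrt(sum(S^2))
  if (s0 == 0) abort("degenerate predictor: X'Y is zero, nothing to regress")

  W <- matrix(0, p, ncomp)                    # X-weights (the "R" matrix)
  Q <- matrix(0, r, ncomp)                    # Y-loadings
  V <- matrix(0, p, ncomp)                    # orthonormal basis for deflation
  a <- 0L
  for (k in seq_len(ncomp)) {
    if (sqrt(sum(S^2)) <= tol * s0) break
    ee <- eigen(crossprod(S), symmetric = TRUE)
    q <- ee$vectors[, 1L]
    w <- S %*% q                              # dominant left singular direction
    t <- Xc %*% w
    tn <- sqrt(sum(t^2))
    if (tn <= tol * s0) break
    t <- t / tn
    w <- w / tn
    p_load <- crossprod(Xc, t)
    q_load <- crossprod(Yc, t)
    v <- p_load
    if (a > 0L) {                             # re-orthogonalize twice for stability
      Va <- V[, seq_len(a), drop = FALSE]
      v <- v - Va %*% crossprod(Va, v)
      v <- v - Va %*% crossprod(Va, v)
    }
    vn <- sqrt(sum(v^2))
    if (vn <= tol * sqrt(sum(p_load^2))) break
    v <- v / vn
    S <- S - v %*% crossprod(v, S)
    a <- a + 1L
    W[, a] <- w
    Q[, a] <- q_load
    V[, a] <- v
  }
  if (a == 0L) abort("degenerate predictor: no latent factor could be extracted")
  if (a < ncomp) {
    warn(sprintf("cross-product matrix exhausted after %d component(s); requested %d",
                 a, ncomp))
  }
  W <- W[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]
  B <- W %*% t(Q)
  dimnames(B) <- list(colnames(X), colnames(Y))

  structure(
    list(
      coefficients = B,
      n_components = a,
      ncomp_requested = ncomp,
      weights = W,
      y_loadings = Q,
      x_means = x_means,
      y_means = y_means,
      center = center,
      training_dims = c(m = m, p = p, r = r)
    ),
    class = "simpls_fit"
  )
}

#' @export
predict.simpls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$coefficients)) {
    abort("newdata has wrong number of predictor columns")
  }
  Xc <- sweep(newdata, 2L, object$x_means)
  sweep(Xc %*% object$coefficients, 2L, object$y_means, `+`)
}

#' @export
print.simpls_fit <- function(x, ...) {
  d <- x$training_dims
  cat(sprintf("SIMPLS fit: %d observations, %d predictors, %d responses, %d component(s)%s\n",
              d["m"], d["p"], d["r"], x$n_components,
              if (x$center) " (centered)" else ""))
  invisible(x)
}
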