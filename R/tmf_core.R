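#' Low-rank PSD factorization of a signed interaction matrix
#'
#' Decomposes a symmetric adjacency matrix as `A ~ A_d A_d'` through its
#' eigendecomposition `A = U L U'`. Signed adjacency matrices are indefinite,
#' so a real Gram factor only exists on the positive part of the spectrum:
#' the factorization retains the `rank` largest strictly positive
#' eigenvalues and sets `A_d = U_r sqrt(L_r)`. Among Gram factorizations of
#' rank at most `rank`, this attains the minimal Frobenius reconstruction
#' error.
#'
#' @param A Symmetric numeric matrix (typically a signed interaction matrix,
#'   possibly pre-scaled).
#' @param rank `"auto"` (default) keeps every positive eigenvalue above
#'   `tol` times the largest, capped at `nrow(A) - 1`; an integer keeps at
#'   most that many leading positive eigenvalues.
#' @param tol Relative threshold under which a positive eigenvalue is
#'   treated as numerically zero.
#' @return An object of class `latent_factorization`: list with `values`
#'   (the m x r latent factor `A_d`), `eigen_values` (retained, descending),
#'   `eigen_vectors` (m x r), `rank`.
#' @examples
#' A <- rbind(c(0, 1), c(1, 0))
#' f <- factorize_interactions(A, rank = 1)
#' f$values %*% t(f$values)  # every entry 0.5
#' @export
factorize_interactions <- function(A, rank = "auto", tol = 1e-10) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) abort("interaction matrix must be square")
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A)))) {
    abort("interaction matrix must be symmetric")
  }
  m <- nrow(A)
  ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- ee$values > tol * max(abs(ee$values), tol)
  n_pos <- sum(pos)
  if (n_pos == 0L) abort("no latent structure: matrix has no positive eigenvalue")

  r <- if (identical(rank, "auto")) min(n_pos, m - 1L) else {
    if (!is.numeric(rank) || length(rank) != 1L || rank < 1 || rank > m) {
      abort("rank must be \"auto\" or an integer in [1, m]")
    }
    min(as.integer(rank), n_pos)
  }
  lam <- ee$values[seq_len(r)]
  U <- ee$vectors[, seq_len(r), drop = FALSE]
  rownames(U) <- rownames(A)
  structure(
    list(
      values = U %*% diag(sqrt(lam), r),
      eigen_values = lam,
      eigen_vectors = U,
      rank = r
    ),
    class = "latent_factorization"
  )
}

#' Fit the triple-matrix-factorization interaction model
#'
#' Couples a signed drug-drug interaction network to binary drug features
#' via the bilinear model `A ~ F Theta F'`, solved in three steps:
#' \enumerate{
#'   \item factorize the (scaled) adjacency into a latent interaction space,
#'     `A ~ A_d A_d'` ([factorize_interactions()]);
#'   \item regress the latent coordinates on the observed features,
#'     `A_d ~ F B`, by SIMPLS ([simpls_fit()]);
#'   \item form the symmetric feature projection `Theta = B B'`.
#' }
#' `Theta` is never materialized during fitting; predictions use the
#' factored form `(F_x B)(F_y B)'`, which is mathematically identical.
#'
#' @param A Signed interaction matrix (see [interaction_matrix()]).
#' @param F Binary feature matrix over the same drugs, in the same row order.
#' @param rank Latent rank passed to [factorize_interactions()].
#' @param ncomp Number of SIMPLS latent factors L.
#' @param scale_factor Multiplier applied to `A` before solving (default
#'   1000). With thousands of feature columns the entries of `Theta` are
#'   tiny; pre-scaling keeps them in a numerically comfortable range.
#'   Predictions scale linearly with it, so rankings and AUC/AUPR are
#'   unaffected.
#' @param binary If `TRUE`, fit on the binarized network ([binarize()])
#'   for conventional interaction prediction.
#' @return An object of class `tmfuf_fit`: list with `B` (p x r regression
#'   coefficients), `latent`, `plsr`, `F_train`, `drugs`, `feature_names`
#'   and `hyperparams`.
#' @seealso [predict_new_vs_known()], [predict_new_vs_new()], [get_theta()]
#' @export
fit_tmfuf <- function(A, F, rank = "auto", ncomp = 10, scale_factor = 1000,
                      binary = FALSE) {
  validate_interaction_matrix(A)
  if (nrow(F) != nrow(A)) abort("A and F must cover the same drugs")
  if (!is.null(rownames(A)) && !is.null(rownames(F)) &&
      !identical(rownames(A), rownames(F))) {
    abort("A and F must list drugs in the same order")
  }
  if (scale_factor <= 0) abort("scale_factor must be positive")
  if (binary) A <- binarize(A)

  latent <- factorize_interactions(A * scale_factor, rank = rank)
  plsr <- simpls_fit(F, latent$values, ncomp = ncomp)
  structure(
    list(
      B = plsr$coefficients,
      latent = latent,
      plsr = plsr,
      F_train = F,
      drugs = rownames(A) %||% as.character(seq_len(nrow(A))),
      feature_names = colnames(F) %||% as.character(seq_len(ncol(F))),
      hyperparams = list(rank = rank, rank_used = latent$rank, ncomp = ncomp,
                         scale_factor = scale_factor, binary = binary)
    ),
    class = "tmfuf_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score interactions between new drugs and the training drugs
#'
#' Evaluates the bilinear predictor `F_x Theta F'` for `u` new drugs against
#' the `m` training drugs. The sign of a score encodes the predicted
#' interaction type (positive enhancive, negative degressive); its magnitude
#' is the confidence.
#'
#' @param model A fitted `tmfuf_fit`.
#' @param F_x Binary feature matrix of the new drugs (u x p).
#' @return A u x m numeric score matrix (new drugs x training drugs).
#' @export
predict_new_vs_known <- function(model, F_x) {
  check_feature_dim(model, F_x)
  (as.matrix(F_x) %*% model$B) %*% t(model$F_train %*% model$B)
}

#' Score interactions among new drugs
#'
#' Evaluates `F_x Theta F_y'` for two sets of new drugs. With
#' `F_y = F_x` the result is symmetric; the diagonal (self-pairs) carries no
#' meaning and should be ignored.
#'
#' @inheritParams predict_new_vs_known
#' @param F_y Binary feature matrix of the second set of new drugs (v x p);
#'   defaults to `F_x`.
#' @return A u x v numeric score matrix.
#' @export
predict_new_vs_new <- function(model, F_x, F_y = F_x) {
  check_feature_dim(model, F_x)
  check_feature_dim(model, F_y)
  (as.matrix(F_x) %*% model$B) %*% t(as.matrix(F_y) %*% model$B)
}

check_feature_dim <- function(model, F_x) {
  if (ncol(F_x) != nrow(model$B)) {
    abort(sprintf("feature dimension mismatch: model has p = %d, input has %d",
                  nrow(model$B), ncol(F_x)))
  }
  invisible(TRUE)
}

#' Materialize the feature projection matrix
#'
#' Forms `Theta = B B'` explicitly (p x p). For large feature vocabularies
#' prefer the streaming access used by [significant_pairs()] and
#' [summarize_theta()].
#'
#' @param model A fitted `tmfuf_fit`.
#' @return A symmetric p x p matrix with feature names as dimnames.
#' @export
get_theta <- function(model) {
  Theta <- tcrossprod(model$B)
  dimnames(Theta) <- list(model$feature_names, model$feature_names)
  Theta
}

#' Training reconstruction error of a fitted model
#'
#' Frobenius norm of `A_scaled - F Theta F'` over off-diagonal entries
#' (self-pairs are not interactions and are excluded).
#'
#' @param model A fitted `tmfuf_fit`.
#' @param A Signed interaction matrix on the training drugs.
#' @return A non-negative scalar.
#' @export
reconstruction_error <- function(model, A) {
  validate_interaction_matrix(A)
  if (nrow(A) != nrow(model$F_train)) abort("dimension mismatch between A and the model")
  if (model$hyperparams$binary) A <- binarize(A)
  S <- predict_new_vs_new(model, model$F_train)
  R <- A * model$hyperparams$scale_factor - S
  diag(R) <- 0
  sqrt(sum(R^2))
}

#' @export
print.tmfuf_fit <- function(x, ...) {
  h <- x$hyperparams
  cat(sprintf(paste0(
    "Triple-matrix-factorization interaction model\n",
    "  drugs: %d, features: %d\n",
    "  latent rank: %d (requested %s), SIMPLS components: %d (used %d)\n",
    "  scale factor: %g, network: %s\n"),
    length(x$drugs), length(x$feature_names),
    h$rank_used, as.character(h$rank), h$ncomp, x$plsr$n_components,
    h$scale_factor, if (h$binary) "binary" else "signed"))
  invisible(x)
}
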