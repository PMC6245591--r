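test_that("factorize_interactions reproduces hand-computed eigendecompositions", {
  f1 <- factorize_interactions(diag(2), rank = 2)
  expect_equal(tcrossprod(f1$values), diag(2), tolerance = 1e-12)

  A <- rbind(c(0, 1), c(1, 0))
  f2 <- factorize_interactions(A, rank = 1)
  expect_equal(abs(as.vector(f2$values)), c(sqrt(0.5), sqrt(0.5)), tolerance = 1e-10)
  expect_equal(tcrossprod(f2$values), matrix(0.5, 2, 2), tolerance = 1e-10)
  expect_equal(sqrt(sum((A - tcrossprod(f2$values))^2)), 1.0, tolerance = 1e-10)

  A3 <- matrix(1, 3, 3) - diag(3)  # eigenvalues 2, -1, -1
  f3 <- factorize_interactions(A3, rank = 1)
  expect_equal(tcrossprod(f3$values), matrix(2 / 3, 3, 3), tolerance = 1e-10)
  expect_equal(f3$eigen_values, 2, tolerance = 1e-10)
})

test_that("factorization rejects asymmetric and structureless matrices", {
  expect_error(factorize_interactions(rbind(c(0, 1), c(0, 0))), "symmetric")
  expect_error(factorize_interactions(matrix(0, 3, 3)), "no latent structure")
  expect_error(factorize_interactions(-diag(2)), "no latent structure")
  expect_error(factorize_interactions(diag(3), rank = 5), "rank")
  expect_error(factorize_interactions(diag(3), rank = 0), "rank")
})

test_that("factorization attains the optimal PSD rank-r Frobenius error", {
  set.seed(11)
  for (i in 1:25) {
    A <- matrix(sample(c(-1, 0, 1), 16, replace = TRUE), 4, 4)
    A <- sign(A + t(A))
    diag(A) <- 0
    if (max(eigen(A, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) next
    for (r in 1:3) {
      f <- factorize_interactions(A, rank = r)
      err <- sqrt(sum((A - tcrossprod(f$values))^2))
      expect_lte(err, oracle_psd_rank_r_error(A, r) + 1e-9)
    }
  }
})

test_that("the fitted projection matrix is symmetric positive semidefinite", {
  fit <- planted()$fit
  Theta <- get_theta(fit)
  expect_equal(Theta, t(Theta), tolerance = 1e-12)
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  # projection equals B B' by construction
  expect_equal(unname(Theta), unname(tcrossprod(fit$B)), tolerance = 1e-12)
})

test_that("bilinear predictors evaluate the projection matrix correctly", {
  # forged model with known coefficients: scores are exactly F_x Theta F_y'
  set.seed(12)
  p <- 6
  B <- matrix(rnorm(p * 2), p, 2, dimnames = list(paste0("f", 1:p), NULL))
  F_train <- diag(p); rownames(F_train) <- paste0("d", 1:p)
  model <- forge_model(B, F_train)
  Theta <- get_theta(model)

  # unit feature rows pick single projection entries
  e2 <- matrix(0, 1, p); e2[2] <- 1
  e5 <- matrix(0, 1, p); e5[5] <- 1
  expect_equal(as.numeric(predict_new_vs_new(model, e2, e5)), Theta[2, 5])

  # zero projection -> all scores zero
  null_model <- forge_model(B * 0, F_train)
  expect_true(all(predict_new_vs_known(null_model, e2) == 0))

  # identity projection counts co-occurring features
  id_model <- forge_model(diag(p), F_train)
  Fx <- matrix(rbinom(3 * p, 1, 0.5), 3, p)
  Fy <- matrix(rbinom(2 * p, 1, 0.5), 2, p)
  expect_equal(predict_new_vs_new(id_model, Fx, Fy), Fx %*% t(Fy))

  # role symmetry
  expect_equal(predict_new_vs_new(model, Fx, Fy),
               t(predict_new_vs_new(model, Fy, Fx)), tolerance = 1e-12)
  S <- predict_new_vs_new(model, Fx, Fx)
  expect_equal(S, t(S), tolerance = 1e-12)

  expect_error(predict_new_vs_known(model, Fx[, 1:3]), "dimension mismatch")
})

test_that("training predictions and reconstruction error share one code path", {
  pl <- planted()
  fit <- pl$fit
  S1 <- predict_new_vs_known(fit, fit$F_train)
  S2 <- predict_new_vs_new(fit, fit$F_train)
  expect_equal(S1, S2, tolerance = 1e-10)
  R <- pl$ds$A * fit$hyperparams$scale_factor - S2
  diag(R) <- 0
  expect_equal(reconstruction_error(fit, pl$ds$A), sqrt(sum(R^2)), tolerance = 1e-10)
})

test_that("scale factor covaries linearly and leaves rankings unchanged", {
  ds <- generate_synth(synth_config(m = 30, p = 40, seed = 5))
  f1 <- suppressWarnings(fit_tmfuf(ds$A, ds$F, rank = 3, ncomp = 8, scale_factor = 1))
  f1000 <- suppressWarnings(fit_tmfuf(ds$A, ds$F, rank = 3, ncomp = 8, scale_factor = 1000))
  expect_equal(get_theta(f1000), 1000 * get_theta(f1), tolerance = 1e-6)
  s1 <- predict_new_vs_new(f1, ds$F)
  s1000 <- predict_new_vs_new(f1000, ds$F)
  expect_equal(s1000, 1000 * s1, tolerance = 1e-6)
  ut <- upper.tri(s1)
  lab <- ds$A[ut]
  expect_equal(score_comprehensive(lab, s1[ut])$auc,
               score_comprehensive(lab, s1000[ut])$auc)
})

test_that("reconstruction error behaves as a norm and vanishes on exact fits", {
  ds <- generate_synth(synth_config(m = 20, p = 30, seed = 8))
  fit <- suppressWarnings(fit_tmfuf(ds$A, ds$F, ncomp = 5))
  err <- reconstruction_error(fit, ds$A)
  expect_gte(err, 0)

  # null projection: error equals the norm of the scaled adjacency
  null_model <- forge_model(matrix(0, ncol(ds$F), 1), ds$F, scale_factor = 1000)
  expect_equal(reconstruction_error(null_model, ds$A),
               sqrt(sum((ds$A * 1000)^2)), tolerance = 1e-10)

  # with an identity feature matrix the regression interpolates exactly, so
  # the only residual is the spectral truncation of the adjacency itself
  A <- ds$A
  F_id <- diag(nrow(A)); dimnames(F_id) <- list(rownames(A), rownames(A))
  fid <- suppressWarnings(fit_tmfuf(A, F_id, rank = "auto", ncomp = nrow(A),
                                    scale_factor = 1))
  ee <- eigen(A, symmetric = TRUE)
  pos <- ee$values > 1e-10 * max(abs(ee$values))
  recon <- ee$vectors[, pos, drop = FALSE] %*%
    (ee$values[pos] * t(ee$vectors[, pos, drop = FALSE]))
  R <- A - recon; diag(R) <- 0
  expect_equal(reconstruction_error(fid, A), sqrt(sum(R^2)), tolerance = 1e-6)
})

test_that("fitting degenerate networks fails with a clear message", {
  F <- matrix(rbinom(30, 1, 0.5), 5, 6)
  A0 <- matrix(0L, 5, 5)
  expect_error(suppressWarnings(fit_tmfuf(A0, F)), "no latent structure")
})
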