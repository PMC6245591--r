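#' Configuration for the synthetic interaction benchmark
#'
#' Describes a drug universe with planted bilinear structure: binary feature
#' profiles, a sparse signed true projection matrix, and a signed
#' interaction network obtained by thresholding the true bilinear scores.
#' The defaults mimic the statistical shape of curated comprehensive
#' interaction networks: sparse, with an enhancive majority (the default
#' enhancive fraction 0.776 matches the 18710:5404 enhancive:degressive
#' ratio of the published network the model was developed on).
#'
#' @param m Number of drugs (>= 4).
#' @param p Number of binary feature entries.
#' @param r_true Planted latent rank (`r_true < min(m, p)`).
#' @param feature_density Expected fraction of 1s in the feature matrix.
#' @param interaction_density Expected fraction of nonzero off-diagonal
#'   entries in the interaction matrix.
#' @param enhancive_fraction Expected fraction of interactions that are
#'   enhancive (+1).
#' @param label_noise Probability each pair's label is resampled uniformly
#'   from \{-1, 0, +1\}.
#' @param b_density Fraction of nonzero entries in the planted coefficient
#'   matrix; sparse coefficients give the true projection matrix a heavy
#'   near-zero mode with a few strong feature pairs.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(m = 60, p = 80, r_true = 3, feature_density = 0.15,
                         interaction_density = 0.12,
                         enhancive_fraction = 0.776, label_noise = 0,
                         b_density = 0.1, seed = 1) {
  probs <- c(feature_density = feature_density,
             interaction_density = interaction_density,
             enhancive_fraction = enhancive_fraction,
             label_noise = label_noise, b_density = b_density)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (m < 4) abort("m must be >= 4")
  if (r_true >= min(m, p) || r_true < 1) abort("r_true must satisfy 1 <= r_true < min(m, p)")
  structure(
    list(m = as.integer(m), p = as.integer(p), r_true = as.integer(r_true),
         feature_density = feature_density,
         interaction_density = interaction_density,
         enhancive_fraction = enhancive_fraction,
         label_noise = label_noise, b_density = b_density,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic drug universe with planted bilinear structure
#'
#' Draws `F ~ Bernoulli(feature_density)`, a sparse signed coefficient
#' matrix `B_true` (signs +/-1, magnitudes uniform in \[0.5, 1.5\]), forms
#' raw scores `S = F B_true B_true' F'`, and thresholds the off-diagonal
#' scores at two empirical quantiles chosen so the realized interaction
#' density and enhancive fraction match the request: the top scores become
#' +1, the bottom scores -1, the middle 0 (ties broken deterministically by
#' score order). Labels are then symmetrized, the diagonal zeroed, and
#' optional label noise resamples each pair uniformly from \{-1, 0, +1\}.
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_dataset`: list with `A` (signed
#'   interaction matrix), `F` (binary feature matrix), `B_true`,
#'   `theta_true = B_true B_true'`, `thresholds` (lower, upper score
#'   cutoffs), `config`.
#' @export
generate_synth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  m <- config$m; p <- config$p; r_true <- config$r_true
  local_seed(config$seed, {
    drugs <- sprintf("d%03d", seq_len(m))
    feats <- sprintf("se%04d", seq_len(p))
    F <- matrix(rbinom(m * p, 1L, config$feature_density), m, p,
                dimnames = list(drugs, feats))
    storage.mode(F) <- "integer"

    mask <- rbinom(p * r_true, 1L, config$b_density)
    signs <- sample(c(-1, 1), p * r_true, replace = TRUE)
    mags <- runif(p * r_true, 0.5, 1.5)
    B_true <- matrix(mask * signs * mags, p, r_true,
                     dimnames = list(feats, NULL))

    G <- F %*% B_true
    S <- tcrossprod(G)
    ut <- which(upper.tri(S))
    s <- S[ut]
    n_pairs <- length(s)
    k_tot <- round(config$interaction_density * n_pairs)
    k_up <- round(k_tot * config$enhancive_fraction)
    k_dn <- k_tot - k_up
    if (k_tot < 1 && config$label_noise == 0) {
      abort("degenerate config: no interaction would be generated")
    }
    if (min(s) == max(s) && k_tot >= 1) {
      abort("degenerate config: planted scores are constant, cannot threshold")
    }
    labels <- integer(n_pairs)
    if (k_up > 0) labels[order(s, decreasing = TRUE)[seq_len(k_up)]] <- 1L
    if (k_dn > 0) labels[order(s)[seq_len(k_dn)]] <- -1L
    thr <- c(lower = if (k_dn > 0) sort(s)[k_dn] else -Inf,
             upper = if (k_up > 0) sort(s, decreasing = TRUE)[k_up] else Inf)

    flip <- runif(n_pairs) < config$label_noise
    if (any(flip)) labels[flip] <- sample(c(-1L, 0L, 1L), sum(flip), replace = TRUE)

    A <- matrix(0L, m, m, dimnames = list(drugs, drugs))
    A[ut] <- labels
    A <- A + t(A)
    if (all(A == 0)) abort("degenerate config: generated network is empty")

    structure(
      list(A = A, F = F, B_true = B_true, theta_true = tcrossprod(B_true),
           thresholds = thr, config = config),
      class = "synth_dataset"
    )
  })
}

#' Recovery diagnostics of a fitted model against the planted truth
#'
#' Compares a fitted model with the generating structure of a synthetic
#' dataset:
#' \describe{
#'   \item{theta_correlation}{Pearson correlation between the upper
#'     triangles (diagonal included) of the planted and fitted projection
#'     matrices. Scale-invariant, so the fit's `scale_factor` is irrelevant.
#'     `NA` when the fitted projection is constant.}
#'   \item{sign_agreement}{Fraction of interacting training pairs whose
#'     predicted type matches the true sign. A non-negative score is called
#'     enhancive, so an uninformative all-zero model falls back to the
#'     majority (+1) call rather than matching nothing.}
#'   \item{heldout_auc}{Comprehensive AUC of new-vs-known predictions for
#'     `test_drugs` against the remaining drugs (`NA` when no test drugs
#'     are designated).}
#' }
#'
#' @param dataset A `synth_dataset` from [generate_synth()].
#' @param model A `tmfuf_fit` trained on the dataset's drugs minus
#'   `test_drugs` (or on all drugs when `test_drugs` is `NULL`).
#' @param test_drugs Integer indices (or drug ids) of drugs held out from
#'   training, or `NULL`.
#' @return A one-row tibble with `theta_correlation`, `sign_agreement`,
#'   `heldout_auc`.
#' @export
recovery_report <- function(dataset, model, test_drugs = NULL) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (nrow(model$B) != ncol(dataset$F)) {
    abort("dimension mismatch between model and dataset features")
  }
  theta_fit <- get_theta(model)
  tt <- upper_entries(dataset$theta_true, diag = TRUE)
  tf <- upper_entries(theta_fit, diag = TRUE)
  theta_cor <- if (stats::sd(tf) == 0 || stats::sd(tt) == 0) NA_real_ else cor(tt, tf)

  m <- nrow(dataset$A)
  if (is.character(test_drugs)) test_drugs <- match(test_drugs, rownames(dataset$A))
  train <- if (is.null(test_drugs)) seq_len(m) else setdiff(seq_len(m), test_drugs)

  F_tr <- dataset$F[train, , drop = FALSE]
  S_tr <- predict_new_vs_new(model, F_tr)
  A_tr <- dataset$A[train, train, drop = FALSE]
  nz <- upper.tri(A_tr) & A_tr != 0
  sign_agree <- if (!any(nz)) NA_real_ else {
    mean(ifelse(S_tr[nz] >= 0, 1L, -1L) == A_tr[nz])
  }

  heldout_auc <- NA_real_
  if (!is.null(test_drugs) && length(test_drugs) > 0) {
    P <- predict_new_vs_known(model, dataset$F[test_drugs, , drop = FALSE])
    L <- dataset$A[test_drugs, train, drop = FALSE]
    if (ncol(P) != length(train)) abort("model training drugs do not match test_drugs complement")
    heldout_auc <- score_comprehensive(as.vector(L), as.vector(P))$auc
  }
  tibble::tibble(theta_correlation = theta_cor, sign_agreement = sign_agree,
                 heldout_auc = heldout_auc)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `edges.tsv`, `F.mtx` + `features.txt` + `drugs.txt`, and
#' `truth.json` (planted coefficients, thresholds, configuration) into a
#' directory.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_synth <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_interactions(dataset$A, file.path(dir, "edges.tsv"))
  write_feature_matrix(dataset$F, dir)
  truth <- list(
    B_true = unname(as.data.frame(dataset$B_true)),
    thresholds = as.list(dataset$thresholds),
    config = unclass(dataset$config)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' @export
print.synth_dataset <- function(x, ...) {
  st <- network_stats(x$A)
  cat(sprintf(paste0(
    "synthetic drug universe: %d drugs, %d features, planted rank %d\n",
    "  %d interactions (%d enhancive, %d degressive), label noise %.2f\n"),
    x$config$m, x$config$p, x$config$r_true,
    st$n_interactions, st$n_enhancive, st$n_degressive, x$config$label_noise))
  invisible(x)
}
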