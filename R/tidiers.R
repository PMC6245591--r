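#' Tidy a fitted interaction model
#'
#' Returns the SIMPLS regression coefficients in long form: one row per
#' (feature, latent dimension) pair.
#'
#' @param x A `tmfuf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `latent`, `estimate`.
#' @export
tidy.tmfuf_fit <- function(x, ...) {
  B <- x$B
  tibble::tibble(
    feature = rep(x$feature_names, times = ncol(B)),
    latent = rep(seq_len(ncol(B)), each = nrow(B)),
    estimate = as.vector(B)
  )
}

#' @rdname tidy.tmfuf_fit
#' @export
glance.tmfuf_fit <- function(x, ...) {
  h <- x$hyperparams
  tibble::tibble(
    n_drugs = length(x$drugs),
    n_features = length(x$feature_names),
    latent_rank = h$rank_used,
    n_components = x$plsr$n_components,
    scale_factor = h$scale_factor,
    binary_mode = h$binary
  )
}

#' Tidy an evaluation result
#'
#' Returns the ROC and PR curve points in long form.
#'
#' @param x A `ddi_eval` from [score_binary()] or [score_comprehensive()].
#' @param ... Unused.
#' @return A tibble with columns `curve` (`"roc"`/`"pr"`), `threshold`,
#'   `x`, `y` (fpr/tpr for ROC, recall/precision for PR).
#' @export
tidy.ddi_eval <- function(x, ...) {
  roc <- tibble::tibble(curve = "roc", threshold = x$roc$threshold)
  roc$x <- x$roc$fpr
  roc$y <- x$roc$tpr
  pr <- tibble::tibble(curve = "pr", threshold = x$pr$threshold)
  pr$x <- x$pr$recall
  pr$y <- x$pr$precision
  dplyr::bind_rows(roc, pr)
}

#' @rdname tidy.ddi_eval
#' @export
glance.ddi_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, aupr = x$aupr, n_pos = x$n_pos,
                 n_neg = x$n_neg, protocol = x$protocol)
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [run_cv()].
#' @param ... Unused.
#' @return The per-round tibble (`tidy`) or a one-row aggregate (`glance`).
#' @export
tidy.cv_result <- function(x, ...) x$rounds

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, protocol = x$protocol, K = x$K,
                 auc = x$auc, aupr = x$aupr,
                 n_rounds_scored = x$n_rounds_scored,
                 n_rounds = nrow(x$rounds))
}

#' @rdname tidy.cv_result
#' @export
tidy.cv_repeat_result <- function(x, ...) x$repeats

#' @rdname tidy.cv_result
#' @export
glance.cv_repeat_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, protocol = x$protocol, K = x$K,
                 repeats = nrow(x$repeats),
                 auc_mean = x$auc_mean, auc_sd = x$auc_sd, auc_sem = x$auc_sem,
                 aupr_mean = x$aupr_mean, aupr_sd = x$aupr_sd,
                 aupr_sem = x$aupr_sem)
}

#' Tidy a latent-factor tuning result
#'
#' @param x A `tmfuf_tuning` from [tune_latent_factors()].
#' @param ... Unused.
#' @return The per-L tibble (`tidy`) or the best row (`glance`).
#' @export
tidy.tmfuf_tuning <- function(x, ...) x$results

#' @rdname tidy.tmfuf_tuning
#' @export
glance.tmfuf_tuning <- function(x, ...) {
  dplyr::filter(x$results, .data$ncomp == x$best_ncomp) |>
    dplyr::rename(best_ncomp = "ncomp")
}

#' Tidy a projection-matrix summary
#'
#' @param x A `theta_summary` from [summarize_theta()].
#' @param ... Unused.
#' @return The histogram tibble (`tidy`) or a one-row summary (`glance`).
#' @export
tidy.theta_summary <- function(x, ...) x$histogram

#' @rdname tidy.theta_summary
#' @export
glance.theta_summary <- function(x, ...) {
  tibble::tibble(n_entries = x$n_entries, threshold = x$threshold,
                 n_significant_positive = x$n_significant_positive,
                 n_significant_negative = x$n_significant_negative,
                 scale_factor = x$scale_factor)
}
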