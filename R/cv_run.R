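#' Run a cold-start cross-validation experiment
#'
#' For each round of the plan the model is refitted on the training-pair
#' submatrix only, test pairs are scored with the bilinear predictor
#' (new-vs-known for CV1 rounds; new-vs-new for CV2, using one group against
#' itself off-diagonal in within-group rounds), and AUC/AUPR are computed
#' under the requested protocol. The aggregate is the mean over scored
#' rounds. Rounds whose test block lacks a positive (or negative) sample
#' are skipped with a warning and excluded from the mean; so are rounds
#' whose training submatrix is all zero.
#'
#' @param A Signed interaction matrix.
#' @param F Binary feature matrix, same drugs and order as `A`.
#' @param plan A `cv_plan` from [make_cv1_plan()] or [make_cv2_plan()].
#' @param protocol `"comprehensive"` scores the signed network via
#'   [score_comprehensive()]; `"conventional"` binarizes the network and
#'   scores via [score_binary()]. The per-round model is trained on the
#'   matching (signed or binarized) network.
#' @param rank,ncomp,scale_factor Hyperparameters passed to [fit_tmfuf()],
#'   shared by every round.
#' @return An object of class `cv_result`: list with `auc`, `aupr`
#'   (means over scored rounds), `rounds` (per-round tibble), `protocol`,
#'   `scheme`, `K`, `seed`, `n_rounds_scored`.
#' @export
run_cv <- function(A, F, plan,
                   protocol = c("comprehensive", "conventional"),
                   rank = "auto", ncomp = 10, scale_factor = 1000) {
  protocol <- match.arg(protocol)
  validate_interaction_matrix(A)
  if (nrow(F) != nrow(A)) abort("A and F must cover the same drugs")
  if (plan$m != nrow(A)) abort("plan was built for a different number of drugs")
  A_use <- if (protocol == "conventional") binarize(A) else A

  rows <- purrr::imap(plan$rounds, function(rd, i) {
    tr <- rd$train
    res <- list(auc = NA_real_, aupr = NA_real_, n_pos = NA_integer_,
                n_neg = NA_integer_, skipped = TRUE, reason = "")
    A_tr <- A_use[tr, tr, drop = FALSE]
    if (all(A_tr == 0)) {
      warn(sprintf("round %d skipped: training submatrix has no interaction", i))
      res$reason <- "empty training network"
    } else {
      fit <- fit_tmfuf(A_tr, F[tr, , drop = FALSE], rank = rank, ncomp = ncomp,
                       scale_factor = scale_factor,
                       binary = (protocol == "conventional"))
      ls <- round_test_scores(fit, A_use, F, rd)
      n_pos <- sum(ls$labels != 0)
      n_neg <- sum(ls$labels == 0)
      if (n_pos < 1 || n_neg < 1) {
        warn(sprintf("round %d skipped: test block lacks a %s sample", i,
                     if (n_pos < 1) "positive" else "negative"))
        res$reason <- "single-class test block"
        res$n_pos <- n_pos; res$n_neg <- n_neg
      } else {
        ev <- if (protocol == "comprehensive") {
          score_comprehensive(ls$labels, ls$scores)
        } else {
          score_binary(ls$labels, ls$scores)
        }
        res <- list(auc = ev$auc, aupr = ev$aupr, n_pos = ev$n_pos,
                    n_neg = ev$n_neg, skipped = FALSE, reason = "")
      }
    }
    tibble::tibble(
      round = i, kind = rd$kind, n_train = length(tr),
      n_test_pairs = res$n_pos + res$n_neg,
      n_pos = res$n_pos, n_neg = res$n_neg,
      auc = res$auc, aupr = res$aupr,
      skipped = res$skipped, reason = res$reason
    )
  })
  rounds <- dplyr::bind_rows(rows)
  scored <- dplyr::filter(rounds, !.data$skipped)
  if (nrow(scored) == 0L) abort("no round produced a defined metric")

  structure(
    list(
      auc = mean(scored$auc),
      aupr = mean(scored$aupr),
      rounds = rounds,
      protocol = protocol,
      scheme = plan$scheme,
      K = plan$K,
      seed = plan$seed,
      n_rounds_scored = nrow(scored)
    ),
    class = "cv_result"
  )
}

# Labels and scores of one round's test block (each unordered pair once).
round_test_scores <- function(fit, A_use, F, rd) {
  a <- rd$test_a
  if (identical(rd$kind, "cv1")) {
    P <- predict_new_vs_known(fit, F[a, , drop = FALSE])
    L <- A_use[a, rd$train, drop = FALSE]
    list(labels = as.vector(L), scores = as.vector(P))
  } else if (identical(rd$kind, "within")) {
    P <- predict_new_vs_new(fit, F[a, , drop = FALSE])
    L <- A_use[a, a, drop = FALSE]
    ut <- upper.tri(P)
    list(labels = L[ut], scores = P[ut])
  } else {
    b <- rd$test_b
    P <- predict_new_vs_new(fit, F[a, , drop = FALSE], F[b, , drop = FALSE])
    L <- A_use[a, b, drop = FALSE]
    list(labels = as.vector(L), scores = as.vector(P))
  }
}

#' Repeat cross-validation under multiple random partitions
#'
#' Rebuilds the fold partition under `repeats` seeds derived from the master
#' seed, reruns the experiment, and reports the per-repeat aggregates along
#' with their mean, standard deviation and standard error.
#'
#' @inheritParams run_cv
#' @param scheme `"cv1"` or `"cv2"`.
#' @param K Fold count.
#' @param repeats Number of repetitions.
#' @param seed Master seed; per-repeat partition seeds are drawn from it.
#' @return An object of class `cv_repeat_result`: list with `repeats`
#'   (tibble: repeat_, seed, auc, aupr), `auc_mean`, `auc_sd`, `auc_sem`,
#'   `aupr_mean`, `aupr_sd`, `aupr_sem`, plus the experiment settings.
#' @export
run_cv_repeated <- function(A, F, scheme = c("cv1", "cv2"), K = 10,
                            repeats = 50, seed = 1,
                            protocol = c("comprehensive", "conventional"),
                            rank = "auto", ncomp = 10, scale_factor = 1000) {
  scheme <- match.arg(scheme)
  protocol <- match.arg(protocol)
  seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1L, repeats))
  maker <- if (scheme == "cv1") make_cv1_plan else make_cv2_plan
  per <- purrr::map2(seq_len(repeats), seeds, function(i, s) {
    plan <- maker(nrow(A), K, s)
    r <- run_cv(A, F, plan, protocol = protocol, rank = rank, ncomp = ncomp,
                scale_factor = scale_factor)
    tibble::tibble(repeat_ = i, seed = s, auc = r$auc, aupr = r$aupr)
  })
  reps <- dplyr::bind_rows(per)
  structure(
    list(
      repeats = reps,
      auc_mean = mean(reps$auc), auc_sd = stats::sd(reps$auc),
      auc_sem = stats::sd(reps$auc) / sqrt(nrow(reps)),
      aupr_mean = mean(reps$aupr), aupr_sd = stats::sd(reps$aupr),
      aupr_sem = stats::sd(reps$aupr) / sqrt(nrow(reps)),
      scheme = scheme, K = K, protocol = protocol, seed = seed
    ),
    class = "cv_repeat_result"
  )
}

#' Tune the number of SIMPLS latent factors
#'
#' Runs conventional (binary-protocol) CV1 for each candidate L and selects
#' the one maximizing mean AUC; ties go to the smallest L. This mirrors how
#' the latent-factor count — the model's single tunable parameter — is
#' chosen on the new-vs-known screening task.
#'
#' @inheritParams run_cv
#' @param grid Candidate values of L; the customary grid is
#'   `c(1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 150)`.
#' @param K Fold count for the internal CV1.
#' @param seed Seed for the fold partition (shared across the grid so every
#'   L sees identical folds).
#' @return An object of class `tmfuf_tuning`: list with `best_ncomp` and
#'   `results` (tibble: ncomp, auc, aupr).
#' @export
tune_latent_factors <- function(A, F, grid = c(1, 5, 10, 20, 30, 40, 50, 60,
                                               70, 80, 90, 100, 150),
                                K = 10, seed = 1, rank = "auto",
                                scale_factor = 1000) {
  if (length(grid) < 1) abort("grid must be non-empty")
  grid <- sort(unique(as.integer(grid)))
  plan <- make_cv1_plan(nrow(A), K, seed)
  results <- purrr::map(grid, function(L) {
    r <- run_cv(A, F, plan, protocol = "conventional", rank = rank,
                ncomp = L, scale_factor = scale_factor)
    tibble::tibble(ncomp = L, auc = r$auc, aupr = r$aupr)
  }) |> dplyr::bind_rows()
  structure(
    list(best_ncomp = results$ncomp[which.max(results$auc)], results = results,
         K = K, seed = seed),
    class = "tmfuf_tuning"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s %s cross-validation (K = %d): mean AUC = %.4f, mean AUPR = %.4f over %d/%d round(s)\n",
              toupper(x$scheme), x$protocol, x$K, x$auc, x$aupr,
              x$n_rounds_scored, nrow(x$rounds)))
  invisible(x)
}

#' @export
print.cv_repeat_result <- function(x, ...) {
  cat(sprintf("%s %s CV, %d repeats: AUC = %.4f +/- %.4f (SD), AUPR = %.4f +/- %.4f (SD)\n",
              toupper(x$scheme), x$protocol, nrow(x$repeats),
              x$auc_mean, x$auc_sd, x$aupr_mean, x$aupr_sd))
  invisible(x)
}

#' @export
print.tmfuf_tuning <- function(x, ...) {
  cat(sprintf("latent-factor tuning over {%s}: best L = %d\n",
              paste(x$results$ncomp, collapse = ","), x$best_ncomp))
  invisible(x)
}
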