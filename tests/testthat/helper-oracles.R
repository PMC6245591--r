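# Independent oracles and small fixture builders shared across tests.

# O(n^2) pairwise-comparison AUC: every (positive, negative) pair contributes
# 1 if ranked correctly, 1/2 on a tie.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force AUPR: enumerate every distinct score as a threshold (ties enter
# together), accumulate precision x recall-increment.
oracle_aupr <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Best achievable Frobenius error of a PSD rank-<=r Gram approximation,
# searched over all subsets of non-negative eigenvalues of size <= r.
oracle_psd_rank_r_error <- function(A, r) {
  ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keepable <- which(ee$values > 0)
  best <- sqrt(sum(A^2))  # empty subset: approximate by zero
  if (length(keepable) > 0) {
    for (k in seq_len(min(r, length(keepable)))) {
      for (subset in utils::combn(keepable, k, simplify = FALSE)) {
        U <- ee$vectors[, subset, drop = FALSE]
        approx <- U %*% diag(ee$values[subset], k) %*% t(U)
        best <- min(best, sqrt(sum((A - approx)^2)))
      }
    }
  }
  best
}

# Least-squares oracle via the normal equations (full-column-rank X only).
oracle_ols <- function(X, Y) solve(crossprod(X), crossprod(X, Y))

# Construct a model object with a prescribed coefficient matrix, bypassing
# fitting; used to probe prediction/significance code paths directly.
forge_model <- function(B, F_train, scale_factor = 1000, binary = FALSE) {
  structure(
    list(
      B = B,
      F_train = F_train,
      drugs = rownames(F_train) %||% as.character(seq_len(nrow(F_train))),
      feature_names = rownames(B) %||% colnames(F_train) %||%
        as.character(seq_len(nrow(B))),
      hyperparams = list(rank = "forged", rank_used = ncol(B), ncomp = ncol(B),
                         scale_factor = scale_factor, binary = binary)
    ),
    class = "tmfuf_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The planted benchmark instance used across recovery tests (computed once).
planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_synth(synth_config(seed = 1))
      fit <- suppressWarnings(fit_tmfuf(ds$A, ds$F, rank = 3, ncomp = 20))
      cache <<- list(ds = ds, fit = fit)
    }
    cache
  }
})

tiny_edges <- function() {
  tibble::tibble(drug_a = c("d1", "d2"), drug_b = c("d2", "d3"),
                 type = c(1L, -1L))
}
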