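test_that("plans contain the right number and shape of rounds", {
  expect_length(make_cv1_plan(60, 10, 1)$rounds, 10)
  expect_length(make_cv2_plan(60, 10, 1)$rounds, 55)
  expect_length(make_cv1_plan(9, 3, 1)$rounds, 3)
  expect_length(make_cv2_plan(9, 3, 1)$rounds, 6)

  plan <- make_cv1_plan(9, 3, 2)
  for (rd in plan$rounds) {
    expect_length(rd$train, 6)
    expect_length(rd$test_a, 3)
    expect_equal(nrow(cv_round_pairs(rd, 9)$test_pairs), 18)
  }
  expect_error(make_cv1_plan(3, 5, 1), "at least K")
})

test_that("every round's train/test/blind pair sets partition all pairs", {
  for (K in 2:5) {
    for (m in c(K + 1, 2 * K + 3, 30)) {
      for (maker in list(make_cv1_plan, make_cv2_plan)) {
        plan <- maker(m, K, seed = K * 100 + m)
        all_keys <- sort((function(p) (p[, 1] - 1) * m + p[, 2])(
          t(utils::combn(m, 2))))
        for (rd in plan$rounds) {
          ps <- cv_round_pairs(rd, m)
          keys <- lapply(ps, function(p) if (nrow(p)) (p[, 1] - 1) * m + p[, 2] else integer(0))
          expect_equal(sort(unname(unlist(keys))), all_keys)
          expect_equal(sum(lengths(keys)), length(all_keys))  # disjoint
          # no test drug appears in a training pair
          test_drugs <- union(rd$test_a, rd$test_b)
          expect_length(intersect(as.vector(ps$train_pairs), test_drugs), 0)
        }
      }
    }
  }
})

test_that("CV1 test blocks cover between-fold pairs symmetrically; CV2 complements them", {
  for (K in c(2, 3, 5)) {
    m <- 4 * K + 1
    seed <- K
    cv1 <- make_cv1_plan(m, K, seed)
    cv2 <- make_cv2_plan(m, K, seed)
    expect_identical(cv1$folds, cv2$folds)  # same partition under one seed

    # every between-fold pair is tested in exactly two rounds (once with each
    # endpoint playing the new drug); within-fold pairs are never CV1-tested
    keys <- unname(unlist(lapply(cv1$rounds, function(rd) {
      p <- cv_round_pairs(rd, m)$test_pairs
      (p[, 1] - 1) * m + p[, 2]
    })))
    fold_of <- integer(m)
    for (k in seq_len(K)) fold_of[cv1$folds[[k]]] <- k
    between <- t(utils::combn(m, 2))
    between <- between[fold_of[between[, 1]] != fold_of[between[, 2]], , drop = FALSE]
    expect_equal(sort(unique(keys)), sort((between[, 1] - 1) * m + between[, 2]))
    expect_true(all(table(keys) == 2))

    # within-group CV2 test pairs = the fold interior CV1 leaves blind
    for (k in seq_len(K)) {
      blind1 <- cv_round_pairs(cv1$rounds[[k]], m)$blind_pairs
      test2 <- cv_round_pairs(cv2$rounds[[k]], m)$test_pairs
      expect_equal(blind1[order(blind1[, 1], blind1[, 2]), , drop = FALSE],
                   test2[order(test2[, 1], test2[, 2]), , drop = FALSE])
    }
  }
})

test_that("plans are reproducible from their seed", {
  expect_identical(make_cv2_plan(40, 4, 99), make_cv2_plan(40, 4, 99))
  expect_false(identical(make_cv2_plan(40, 4, 99)$folds,
                         make_cv2_plan(40, 4, 100)$folds))
})

test_that("score_binary matches hand examples and the pairwise oracle", {
  expect_equal(score_binary(c(1, 0), c(0.9, 0.1))$auc, 1.0)
  expect_equal(score_binary(c(1, 0), c(0.1, 0.9))$auc, 0.0)
  ev <- score_binary(c(1, 1, 0, 0), c(4, 2, 3, 1))
  expect_equal(ev$auc, 0.75)
  expect_equal(ev$aupr, oracle_aupr(c(1, 1, 0, 0), c(4, 2, 3, 1)))

  set.seed(21)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))  # both classes present
    scores <- sample(seq(0, 2, by = 0.5), n, replace = TRUE)  # ties likely
    ev <- score_binary(labels, scores)
    expect_equal(ev$auc, oracle_auc(labels, scores))
    expect_equal(ev$aupr, oracle_aupr(labels, scores))
  }
})

test_that("score_binary agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  labels <- rbinom(60, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- rnorm(60)
  expect_equal(score_binary(labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("the comprehensive protocol flips degressive labels and scores", {
  expect_equal(score_comprehensive(c(1, -1, 0), c(2.0, -1.5, 0.1))$auc, 1.0)
  expect_equal(score_comprehensive(c(1, -1, 0), c(-2.0, 1.5, 0.1))$auc, 0.0)
  expect_equal(score_comprehensive(c(1, -1, 0, 0), rep(0, 4))$auc, 0.5)

  # flipping is exactly score negation for degressive samples
  set.seed(23)
  labels <- sample(c(-1, 0, 1), 30, replace = TRUE); labels[1:2] <- c(-1, 0)
  scores <- rnorm(30)
  manual <- score_binary(as.integer(labels != 0),
                         ifelse(labels == -1, -scores, scores))
  expect_equal(score_comprehensive(labels, scores)$auc, manual$auc)
  expect_equal(score_comprehensive(labels, scores)$aupr, manual$aupr)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(24)
  labels <- c(1, 0, rbinom(18, 1, 0.5))
  scores <- rnorm(20)
  base <- score_binary(labels, scores)$auc
  expect_equal(score_binary(labels, exp(scores))$auc, base)
  expect_equal(score_binary(labels, 3 * scores + 7)$auc, base)
  expect_equal(score_binary(labels, rank(scores, ties.method = "average"))$auc, base)
})

test_that("single-class inputs are rejected", {
  expect_error(score_binary(c(1, 1), c(0.1, 0.2)), "undefined metric")
  expect_error(score_binary(c(0, 0), c(0.1, 0.2)), "undefined metric")
  expect_error(score_comprehensive(c(1, -1), c(0.1, 0.2)), "undefined metric")
  expect_error(score_comprehensive(c(0, 0), c(0.1, 0.2)), "undefined metric")
})

test_that("run_cv is reproducible and reports per-round bookkeeping", {
  ds <- generate_synth(synth_config(m = 30, p = 40, seed = 6))
  plan <- make_cv1_plan(30, 3, 7)
  r1 <- suppressWarnings(run_cv(ds$A, ds$F, plan, "comprehensive", rank = 3, ncomp = 8))
  r2 <- suppressWarnings(run_cv(ds$A, ds$F, plan, "comprehensive", rank = 3, ncomp = 8))
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$rounds, r2$rounds)
  expect_equal(nrow(r1$rounds), 3)
  expect_true(all(r1$rounds$n_pos + r1$rounds$n_neg == r1$rounds$n_test_pairs))

  conv <- suppressWarnings(run_cv(ds$A, ds$F, plan, "conventional", rank = 3, ncomp = 8))
  expect_true(conv$auc >= 0 && conv$auc <= 1)
})

test_that("repeated CV reports dispersion across partitions", {
  ds <- generate_synth(synth_config(m = 30, p = 40, seed = 6))
  rep_res <- suppressWarnings(
    run_cv_repeated(ds$A, ds$F, "cv1", K = 3, repeats = 3, seed = 5,
                    rank = 3, ncomp = 8))
  expect_equal(nrow(rep_res$repeats), 3)
  expect_equal(rep_res$auc_sem, rep_res$auc_sd / sqrt(3))
  rep_res2 <- suppressWarnings(
    run_cv_repeated(ds$A, ds$F, "cv1", K = 3, repeats = 3, seed = 5,
                    rank = 3, ncomp = 8))
  expect_equal(rep_res$repeats, rep_res2$repeats)
})

test_that("tuning returns the smallest L on ties and degenerate grids directly", {
  ds <- generate_synth(synth_config(m = 30, p = 40, seed = 6))
  tn <- suppressWarnings(tune_latent_factors(ds$A, ds$F, grid = 5, K = 3, seed = 2))
  expect_equal(tn$best_ncomp, 5L)
  expect_equal(nrow(tn$results), 1)
  expect_error(tune_latent_factors(ds$A, ds$F, grid = integer(0)), "non-empty")
})
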