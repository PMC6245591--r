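#' Cold-start cross-validation plans
#'
#' Both schemes partition the drugs (not the drug pairs) into K near-equal
#' folds, so that test drugs carry no interaction information into training —
#' the cold-start condition for new drugs.
#'
#' \describe{
#'   \item{CV1}{K rounds. In round k the drugs of fold k play the role of new
#'     drugs; training pairs are the pairs among the remaining drugs, test
#'     pairs are the pairs between fold k and the training drugs, and pairs
#'     inside fold k are blind (used by neither phase).}
#'   \item{CV2}{K(K+1)/2 rounds. K within-group rounds test the pairs inside
#'     one fold (training on the other K-1 folds; pairs linking test drugs to
#'     training drugs are blind), plus K(K-1)/2 between-group rounds testing
#'     the pairs between two folds (training on the remaining K-2 folds; all
#'     other pairs blind).}
#' }
#'
#' Fold assignment shuffles the drug indices with the given seed and deals
#' them into K folds round-robin.
#'
#' @param m Number of drugs.
#' @param K Number of folds (>= 2; CV2 between-group rounds need K >= 3 for
#'   a non-empty training set, K = 2 is allowed but its between-group round
#'   trains on a single fold).
#' @param seed Integer seed controlling the fold shuffle.
#' @return An object of class `cv_plan`: list with `scheme`, `K`, `m`,
#'   `seed`, `folds` (list of K index vectors) and `rounds` (list of lists
#'   with `train`, `test_a`, `test_b`, `kind`).
#' @examples
#' plan <- make_cv1_plan(9, K = 3, seed = 1)
#' length(plan$rounds)  # 3
#' length(make_cv2_plan(9, K = 3, seed = 1)$rounds)  # 6
#' @export
make_cv1_plan <- function(m, K, seed) {
  folds <- make_folds(m, K, seed)
  rounds <- lapply(seq_len(K), function(k) {
    test <- folds[[k]]
    list(train = sort(unlist(folds[-k], use.names = FALSE)),
         test_a = test, test_b = test, kind = "cv1")
  })
  new_cv_plan("cv1", K, m, seed, folds, rounds)
}

#' @rdname make_cv1_plan
#' @export
make_cv2_plan <- function(m, K, seed) {
  folds <- make_folds(m, K, seed)
  within <- lapply(seq_len(K), function(k) {
    test <- folds[[k]]
    list(train = sort(unlist(folds[-k], use.names = FALSE)),
         test_a = test, test_b = test, kind = "within")
  })
  combos <- utils::combn(K, 2L)
  between <- lapply(seq_len(ncol(combos)), function(j) {
    i1 <- combos[1L, j]; i2 <- combos[2L, j]
    list(train = sort(unlist(folds[-c(i1, i2)], use.names = FALSE)),
         test_a = folds[[i1]], test_b = folds[[i2]], kind = "between")
  })
  new_cv_plan("cv2", K, m, seed, folds, c(within, between))
}

make_folds <- function(m, K, seed) {
  if (K < 2) abort("K must be >= 2")
  if (m < K) abort("m must be at least K")
  idx <- local_seed(seed, sample.int(m))
  split(idx, rep_len(seq_len(K), m))
}

new_cv_plan <- function(scheme, K, m, seed, folds, rounds) {
  structure(
    list(scheme = scheme, K = as.integer(K), m = as.integer(m),
         seed = as.integer(seed),
         folds = lapply(folds, function(f) sort(unname(f))),
         rounds = rounds),
    class = "cv_plan"
  )
}

#' Pair bookkeeping of one cross-validation round
#'
#' Splits all unordered drug pairs of a round into the training block, the
#' test block, and the blind block. The three sets always partition the
#' full set of unordered pairs.
#'
#' @param round One element of a `cv_plan`'s `rounds` list.
#' @param m Total number of drugs.
#' @return List with 2-column integer matrices `train_pairs`, `test_pairs`,
#'   `blind_pairs` (each row an i < j pair).
#' @export
cv_round_pairs <- function(round, m) {
  train <- pairs_within(round$train)
  test <- if (identical(round$test_a, round$test_b)) {
    if (identical(round$kind, "cv1")) pairs_between(round$test_a, round$train)
    else pairs_within(round$test_a)
  } else {
    pairs_between(round$test_a, round$test_b)
  }
  all_pairs <- pairs_within(seq_len(m))
  used <- c(pair_key(train, m), pair_key(test, m))
  blind <- all_pairs[!(pair_key(all_pairs, m) %in% used), , drop = FALSE]
  list(train_pairs = train, test_pairs = test, blind_pairs = blind)
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("%s cross-validation plan: %d drugs, K = %d, %d round(s), seed %d\n",
              toupper(x$scheme), x$m, x$K, length(x$rounds), x$seed))
  invisible(x)
}
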