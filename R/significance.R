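#' Distribution of the feature projection entries
#'
#' Histograms the upper triangle (including the diagonal) of
#' `Theta = B B'` and counts entries whose absolute value exceeds the
#' significance threshold. Rows of `Theta` are streamed in blocks from `B`,
#' so the full p x p matrix is never held at once.
#'
#' @param model A fitted `tmfuf_fit`.
#' @param bins Number of histogram bins.
#' @param threshold Significance cutoff on `|theta|`. The default 1 is
#'   calibrated to the default `scale_factor = 1000` of [fit_tmfuf()];
#'   the two are meaningful only together.
#' @param block_size Number of rows of `Theta` materialized per block.
#' @return An object of class `theta_summary`: list with `histogram`
#'   (tibble: bin_low, bin_high, count), `n_significant_positive`,
#'   `n_significant_negative`, `threshold`, `n_entries`, `scale_factor`.
#' @export
summarize_theta <- function(model, bins = 50, threshold = 1, block_size = 512L) {
  p <- nrow(model$B)
  rng <- c(Inf, -Inf)
  for (blk in theta_blocks(p, block_size)) {
    Tb <- model$B[blk, , drop = FALSE] %*% t(model$B)
    vals <- Tb[col(Tb) >= blk[1] + row(Tb) - 1]  # entries with column >= row
    rng <- c(min(rng[1], min(vals)), max(rng[2], max(vals)))
  }
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)

  counts <- integer(bins)
  n_pos <- n_neg <- 0L
  n_entries <- 0L
  for (blk in theta_blocks(p, block_size)) {
    Tb <- model$B[blk, , drop = FALSE] %*% t(model$B)
    vals <- Tb[col(Tb) >= blk[1] + row(Tb) - 1]
    bi <- findInterval(vals, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- counts + tabulate(bi, nbins = bins)
    n_pos <- n_pos + sum(vals > threshold)
    n_neg <- n_neg + sum(vals < -threshold)
    n_entries <- n_entries + length(vals)
  }
  structure(
    list(
      histogram = tibble::tibble(bin_low = breaks[-(bins + 1L)],
                                 bin_high = breaks[-1L], count = counts),
      n_significant_positive = n_pos,
      n_significant_negative = n_neg,
      threshold = threshold,
      n_entries = n_entries,
      scale_factor = model$hyperparams$scale_factor
    ),
    class = "theta_summary"
  )
}

theta_blocks <- function(p, block_size) {
  starts <- seq(1L, p, by = as.integer(block_size))
  lapply(starts, function(s) s:min(s + block_size - 1L, p))
}

#' Significant feature pairs from the projection matrix
#'
#' Scans `Theta = B B'` (upper triangle, diagonal included) for entries with
#' `|theta| > threshold`, ranks them by absolute value (descending, global
#' rank across both directions) and keeps the strongest `top_k` per
#' direction. Positive entries mark feature pairs pushing towards enhancive
#' interactions, negative entries towards degressive ones. Diagonal
#' self-pairs are reported but flagged via `self_pair`.
#'
#' The scan streams `Theta` in row blocks from `B`, so the p x p matrix is
#' never fully materialized.
#'
#' @inheritParams summarize_theta
#' @param top_k Number of pairs to keep per direction (enhancive /
#'   degressive); `Inf` keeps all significant pairs.
#' @return A tibble with columns `rank` (global, by `|theta|`), `feature_a`,
#'   `feature_b`, `theta`, `direction` (`"enhancive"` / `"degressive"`),
#'   `self_pair`. May have zero rows.
#' @export
significant_pairs <- function(model, threshold = 1, top_k = 10,
                              block_size = 512L) {
  if (threshold <= 0) abort("threshold must be positive")
  p <- nrow(model$B)
  feats <- model$feature_names
  hits <- list()
  for (blk in theta_blocks(p, block_size)) {
    Tb <- model$B[blk, , drop = FALSE] %*% t(model$B)
    keep <- which(abs(Tb) > threshold & col(Tb) >= blk[1] + row(Tb) - 1,
                  arr.ind = TRUE)
    if (nrow(keep) > 0L) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        i = blk[1] + keep[, 1L] - 1L,
        j = keep[, 2L],
        theta = Tb[keep]
      )
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(rank = integer(0), feature_a = character(0),
                          feature_b = character(0), theta = numeric(0),
                          direction = character(0), self_pair = logical(0)))
  }
  all_hits <- dplyr::bind_rows(hits) |>
    dplyr::arrange(dplyr::desc(abs(.data$theta))) |>
    dplyr::mutate(rank = dplyr::row_number())
  all_hits |>
    dplyr::mutate(
      feature_a = feats[.data$i],
      feature_b = feats[.data$j],
      direction = ifelse(.data$theta > 0, "enhancive", "degressive"),
      self_pair = .data$i == .data$j
    ) |>
    dplyr::group_by(.data$direction) |>
    dplyr::slice_head(n = if (is.finite(top_k)) as.integer(top_k) else nrow(all_hits)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$rank) |>
    dplyr::select("rank", "feature_a", "feature_b", "theta", "direction",
                  "self_pair")
}
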