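#' Read a signed interaction edge list
#'
#' Reads a tab-separated edge list with columns `drug_a`, `drug_b`, `type`.
#' `type` may be `enhancive`/`degressive` or `+1`/`-1` (also `1`/`-1`).
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble with columns `drug_a`, `drug_b` (character) and
#'   `type` (integer, +1 enhancive / -1 degressive).
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  need <- c("drug_a", "drug_b", "type")
  if (!all(need %in% names(df))) {
    abort(paste0("edge list must have columns: ", paste(need, collapse = ", ")))
  }
  tibble::tibble(
    drug_a = df$drug_a,
    drug_b = df$drug_b,
    type = parse_interaction_type(df$type)
  )
}

parse_interaction_type <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("enhancive", "+1", "1")] <- 1L
  out[x %in% c("degressive", "-1", "−1")] <- -1L
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(paste0("unrecognized interaction type(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out
}

#' Build a signed interaction matrix from an edge list
#'
#' Constructs the m x m symmetric signed adjacency matrix of a comprehensive
#' drug-drug interaction network: entries are +1 (enhancive), -1 (degressive)
#' or 0 (no known interaction), with a zero diagonal.
#'
#' Duplicate edges with the same sign are deduplicated with a warning;
#' duplicates with conflicting signs and self-loops are errors.
#'
#' @param edges A data frame with columns `drug_a`, `drug_b`, `type`
#'   (see [read_edge_list()]), or a path to such a TSV file.
#' @param drugs Character vector of unique drug identifiers; defines row and
#'   column order of the matrix.
#' @return An integer matrix with `drugs` as dimnames.
#' @examples
#' edges <- tibble::tibble(drug_a = c("d1", "d2"), drug_b = c("d2", "d3"),
#'                         type = c(1L, -1L))
#' interaction_matrix(edges, c("d1", "d2", "d3"))
#' @export
interaction_matrix <- function(edges, drugs) {
  if (is.character(edges) && length(edges) == 1L) edges <- read_edge_list(edges)
  stopifnot(is.data.frame(edges))
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs) || any(!nzchar(drugs))) {
    abort("drug identifiers must be unique and non-empty")
  }
  m <- length(drugs)
  A <- matrix(0L, m, m, dimnames = list(drugs, drugs))
  if (nrow(edges) == 0L) return(A)

  ia <- match(as.character(edges$drug_a), drugs)
  ib <- match(as.character(edges$drug_b), drugs)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(edges$drug_a[is.na(ia)], edges$drug_b[is.na(ib)]))
    abort(paste0("unknown drug id(s) in edge list: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(ia == ib)) {
    abort(paste0("self-loop edge(s) not allowed: ",
                 paste(head(drugs[ia[ia == ib]], 5), collapse = ", ")))
  }
  type <- if (is.numeric(edges$type)) as.integer(edges$type)
          else parse_interaction_type(edges$type)
  if (!all(type %in% c(-1L, 1L))) abort("edge types must be +1 or -1")

  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- (lo - 1L) * m + hi
  if (anyDuplicated(key)) {
    split_type <- split(type, key)
    conflict <- vapply(split_type, function(t) length(unique(t)) > 1L, logical(1))
    if (any(conflict)) {
      k <- as.integer(names(split_type)[conflict][1])
      i <- (k - 1L) %/% m + 1L; j <- (k - 1L) %% m + 1L
      abort(paste0("conflicting duplicate edge with opposite signs: ",
                   drugs[i], " -- ", drugs[j]))
    }
    warn("duplicate identical edges found; deduplicating")
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]; type <- type[keep]
  }
  A[cbind(lo, hi)] <- type
  A[cbind(hi, lo)] <- type
  A
}

#' @rdname interaction_matrix
#' @param path Path to a TSV edge list.
#' @export
load_interactions <- function(path, drugs) interaction_matrix(path, drugs)

#' Validate a signed interaction matrix
#'
#' Checks symmetry, entries in \{-1, 0, +1\} and a zero diagonal.
#'
#' @param A Matrix to validate.
#' @return Invisibly `TRUE`; aborts with a message otherwise.
#' @export
validate_interaction_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort("interaction matrix must be square")
  if (!all(A %in% c(-1, 0, 1))) abort("interaction entries must be -1, 0 or +1")
  if (!isTRUE(all.equal(unname(A), unname(t(A))))) abort("interaction matrix must be symmetric")
  if (any(diag(A) != 0)) abort("interaction matrix must have a zero diagonal (no self-interaction)")
  invisible(TRUE)
}

#' Collapse a signed interaction matrix to binary
#'
#' Conventional binary interaction networks ignore the pharmacological
#' direction: every nonzero (enhancive or degressive) entry becomes +1.
#'
#' @param A Signed interaction matrix.
#' @return Integer matrix of the same shape with entries in \{0, 1\}.
#' @export
binarize <- function(A) {
  B <- abs(sign(A))
  storage.mode(B) <- "integer"
  dimnames(B) <- dimnames(A)
  B
}

#' Network statistics of an interaction matrix
#'
#' Counts interacting pairs by type and summarizes per-drug degrees, overall
#' and split by enhancive / degressive edges.
#'
#' @param A Signed interaction matrix.
#' @return A one-row tibble with counts (`n_drugs`, `n_interactions`,
#'   `n_enhancive`, `n_degressive`) and `{degree,enhancive_degree,
#'   degressive_degree}_{mean,median,max,min}` summaries.
#' @export
network_stats <- function(A) {
  validate_interaction_matrix(A)
  deg_all <- rowSums(A != 0)
  deg_en <- rowSums(A == 1)
  deg_de <- rowSums(A == -1)
  smry <- function(d, what) {
    out <- list(mean(d), stats::median(d), max(d), min(d))
    names(out) <- paste0(what, "_", c("mean", "median", "max", "min"))
    out
  }
  tibble::as_tibble(c(
    list(
      n_drugs = nrow(A),
      n_interactions = sum(deg_all) / 2,
      n_enhancive = sum(deg_en) / 2,
      n_degressive = sum(deg_de) / 2
    ),
    smry(deg_all, "degree"),
    smry(deg_en, "enhancive_degree"),
    smry(deg_de, "degressive_degree")
  ))
}

#' Convert an interaction matrix back to an edge list
#'
#' @param A Signed interaction matrix.
#' @return A tibble with columns `drug_a`, `drug_b`, `type`; one row per
#'   unordered interacting pair.
#' @export
as_edge_list <- function(A) {
  validate_interaction_matrix(A)
  drugs <- rownames(A)
  if (is.null(drugs)) drugs <- as.character(seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  tibble::tibble(
    drug_a = drugs[idx[, 1L]],
    drug_b = drugs[idx[, 2L]],
    type = as.integer(A[idx])
  )
}

#' @rdname as_edge_list
#' @param path Output TSV path; `type` is written as `enhancive`/`degressive`.
#' @export
write_interactions <- function(A, path) {
  el <- as_edge_list(A)
  el$type <- ifelse(el$type > 0, "enhancive", "degressive")
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network_stats
#' @param stats A tibble from `network_stats()`.
#' @param path Output JSON path.
#' @export
write_network_stats <- function(stats, path) {
  jsonlite::write_json(as.list(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary drug feature matrix
#'
#' Reads either a sparse MatrixMarket coordinate file with sidecar label
#' files (`features.txt`, `drugs.txt`, one label per line, order defining
#' columns / rows), or a dense tab-separated table whose first column holds
#' drug ids and whose header names the feature columns.
#'
#' @param path Path to a `.mtx` MatrixMarket file or a dense TSV.
#' @param features_path,drugs_path Sidecar label files for the MatrixMarket
#'   layout; default to `features.txt` / `drugs.txt` next to `path`.
#' @return A binary integer matrix (drugs x features) with dimnames.
#' @export
read_feature_matrix <- function(path, features_path = NULL, drugs_path = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    dir <- dirname(path)
    if (is.null(features_path)) features_path <- file.path(dir, "features.txt")
    if (is.null(drugs_path)) drugs_path <- file.path(dir, "drugs.txt")
    M <- as.matrix(Matrix::readMM(path))
    feats <- readLines(features_path)
    drugs <- readLines(drugs_path)
    if (nrow(M) != length(drugs) || ncol(M) != length(feats)) {
      abort("feature matrix dimensions do not match sidecar label files")
    }
    dimnames(M) <- list(drugs, feats)
  } else {
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
    drugs <- as.character(df[[1L]])
    M <- as.matrix(df[, -1L, drop = FALSE])
    rownames(M) <- drugs
  }
  storage.mode(M) <- "integer"
  validate_feature_matrix(M)
  M
}

#' Write a binary feature matrix as MatrixMarket plus label sidecars
#'
#' @param F Binary feature matrix with dimnames.
#' @param dir Output directory; writes `F.mtx`, `features.txt`, `drugs.txt`.
#' @return Invisibly, the path to the `.mtx` file.
#' @export
write_feature_matrix <- function(F, dir) {
  validate_feature_matrix(F)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, "F.mtx")
  Matrix::writeMM(Matrix::Matrix(F * 1, sparse = TRUE), mtx)
  writeLines(colnames(F), file.path(dir, "features.txt"))
  writeLines(rownames(F), file.path(dir, "drugs.txt"))
  invisible(mtx)
}

#' Validate a binary feature matrix
#'
#' Entries must be 0/1 and feature names unique. All-zero feature columns are
#' kept but reported with a warning (no column filtering is applied).
#'
#' @param F Matrix to validate.
#' @return Invisibly `TRUE`.
#' @export
validate_feature_matrix <- function(F) {
  if (!is.matrix(F)) abort("feature matrix must be a matrix")
  if (!all(F %in% c(0, 1))) abort("feature entries must be 0 or 1")
  if (!is.null(colnames(F)) && anyDuplicated(colnames(F))) {
    abort("feature names must be unique")
  }
  nz <- colSums(F)
  if (any(nz == 0)) {
    warn(paste0(sum(nz == 0), " all-zero feature column(s) present"))
  }
  invisible(TRUE)
}
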