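#' Standardize the phenotypes of one cluster
#'
#' Centers and scales each member phenotype to mean 0, SD 1 across
#' individuals; the cluster-wise scaling applied before any representative
#' is built.
#'
#' @param Y d x n phenotype matrix (rows = phenotypes).
#' @param members indices (or row names) of the cluster's phenotypes.
#' @return The |members| x n standardized block.
#' @export
standardize_cluster <- function(Y, members) {
  Y <- as.matrix(Y)
  if (length(members) == 0L) stop("cluster is empty", call. = FALSE)
  Yk <- Y[members, , drop = FALSE]
  .standardize_rows(Yk)
}

#' Mean representative of a cluster
#'
#' Elementwise mean of the (standardized) member phenotypes:
#' \eqn{Y^k_{mean} = |c_k|^{-1} \sum_{Y_i \in c_k} Y_i}.
#'
#' @param Yk cluster block, phenotypes as rows.
#' @return A length-n numeric vector.
#' @export
mean_representative <- function(Yk) {
  Yk <- as.matrix(Yk)
  if (nrow(Yk) == 0L) stop("cluster is empty", call. = FALSE)
  colMeans(Yk)
}

#' Median representative of a cluster
#'
#' Elementwise median of the member phenotypes; for an even member count the
#' mean of the two central order statistics.
#'
#' @inheritParams mean_representative
#' @return A length-n numeric vector.
#' @export
median_representative <- function(Yk) {
  Yk <- as.matrix(Yk)
  if (nrow(Yk) == 0L) stop("cluster is empty", call. = FALSE)
  apply(Yk, 2L, median)
}

#' Top principal-component representatives of a cluster
#'
#' Principal components of the member phenotypes, treating individuals as
#' observations and members as variables. Returns the smallest number m of
#' score vectors whose cumulative explained-variance fraction strictly
#' exceeds `cum_threshold` (default 0.85). Rows are expected to be
#' standardized already (see [standardize_cluster()]), making this a
#' correlation-scale PCA. Each component's sign is fixed so its largest
#' absolute loading is positive, which makes the output deterministic.
#'
#' @param Yk standardized cluster block, phenotypes as rows.
#' @param cum_threshold cumulative contribution threshold in (0, 1).
#' @return A list with `scores` (m x n matrix, one component per row) and
#'   `explained` (the m per-component variance fractions, non-increasing).
#' @export
pca_representatives <- function(Yk, cum_threshold = 0.85) {
  cum_threshold <- .assert_fraction(cum_threshold, "cum_threshold")
  Yk <- as.matrix(Yk)
  if (nrow(Yk) == 0L) stop("cluster is empty", call. = FALSE)
  n <- ncol(Yk)
  Yc <- Yk - rowMeans(Yk)
  # covariance of the member phenotypes (variables) over individuals
  C <- tcrossprod(Yc) / (n - 1)
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  total <- sum(vals)
  if (total == 0) stop("cluster has no variance; cannot build PC representatives",
                       call. = FALSE)
  frac <- vals / total
  m <- which(cumsum(frac) > cum_threshold)[1L]
  V <- ev$vectors[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(m)) {
    pivot <- which.max(abs(V[, j]))
    if (V[pivot, j] < 0) V[, j] <- -V[, j]
  }
  scores <- t(crossprod(Yc, V))       # m x n score vectors
  list(scores = scores, explained = frac[seq_len(m)])
}

#' Build the representative phenotype set for a partition
#'
#' Standardizes each cluster's phenotypes, reduces each cluster by the
#' chosen method (one mean or median row per cluster, or the top principal
#' components under the cumulative-contribution rule), and stacks the
#' resulting rows.
#'
#' @param Y d x n phenotype matrix.
#' @param partition an `agnep_partition` (or label vector) over the rows of
#'   `Y`.
#' @param method `"pca"` (default), `"mean"`, or `"median"`.
#' @param cum_threshold cumulative explained-variance threshold for
#'   `method = "pca"`.
#' @return An object of class `agnep_representatives`: `values` (r x n
#'   matrix), `source_cluster` (r-vector), `method`, `explained_fraction`
#'   (pca only), `cum_threshold`.
#' @examples
#' Y <- matrix(rnorm(120), nrow = 6)
#' part <- agnes(phenotype_distance_matrix(Y), K = 2)
#' build_representatives(Y, part, method = "mean")
#' @export
build_representatives <- function(Y, partition,
                                  method = c("pca", "mean", "median"),
                                  cum_threshold = 0.85) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  labels <- if (inherits(partition, "agnep_partition")) partition$assignment
            else as.integer(partition)
  if (length(labels) != nrow(Y)) {
    stop("partition labels do not match the number of phenotypes", call. = FALSE)
  }
  rows <- list(); src <- integer(0); expl <- numeric(0); nms <- character(0)
  for (k in sort(unique(labels))) {
    members <- which(labels == k)
    Yk <- standardize_cluster(Y, members)
    if (method == "mean") {
      rows[[length(rows) + 1L]] <- mean_representative(Yk)
      src <- c(src, k); nms <- c(nms, sprintf("C%d_mean", k))
    } else if (method == "median") {
      rows[[length(rows) + 1L]] <- median_representative(Yk)
      src <- c(src, k); nms <- c(nms, sprintf("C%d_median", k))
    } else {
      pc <- pca_representatives(Yk, cum_threshold)
      for (j in seq_len(nrow(pc$scores))) {
        rows[[length(rows) + 1L]] <- pc$scores[j, ]
        nms <- c(nms, sprintf("C%d_PC%d", k, j))
      }
      src <- c(src, rep(k, nrow(pc$scores)))
      expl <- c(expl, pc$explained)
    }
  }
  values <- do.call(rbind, rows)
  dimnames(values) <- list(nms, colnames(Y))
  structure(list(values = values, source_cluster = src, method = method,
                 explained_fraction = if (method == "pca") expl else NULL,
                 cum_threshold = if (method == "pca") cum_threshold else NULL),
            class = "agnep_representatives")
}

#' @export
print.agnep_representatives <- function(x, ...) {
  cat(sprintf("agnep_representatives: %d rows (%s) for %d clusters\n",
              nrow(x$values), x$method, length(unique(x$source_cluster))))
  invisible(x)
}
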