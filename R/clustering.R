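#' Euclidean distance matrix between phenotypes
#'
#' Computes the pairwise Euclidean distance
#' \eqn{dist(Y_i, Y_j) = \sqrt{\sum_t (y_{it} - y_{jt})^2}} between phenotype
#' rows over the individuals. By default every phenotype is first
#' standardized (mean 0, SD 1 across individuals) so that measurement units
#' do not dominate the clustering; set `standardize = FALSE` for raw-scale
#' distances.
#'
#' @param Y d x n numeric matrix, phenotypes as rows, individuals as columns.
#' @param standardize standardize rows before computing distances (default
#'   TRUE).
#' @return An object of class `agnep_dist`: list with `values` (d x d
#'   symmetric matrix, zero diagonal) and `labels`.
#' @export
phenotype_distance_matrix <- function(Y, standardize = TRUE) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 phenotypes to build a distance matrix",
                         call. = FALSE)
  if (anyNA(Y)) {
    bad <- which(rowSums(is.na(Y)) > 0)[1L]
    lab <- rownames(Y)[bad] %||% bad
    stop(sprintf("phenotype '%s' contains missing values; handle missing data upstream",
                 lab), call. = FALSE)
  }
  labels <- rownames(Y) %||% paste0("P", seq_len(nrow(Y)))
  if (standardize) Y <- .standardize_rows(Y)
  D <- as.matrix(dist(Y, method = "euclidean"))
  dimnames(D) <- list(labels, labels)
  structure(list(values = D, labels = labels), class = "agnep_dist")
}

#' @export
print.agnep_dist <- function(x, ...) {
  cat(sprintf("agnep_dist: %d phenotypes\n", length(x$labels)))
  invisible(x)
}

# coerce agnep_dist / dist / symmetric matrix to a plain symmetric matrix
.as_dist_matrix <- function(D) {
  if (inherits(D, "agnep_dist")) return(D$values)
  if (inherits(D, "dist")) return(as.matrix(D))
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-10) || any(diag(D) != 0)) {
    stop("`D` must be a symmetric distance matrix with zero diagonal", call. = FALSE)
  }
  D
}

#' Agglomerative nesting (bottom-up hierarchical clustering)
#'
#' Starts from every phenotype in its own cluster and repeatedly merges the
#' two closest clusters until `K` clusters remain. Cluster-to-cluster
#' distance is the single-linkage minimum
#' \eqn{dist_{min}(c_i, c_j) = \min_{p \in c_i, q \in c_j} dist(p, q)}
#' by default; complete and average linkage are available. Ties are broken
#' deterministically by merging the pair whose (smallest member index,
#' largest member index) label pair is lexicographically smallest.
#'
#' @param D distance matrix (`agnep_dist`, `dist`, or symmetric matrix).
#' @param K number of clusters to cut at, 1 <= K <= d.
#' @param linkage `"single"` (default), `"complete"`, or `"average"`.
#' @return An object of class `agnep_partition`: `assignment` (d-vector of
#'   labels 1..K, clusters numbered by first member), `K`, and
#'   `merge_history` (data.frame of cluster-a, cluster-b, merge distance,
#'   d - K rows).
#' @examples
#' D <- phenotype_distance_matrix(matrix(rnorm(80), nrow = 8))
#' agnes(D, K = 3)$assignment
#' @export
agnes <- function(D, K, linkage = c("single", "complete", "average")) {
  linkage <- match.arg(linkage)
  D <- .as_dist_matrix(D)
  d <- nrow(D)
  K <- .assert_scalar_count(K, "K")
  if (K > d) stop(sprintf("K = %d outside 1..%d", K, d), call. = FALSE)

  members <- as.list(seq_len(d))      # member index sets of active clusters
  sizes <- rep(1L, d)
  CD <- D                             # current cluster-to-cluster distances
  diag(CD) <- Inf
  active <- rep(TRUE, d)
  history <- data.frame(cluster_a = integer(0), cluster_b = integer(0),
                        distance = numeric(0))

  n_active <- d
  while (n_active > K) {
    idx <- which(active)
    sub <- CD[idx, idx, drop = FALSE]
    dmin <- min(sub)
    # candidate pairs at the minimum; deterministic lexicographic tie-break
    # on (min member label, max member label)
    hits <- which(sub == dmin, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    lab_lo <- pmin(idx[hits[, 1L]], idx[hits[, 2L]])
    lab_hi <- pmax(idx[hits[, 1L]], idx[hits[, 2L]])
    pick <- order(lab_lo, lab_hi)[1L]
    a <- lab_lo[pick]; b <- lab_hi[pick]

    history <- rbind(history,
                     data.frame(cluster_a = min(members[[a]]),
                                cluster_b = min(members[[b]]),
                                distance = dmin))
    # Lance-Williams update of distances to the merged cluster (kept at slot a)
    others <- setdiff(idx, c(a, b))
    new_d <- switch(linkage,
      single   = pmin(CD[a, others], CD[b, others]),
      complete = pmax(CD[a, others], CD[b, others]),
      average  = (sizes[a] * CD[a, others] + sizes[b] * CD[b, others]) /
                 (sizes[a] + sizes[b]))
    CD[a, others] <- new_d
    CD[others, a] <- new_d
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
    CD[b, ] <- Inf; CD[, b] <- Inf
    n_active <- n_active - 1L
  }

  assignment <- integer(d)
  firsts <- vapply(members[active], min, integer(1L))
  ord <- order(firsts)                # number clusters by first member index
  act <- which(active)[ord]
  for (k in seq_along(act)) assignment[members[[act[k]]]] <- k
  names(assignment) <- rownames(D) %||% paste0("P", seq_len(d))
  structure(list(assignment = assignment, K = K, merge_history = history,
                 linkage = linkage),
            class = "agnep_partition")
}

#' @export
print.agnep_partition <- function(x, ...) {
  cat(sprintf("agnep_partition: %d items in %d clusters (%s linkage)\n",
              length(x$assignment), x$K, x$linkage))
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}

#' Silhouette coefficients for a partition
#'
#' For each phenotype i in cluster \eqn{c_k}, the cohesion a(i) is the mean
#' distance to the other members of \eqn{c_k} (defined as 0 when
#' \eqn{|c_k| = 1}), the separation b(i) is the smallest mean distance to
#' the members of any other cluster, and
#' \eqn{s(i) = (b(i) - a(i)) / \max(b(i), a(i))}. Under the `"unit"`
#' singleton convention a singleton's a(i) = 0 gives s(i) = 1 whenever
#' b(i) > 0; `singleton = "zero"` instead assigns s(i) = 0 to singletons
#' (the convention used by most software). When both a(i) and b(i) are 0
#' (all distances zero), s(i) is defined as 0.
#'
#' @param D distance matrix.
#' @param partition an `agnep_partition` (or a vector of cluster labels).
#' @param singleton `"unit"` (default) or `"zero"`; see Details.
#' @return An object of class `agnep_silhouette`: `per_sample`, `mean_s`,
#'   `a_values`, `b_values`.
#' @export
silhouette <- function(D, partition, singleton = c("unit", "zero")) {
  singleton <- match.arg(singleton)
  D <- .as_dist_matrix(D)
  labels <- if (inherits(partition, "agnep_partition")) partition$assignment
            else as.integer(partition)
  d <- nrow(D)
  if (length(labels) != d) {
    stop("partition labels do not match the distance matrix dimension", call. = FALSE)
  }
  K <- length(unique(labels))
  if (K < 2L) stop("silhouette requires K >= 2 (b(i) is undefined for one cluster)",
                   call. = FALSE)
  a <- b <- s <- numeric(d)
  for (i in seq_len(d)) {
    own <- which(labels == labels[i])
    a[i] <- if (length(own) == 1L) 0 else mean(D[i, setdiff(own, i)])
    b[i] <- min(vapply(setdiff(unique(labels), labels[i]),
                       function(k) mean(D[i, labels == k]), numeric(1L)))
    denom <- max(a[i], b[i])
    s[i] <- if (denom == 0) 0 else (b[i] - a[i]) / denom
    if (singleton == "zero" && length(own) == 1L) s[i] <- 0
  }
  nm <- rownames(D) %||% paste0("P", seq_len(d))
  names(a) <- names(b) <- names(s) <- nm
  structure(list(per_sample = s, mean_s = mean(s), a_values = a, b_values = b),
            class = "agnep_silhouette")
}

#' @export
print.agnep_silhouette <- function(x, ...) {
  cat(sprintf("agnep_silhouette: mean s = %.4f over %d samples\n",
              x$mean_s, length(x$per_sample)))
  invisible(x)
}

#' Select the number of clusters by maximum mean silhouette
#'
#' Cuts the agglomerative hierarchy at every K in `k_min..k_max`, scores
#' each partition by its mean silhouette coefficient, and returns the K
#' with the largest mean silhouette (ties go to the smaller K). The default
#' search range is 2 to d - 1, excluding the all-singletons and
#' single-cluster partitions.
#'
#' Selection scores singletons with s(i) = 0 (`singleton = "zero"`) by
#' default: under the `"unit"` convention every singleton scores 1, so the
#' mean silhouette is maximized by shaving off singletons and the search
#' degenerates to K = d - 1 regardless of the data. The `"unit"` convention
#' remains available for scoring a given partition with [silhouette()].
#'
#' @param D distance matrix over d >= 3 phenotypes.
#' @param k_min,k_max search bounds, 2 <= k_min <= k_max <= d - 1.
#' @param linkage linkage passed to [agnes()].
#' @param singleton singleton convention passed to [silhouette()].
#' @return A list with `K` (selected count), `partition` (the
#'   `agnep_partition` at K), and `s_by_k` (named vector of mean silhouettes).
#' @export
select_k <- function(D, k_min = 2L, k_max = NULL,
                     linkage = c("single", "complete", "average"),
                     singleton = c("zero", "unit")) {
  linkage <- match.arg(linkage)
  singleton <- match.arg(singleton)
  D <- .as_dist_matrix(D)
  d <- nrow(D)
  if (d < 3L) stop("K selection needs d >= 3 phenotypes (search range 2..d-1 is empty)",
                   call. = FALSE)
  if (all(D == 0)) {
    stop("all pairwise distances are zero: no cluster structure to select K from",
         call. = FALSE)
  }
  k_max <- if (is.null(k_max)) d - 1L else .assert_scalar_count(k_max, "k_max")
  k_min <- .assert_scalar_count(k_min, "k_min", min = 2L)
  if (k_min > k_max || k_max > d - 1L) {
    stop(sprintf("need 2 <= k_min <= k_max <= d - 1 (got %d..%d with d = %d)",
                 k_min, k_max, d), call. = FALSE)
  }
  ks <- k_min:k_max
  parts <- lapply(ks, function(k) agnes(D, k, linkage = linkage))
  s_by_k <- vapply(parts, function(p) silhouette(D, p, singleton = singleton)$mean_s,
                   numeric(1L))
  names(s_by_k) <- ks
  best <- which.max(s_by_k)           # which.max returns the first (smallest K) on ties
  list(K = ks[best], partition = parts[[best]], s_by_k = s_by_k)
}
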