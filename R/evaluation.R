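# power evaluation against known simulated QTNs: rank-based empirical-FDR
# power curves, permutation genome-wide thresholds, putative-QTN counting,
# and the full multi-method benchmark loop.

#' Power versus empirical FDR from a scan and its simulation truth
#'
#' Variants are ranked by ascending p-value. At each cut depth t the
#' empirical FDR is (non-QTNs among the top t)/t and the power is (QTNs
#' among the top t)/(total QTNs). For each grid value f the curve reports
#' the maximum power attainable at empirical FDR <= f (0 when no cut
#' qualifies). When `results` is a list of scans from replicate
#' simulations, curves are computed per replicate and averaged.
#'
#' @param results an `agnep_scan`, or a list of them (replicates); paired
#'   element-wise with `truth` when that is a list too.
#' @param truth an `agnep_truth` (or list of them, one per replicate).
#' @param fdr_grid increasing FDR bounds in \[0, 1\].
#' @param method_label label stored on the returned curve.
#' @return An object of class `agnep_power`: `fdr_grid`, `power`
#'   (non-decreasing), `n_replicates`, `method_label`.
#' @export
power_fdr_curve <- function(results, truth, fdr_grid = seq(0, 1, by = 0.01),
                            method_label = "method") {
  if (is.unsorted(fdr_grid, strictly = TRUE) ||
      any(fdr_grid < 0) || any(fdr_grid > 1)) {
    stop("`fdr_grid` must be strictly increasing within [0, 1]", call. = FALSE)
  }
  if (inherits(results, "agnep_scan")) results <- list(results)
  if (inherits(truth, "agnep_truth")) truth <- rep(list(truth), length(results))
  stopifnot(length(results) == length(truth))
  curves <- mapply(function(res, tr) .power_curve_one(res, tr, fdr_grid),
                   results, truth)
  power <- if (is.matrix(curves)) rowMeans(curves) else mean(curves)
  structure(list(fdr_grid = fdr_grid, power = as.numeric(power),
                 n_replicates = length(results), method_label = method_label),
            class = "agnep_power")
}

.power_curve_one <- function(res, tr, fdr_grid) {
  qtn_ids <- tr$qtn_ids %||% as.character(tr$qtn_indices)
  if (!length(qtn_ids)) stop("truth contains no QTNs; power is undefined", call. = FALSE)
  if (!all(qtn_ids %in% res$variant_ids)) {
    stop("truth QTNs are not a subset of the scanned variants", call. = FALSE)
  }
  is_qtn <- res$variant_ids %in% qtn_ids
  ord <- order(res$p_value)
  tp <- cumsum(is_qtn[ord])
  t_seq <- seq_along(ord)
  fdr_t <- (t_seq - tp) / t_seq
  power_t <- tp / length(qtn_ids)
  vapply(fdr_grid, function(f) {
    ok <- fdr_t <= f
    if (any(ok)) max(power_t[ok]) else 0
  }, numeric(1L))
}

#' @export
print.agnep_power <- function(x, ...) {
  at <- c(0.05, 0.1, 0.2)
  p <- vapply(at, function(f) x$power[which.min(abs(x$fdr_grid - f))], numeric(1L))
  cat(sprintf("agnep_power [%s, %d replicate(s)]: power %.3f / %.3f / %.3f at FDR 0.05 / 0.10 / 0.20\n",
              x$method_label, x$n_replicates, p[1L], p[2L], p[3L]))
  invisible(x)
}

#' Permutation genome-wide significance threshold
#'
#' Shuffles the individuals of the representative phenotypes jointly (all
#' rows permuted by the same individual permutation, preserving the
#' between-phenotype correlation; genotypes stay fixed), reruns the MANOVA
#' scan, and records the genome-wide minimum p-value of each permutation.
#' The threshold is the empirical alpha-quantile (the
#' ceiling(alpha * n_perm)-th order statistic) of the permuted minima,
#' returned on the -log10 scale.
#'
#' @param reps an `agnep_representatives` (or r x n matrix).
#' @param genotypes an `agnep_genotypes` (or dosage matrix).
#' @param n_perm number of permutations (default 10).
#' @param alpha quantile level; values below 1/n_perm cannot be resolved and
#'   fall back, with a warning, to the most extreme permuted minimum.
#' @param seed optional integer seed.
#' @param statistic passed to [manova_scan()].
#' @return The threshold as a -log10 p value, with the permuted minima
#'   attached as attribute `"perm_min_p"`.
#' @export
permutation_threshold <- function(reps, genotypes, n_perm = 10, alpha = 0.05,
                                  seed = NULL, statistic = "wilks") {
  n_perm <- .assert_scalar_count(n_perm, "n_perm")
  alpha <- .assert_fraction(alpha, "alpha")
  vals <- if (inherits(reps, "agnep_representatives")) reps$values else as.matrix(reps)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(vals)
  min_p <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(n)
    Yb <- vals[, perm, drop = FALSE]
    colnames(Yb) <- colnames(vals)    # keep the genotype alignment fixed
    min(manova_scan(Yb, genotypes, statistic = statistic)$p_value)
  }, numeric(1L))
  if (alpha < 1 / n_perm) {
    warning(sprintf("alpha = %g is below 1/n_perm = %g; returning the most extreme permuted minimum",
                    alpha, 1 / n_perm), call. = FALSE)
    thr_p <- min(min_p)
  } else {
    thr_p <- sort(min_p)[ceiling(alpha * n_perm)]
  }
  structure(-log10(thr_p), perm_min_p = min_p)
}

#' Count variants exceeding a significance threshold
#'
#' @param results an `agnep_scan`.
#' @param threshold -log10 p threshold (>= 0).
#' @return Number of variants with `neg_log10_p >= threshold`.
#' @export
count_qtns <- function(results, threshold) {
  stopifnot(inherits(results, "agnep_scan"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be a single nonnegative -log10 p value", call. = FALSE)
  }
  sum(results$neg_log10_p >= threshold)
}

#' Multi-method power benchmark on simulated data
#'
#' Runs the full pipeline per replicate — simulate genotypes and phenotypes,
#' cluster the phenotypes with silhouette-selected K, build representatives,
#' scan, and score power against the known QTNs — for each requested method:
#' \describe{
#'   \item{AGNEP}{clustering + top-PC representatives + MANOVA}
#'   \item{AGNEm}{clustering + mean representatives + MANOVA}
#'   \item{AGNEmed}{clustering + median representatives + MANOVA}
#'   \item{MANOVA}{MANOVA on all phenotypes, no clustering}
#'   \item{ANOVA}{univariate per-phenotype scan, ranked by minimum p}
#' }
#'
#' @param preset design preset for [make_design()].
#' @param methods subset of the five method labels above.
#' @param n_qtn,n,m,n_replicates simulation size parameters.
#' @param fdr_grid FDR bounds for the power curves.
#' @param seed integer seed; replicate seeds are derived from it.
#' @param ... further arguments passed to [make_design()].
#' @return A list with `curves` (named list of `agnep_power`) and `table`
#'   (long data.frame: method, fdr, power).
#' @export
run_benchmark <- function(preset, methods = c("AGNEP", "AGNEm", "AGNEmed",
                                              "MANOVA", "ANOVA"),
                          n_qtn = 10, n = 500, m = 1000, n_replicates = 20,
                          fdr_grid = seq(0, 1, by = 0.01), seed = 1, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  n_replicates <- .assert_scalar_count(n_replicates, "n_replicates")
  scans <- stats::setNames(lapply(methods, function(x) vector("list", n_replicates)),
                           methods)
  truths <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    s <- .child_seed(seed, rep_i)
    design <- make_design(preset, n_qtn = n_qtn, n = n, m = m, seed = s, ...)
    geno <- simulate_genotypes(n, m, design$maf_range, seed = .child_seed(s, 1L))
    sim <- simulate_phenotypes(geno, design, seed = .child_seed(s, 2L))
    truths[[rep_i]] <- sim$truth
    Y <- sim$phenotypes
    needs_clust <- any(c("AGNEP", "AGNEm", "AGNEmed") %in% methods)
    part <- if (needs_clust) {
      select_k(phenotype_distance_matrix(Y))$partition
    } else NULL
    for (meth in methods) {
      scans[[meth]][[rep_i]] <- switch(meth,
        AGNEP   = manova_scan(build_representatives(Y, part, "pca"), geno),
        AGNEm   = manova_scan(build_representatives(Y, part, "mean"), geno),
        AGNEmed = manova_scan(build_representatives(Y, part, "median"), geno),
        MANOVA  = manova_scan(.standardize_rows(Y), geno),
        ANOVA   = anova_scan(Y, geno)$min_p)
    }
  }
  curves <- lapply(methods, function(meth) {
    power_fdr_curve(scans[[meth]], truths, fdr_grid, method_label = meth)
  })
  names(curves) <- methods
  table <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(method = cv$method_label, fdr = cv$fdr_grid, power = cv$power,
               stringsAsFactors = FALSE)
  }))
  rownames(table) <- NULL
  list(curves = curves, table = table)
}
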