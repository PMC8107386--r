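# association scans: per-variant MANOVA on representative phenotypes and
# per-phenotype univariate ANOVA, under the model Y = alpha W + B X + E with
# X the minor-allele count. Both scans are vectorized over variants through
# cross-products; a slow per-variant path handles missing genotype calls.

.new_scan <- function(variant_ids, statistic, p_value, scan_kind,
                      phenotype_label = NA_character_, flagged = NULL) {
  structure(list(variant_ids = as.character(variant_ids),
                 statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 neg_log10_p = -log10(as.numeric(p_value)),
                 scan_kind = scan_kind,
                 phenotype_label = phenotype_label,
                 flagged = flagged %||% rep(FALSE, length(variant_ids))),
            class = "agnep_scan")
}

#' @export
print.agnep_scan <- function(x, ...) {
  cat(sprintf("agnep_scan (%s%s): %d variants, min p = %.3g\n",
              x$scan_kind,
              if (!is.na(x$phenotype_label)) paste0(", ", x$phenotype_label) else "",
              length(x$variant_ids), min(x$p_value)))
  invisible(x)
}

#' @export
as.data.frame.agnep_scan <- function(x, ...) {
  data.frame(variant_id = x$variant_ids, statistic = x$statistic,
             p_value = x$p_value, neg_log10_p = x$neg_log10_p,
             flagged = x$flagged, stringsAsFactors = FALSE)
}

# extract an n x r individuals-by-responses matrix from representatives /
# phenotype rows, and align individuals with the genotype object
.align_responses <- function(resp, genotypes) {
  vals <- if (inherits(resp, "agnep_representatives")) resp$values else as.matrix(resp)
  X <- if (inherits(genotypes, "agnep_genotypes")) genotypes$values else as.matrix(genotypes)
  vids <- if (inherits(genotypes, "agnep_genotypes")) genotypes$variant_ids else
    colnames(X) %||% paste0("V", seq_len(ncol(X)))
  rids <- colnames(vals)
  gids <- rownames(X)
  if (!is.null(rids) && !is.null(gids)) {
    if (!setequal(rids, gids)) {
      stop(sprintf("individuals do not match between responses and genotypes (%d unmatched)",
                   length(union(setdiff(rids, gids), setdiff(gids, rids)))),
           call. = FALSE)
    }
    X <- X[match(rids, gids), , drop = FALSE]
  } else if (ncol(vals) != nrow(X)) {
    stop(sprintf("individual axis mismatch: %d response columns vs %d genotype rows",
                 ncol(vals), nrow(X)), call. = FALSE)
  }
  list(Yn = t(vals), X = X, variant_ids = vids)
}

# Wilks' lambda for a single-regressor multivariate regression, computed for
# one variant from centered response matrix Ync (n x r), its inverse total
# SSCP Tinv, and a centered genotype vector
.wilks_one <- function(Ync, Tinv, xc) {
  ssx <- sum(xc^2)
  if (ssx <= 0) return(NA_real_)
  a <- crossprod(Ync, xc)             # r x 1
  1 - as.numeric(t(a) %*% Tinv %*% a) / ssx
}

#' Per-variant MANOVA scan of representative phenotypes
#'
#' For each variant, fits the multivariate regression of the r
#' representative phenotypes on an intercept and the minor-allele count,
#' and tests the genotype term with Wilks' lambda
#' \eqn{\Lambda = |E| / |E + H|} against the intercept-only model. With a
#' single tested regressor the Rao F transform is exact:
#' \eqn{F = \frac{1 - \Lambda}{\Lambda} \cdot \frac{n - 1 - r}{r}} on
#' (r, n - 1 - r) degrees of freedom. The Pillai trace option reports
#' \eqn{V = 1 - \Lambda} (the two statistics are equivalent tests when the
#' hypothesis has one degree of freedom, so p-values coincide).
#'
#' Monomorphic variants cannot be tested and are flagged with p = 1.
#' Individuals with a missing call at a variant are dropped for that
#' variant only.
#'
#' @param reps an `agnep_representatives` object (or an r x n matrix with
#'   representative phenotypes as rows).
#' @param genotypes an `agnep_genotypes` object (or an n x m dosage matrix).
#' @param statistic `"wilks"` (default) or `"pillai"`.
#' @return An `agnep_scan` with one statistic/p-value per variant.
#' @export
manova_scan <- function(reps, genotypes, statistic = c("wilks", "pillai")) {
  statistic <- match.arg(statistic)
  al <- .align_responses(reps, genotypes)
  Yn <- al$Yn; X <- al$X
  n <- nrow(Yn); r <- ncol(Yn); m <- ncol(X)
  if (n <= r + 2L) {
    stop(sprintf("need n > r + 2 individuals (n = %d, r = %d representatives)", n, r),
         call. = FALSE)
  }
  Ync <- sweep(Yn, 2L, colMeans(Yn))
  qrY <- qr(Ync)
  if (qrY$rank < r) {
    dep <- setdiff(seq_len(r), qrY$pivot[seq_len(qrY$rank)])
    nms <- colnames(Yn)[dep] %||% dep
    stop(sprintf("representative phenotypes are rank-deficient; collinear rows: %s",
                 paste(nms, collapse = ", ")), call. = FALSE)
  }
  Tinv <- chol2inv(chol(crossprod(Ync)))

  lambda <- rep(NA_real_, m)
  has_na <- anyNA(X)
  na_cols <- if (has_na) which(colSums(is.na(X)) > 0) else integer(0)
  clean <- setdiff(seq_len(m), na_cols)
  if (length(clean)) {
    Xc <- sweep(X[, clean, drop = FALSE], 2L, colMeans(X[, clean, drop = FALSE]))
    ssx <- colSums(Xc^2)
    A <- crossprod(Xc, Ync)           # m_clean x r
    q <- rowSums((A %*% Tinv) * A)
    lam <- 1 - q / ssx
    lam[ssx <= 0] <- NA_real_
    lambda[clean] <- lam
  }
  for (j in na_cols) {
    keep <- !is.na(X[, j])
    nj <- sum(keep)
    if (nj <= r + 2L) { lambda[j] <- NA_real_; next }
    Yj <- sweep(Yn[keep, , drop = FALSE], 2L, colMeans(Yn[keep, , drop = FALSE]))
    Tj <- crossprod(Yj)
    xj <- X[keep, j] - mean(X[keep, j])
    lambda[j] <- tryCatch(.wilks_one(Yj, chol2inv(chol(Tj)), xj),
                          error = function(e) NA_real_)
    # per-variant error df differs when individuals are dropped; handled below
    attr(lambda, "n_eff") <- c(attr(lambda, "n_eff"),
                               stats::setNames(nj, as.character(j)))
  }

  flagged <- is.na(lambda)
  lambda_c <- pmin(pmax(lambda, .Machine$double.eps), 1)
  n_eff <- rep(n, m)
  ne <- attr(lambda, "n_eff")
  if (!is.null(ne)) n_eff[as.integer(names(ne))] <- ne
  Fstat <- (1 - lambda_c) / lambda_c * (n_eff - 1 - r) / r
  p <- pf(Fstat, r, n_eff - 1 - r, lower.tail = FALSE)
  p[flagged] <- 1
  stat <- if (statistic == "wilks") lambda_c else 1 - lambda_c
  stat[flagged] <- if (statistic == "wilks") 1 else 0
  .new_scan(al$variant_ids, stat, p, "manova", flagged = flagged)
}

#' Per-phenotype univariate ANOVA scan
#'
#' Tests every variant against every phenotype one at a time with the
#' 1-df regression F-test of the additive allele-count term (equivalent to
#' the squared-correlation F, \eqn{F = (n-2) \rho^2 / (1 - \rho^2)}).
#' With `genotype_factor = TRUE` the genotype is instead treated as a
#' categorical factor (up to 3 levels, a 2-df one-way ANOVA).
#'
#' Zero-variance phenotypes are skipped with a warning; monomorphic variants
#' are flagged with p = 1. Returns one scan per phenotype plus a `min_p`
#' summary scan holding, per variant, the minimum p across phenotypes — a
#' ranking device for power comparisons, not a calibrated p-value.
#'
#' @param Y d x n phenotype matrix (rows = phenotypes).
#' @param genotypes an `agnep_genotypes` or n x m dosage matrix.
#' @param genotype_factor treat genotype as a categorical factor.
#' @return An object of class `agnep_anova`: list with `per_phenotype`
#'   (named list of `agnep_scan`) and `min_p` (summary `agnep_scan`).
#' @export
anova_scan <- function(Y, genotypes, genotype_factor = FALSE) {
  Y <- as.matrix(Y)
  al <- .align_responses(Y, genotypes)
  Yn <- al$Yn; X <- al$X
  n <- nrow(Yn); m <- ncol(X)
  if (n < 4L) stop("need at least 4 individuals", call. = FALSE)
  pheno_names <- colnames(Yn) %||% paste0("P", seq_len(ncol(Yn)))
  vars <- apply(Yn, 2L, var)
  if (any(vars == 0)) {
    warning(sprintf("skipping zero-variance phenotype(s): %s",
                    paste(pheno_names[vars == 0], collapse = ", ")), call. = FALSE)
  }
  keep_ph <- which(vars > 0)
  if (!length(keep_ph)) stop("no phenotype with nonzero variance", call. = FALSE)

  has_na <- anyNA(X)
  na_cols <- if (has_na) which(colSums(is.na(X)) > 0) else integer(0)
  clean <- setdiff(seq_len(m), na_cols)
  Xc <- NULL; ssx <- NULL
  if (length(clean)) {
    Xc <- sweep(X[, clean, drop = FALSE], 2L, colMeans(X[, clean, drop = FALSE]))
    ssx <- colSums(Xc^2)
  }

  scans <- vector("list", length(keep_ph))
  names(scans) <- pheno_names[keep_ph]
  for (ii in seq_along(keep_ph)) {
    i <- keep_ph[ii]
    y <- Yn[, i]
    p <- rep(1, m); Fst <- rep(0, m); flagged <- rep(FALSE, m)
    if (length(clean)) {
      if (genotype_factor) {
        res <- .anova_factor_vec(X[, clean, drop = FALSE], y)
        Fst[clean] <- res$F; p[clean] <- res$p; flagged[clean] <- res$flagged
      } else {
        yc <- y - mean(y)
        ssy <- sum(yc^2)
        r2 <- as.numeric(crossprod(Xc, yc))^2 / (ssx * ssy)
        bad <- ssx <= 0 | !is.finite(r2)
        r2 <- pmin(r2, 1 - 1e-15)
        Fv <- (n - 2) * r2 / (1 - r2)
        pv <- pf(Fv, 1, n - 2, lower.tail = FALSE)
        Fv[bad] <- 0; pv[bad] <- 1
        Fst[clean] <- Fv; p[clean] <- pv; flagged[clean] <- bad
      }
    }
    for (j in na_cols) {
      ok <- !is.na(X[, j])
      if (sum(ok) < 4L || var(X[ok, j]) == 0) { flagged[j] <- TRUE; next }
      fit <- if (genotype_factor) {
        stats::anova(stats::lm(y[ok] ~ factor(X[ok, j])))
      } else {
        stats::anova(stats::lm(y[ok] ~ X[ok, j]))
      }
      Fst[j] <- fit$`F value`[1L]; p[j] <- fit$`Pr(>F)`[1L]
    }
    scans[[ii]] <- .new_scan(al$variant_ids, Fst, p, "anova",
                             phenotype_label = pheno_names[i], flagged = flagged)
  }

  pmin_v <- Reduce(pmin, lapply(scans, function(s) s$p_value))
  minp <- .new_scan(al$variant_ids, statistic = rep(NA_real_, m),
                    p_value = pmin_v, scan_kind = "anova",
                    phenotype_label = "min_p")
  structure(list(per_phenotype = scans, min_p = minp), class = "agnep_anova")
}

# vectorized one-way ANOVA with genotype as a 3-level factor
.anova_factor_vec <- function(X, y) {
  n <- nrow(X); m <- ncol(X)
  counts <- matrix(vapply(0:2, function(g) colSums(X == g), numeric(m)),
                   nrow = m, ncol = 3L)
  sums <- matrix(vapply(0:2, function(g) colSums((X == g) * y), numeric(m)),
                 nrow = m, ncol = 3L)
  gmean <- mean(y)
  tss <- sum((y - gmean)^2)
  with_counts <- counts > 0
  glev <- rowSums(with_counts)
  means <- ifelse(counts > 0, sums / counts, 0)
  ssb <- rowSums(counts * (means - gmean)^2)
  ssw <- pmax(tss - ssb, 0)
  df1 <- glev - 1
  df2 <- n - glev
  flagged <- df1 < 1 | df2 < 1
  Fv <- ifelse(flagged, 0, (ssb / pmax(df1, 1)) / (ssw / pmax(df2, 1)))
  pv <- ifelse(flagged, 1, pf(Fv, pmax(df1, 1), pmax(df2, 1), lower.tail = FALSE))
  list(F = Fv, p = pv, flagged = flagged)
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' Returns \eqn{-\log_{10}(\alpha / n_{tests})}; e.g. testing 206603
#' variants at alpha = 0.001 gives 8.3151.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return The corrected threshold on the -log10 p scale.
#' @examples
#' bonferroni_threshold(0.001, 206603)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  alpha <- .assert_fraction(alpha, "alpha")
  n_tests <- .assert_scalar_count(n_tests, "n_tests")
  -log10(alpha / n_tests)
}
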