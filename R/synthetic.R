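#' Simulate biallelic genotypes under Hardy-Weinberg equilibrium
#'
#' Draws, for each variant, a minor-allele frequency uniformly from
#' `maf_range` and then samples minor-allele counts for `n` individuals with
#' Hardy-Weinberg genotype probabilities \eqn{((1-p)^2, 2p(1-p), p^2)}.
#' Variants are mutually independent (no linkage disequilibrium).
#'
#' @param n number of individuals (>= 2).
#' @param m number of variants (>= 1).
#' @param maf_range length-2 numeric interval within (0, 0.5]; the default
#'   \[0.1, 0.5\] matches the simulation designs this package benchmarks.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   output.
#' @return An object of class `agnep_genotypes`: a list with `values`
#'   (n x m integer matrix of minor-allele counts), `maf` (the drawn
#'   frequencies), `variant_ids`, and `individual_ids`.
#' @examples
#' g <- simulate_genotypes(100, 20, seed = 1)
#' range(g$maf)
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.1, 0.5), seed = NULL) {
  n <- .assert_scalar_count(n, "n", min = 2L)
  m <- .assert_scalar_count(m, "m", min = 1L)
  if (!is.numeric(maf_range) || length(maf_range) != 2L || anyNA(maf_range)) {
    stop("`maf_range` must be a numeric interval c(lo, hi)", call. = FALSE)
  }
  if (maf_range[1L] > maf_range[2L]) {
    stop("`maf_range` is empty: lower bound exceeds upper bound", call. = FALSE)
  }
  if (maf_range[1L] <= 0) {
    stop("`maf_range` lower bound must be > 0 (minor-allele frequency)",
         call. = FALSE)
  }
  if (maf_range[2L] > 0.5) {
    stop("`maf_range` upper bound must be <= 0.5 (minor-allele frequency)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  maf <- runif(m, maf_range[1L], maf_range[2L])
  # minor-allele count is Binomial(2, p) under HWE
  values <- matrix(rbinom(n * m, size = 2L, prob = rep(maf, each = n)),
                   nrow = n, ncol = m)
  storage.mode(values) <- "integer"
  new_genotypes(values, maf = maf,
                variant_ids = paste0("V", seq_len(m)),
                individual_ids = paste0("I", seq_len(n)))
}

#' Construct a genotype container
#'
#' @param values n x m matrix of minor-allele counts in \{0, 1, 2\}
#'   (NA allowed for missing calls in real data).
#' @param maf per-variant minor-allele frequency in (0, 0.5]; computed from
#'   `values` when omitted.
#' @param variant_ids,individual_ids identifiers; defaults are generated.
#' @return An `agnep_genotypes` object.
#' @export
new_genotypes <- function(values, maf = NULL, variant_ids = NULL,
                          individual_ids = NULL) {
  values <- as.matrix(values)
  ok <- values %in% c(0L, 1L, 2L) | is.na(values)
  if (!all(ok)) {
    stop("genotype values must be minor-allele counts 0, 1 or 2 (or NA)",
         call. = FALSE)
  }
  n <- nrow(values); m <- ncol(values)
  if (is.null(maf)) maf <- colMeans(values, na.rm = TRUE) / 2
  variant_ids <- variant_ids %||% colnames(values) %||% paste0("V", seq_len(m))
  individual_ids <- individual_ids %||% rownames(values) %||% paste0("I", seq_len(n))
  if (length(maf) != m || length(variant_ids) != m) {
    stop("`maf` and `variant_ids` must match the number of genotype columns",
         call. = FALSE)
  }
  if (length(individual_ids) != n) {
    stop("`individual_ids` must match the number of genotype rows", call. = FALSE)
  }
  dimnames(values) <- list(individual_ids, variant_ids)
  structure(list(values = values, maf = as.numeric(maf),
                 variant_ids = as.character(variant_ids),
                 individual_ids = as.character(individual_ids)),
            class = "agnep_genotypes")
}

#' @export
print.agnep_genotypes <- function(x, ...) {
  cat(sprintf("agnep_genotypes: %d individuals x %d variants, MAF in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), min(x$maf), max(x$maf)))
  invisible(x)
}

# Group index sets of the three simulation designs. I: five disjoint blocks
# of four phenotypes; II: five blocks with pairwise overlaps (1&2 share
# {4,5}, 4&5 share {16,17,18}); III: eight overlapping blocks over 100
# phenotypes.
.design_groups <- list(
  simI   = list(1:4, 5:8, 9:12, 13:16, 17:20),
  simII  = list(1:5, 4:8, 9:12, 13:18, 16:20),
  simIII = list(1:15, 10:30, 31:40, 41:60, 61:75, 70:90, 85:95, 90:100)
)

#' Build a synthetic simulation design
#'
#' Returns a full specification of one of the three benchmark phenotype
#' architectures: `simI` (five independent groups of four phenotypes),
#' `simII` (five groups with overlapping phenotypes), and `simIII` (eight
#' overlapping groups over 100 phenotypes). Causal variants (QTNs) are drawn
#' uniformly without replacement and assigned to groups round-robin so every
#' group carries signal in both the 10- and 50-QTN scenarios.
#'
#' Effect sizes are parameterized through `qtn_variance_frac`: each QTN's
#' allele-count effect is sized at simulation time so it explains that
#' fraction of the baseline (factor + residual) phenotype variance.
#'
#' @param preset one of `"simI"`, `"simII"`, `"simIII"`.
#' @param n_qtn number of causal variants (10 and 50 are the benchmark
#'   scenarios; any positive count is accepted).
#' @param n,m number of individuals and variants (defaults 5000 and 10000).
#' @param maf_range minor-allele frequency interval for the paired genotypes.
#' @param qtn_variance_frac per-QTN fraction of baseline phenotype variance
#'   explained (default 0.005, i.e. 0.5%).
#' @param loading factor loading given to each phenotype for every group that
#'   contains it (default 0.8).
#' @param mixed_sign if TRUE, loadings alternate in sign within each group so
#'   that negative between-phenotype correlations are induced.
#' @param residual_sd residual standard deviation sigma (default 0.6, so a
#'   one-group phenotype has baseline variance 0.8^2 + 0.6^2 = 1).
#' @param residual_cov optional d x d positive semi-definite residual
#'   covariance; overrides `residual_sd` when supplied.
#' @param seed integer seed used to draw the QTN positions.
#' @return An object of class `agnep_design`.
#' @examples
#' d <- make_design("simI", n_qtn = 10, seed = 1)
#' lengths(d$groups)
#' @export
make_design <- function(preset, n_qtn = 10, n = 5000, m = 10000,
                        maf_range = c(0.1, 0.5),
                        qtn_variance_frac = 0.005, loading = 0.8,
                        mixed_sign = FALSE, residual_sd = 0.6,
                        residual_cov = NULL, seed = NULL) {
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(.design_groups)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 as.character(preset)[1L],
                 paste(names(.design_groups), collapse = ", ")), call. = FALSE)
  }
  n_qtn <- .assert_scalar_count(n_qtn, "n_qtn")
  n <- .assert_scalar_count(n, "n", min = 2L)
  m <- .assert_scalar_count(m, "m")
  if (n_qtn > m) stop("`n_qtn` cannot exceed the number of variants `m`", call. = FALSE)
  groups <- .design_groups[[preset]]
  d <- max(unlist(groups))
  if (!is.null(residual_cov)) {
    residual_cov <- as.matrix(residual_cov)
    if (nrow(residual_cov) != d || ncol(residual_cov) != d ||
        !isSymmetric(unname(residual_cov), tol = 1e-8)) {
      stop("`residual_cov` must be a symmetric d x d matrix", call. = FALSE)
    }
    ev <- eigen(residual_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      stop("`residual_cov` must be positive semi-definite", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  qtn_indices <- sort(sample.int(m, n_qtn))
  qtn_group_map <- rep_len(seq_along(groups), n_qtn)

  # loadings matrix: lambda for members of each group, 0 elsewhere; under
  # mixed signs the loading alternates sign along the group's members
  L <- matrix(0, nrow = d, ncol = length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    sgn <- if (mixed_sign) rep_len(c(1, -1), length(idx)) else 1
    L[idx, g] <- loading * sgn
  }

  structure(list(preset = preset, n_individuals = n, n_variants = m,
                 n_phenotypes = d, maf_range = maf_range, groups = groups,
                 qtn_indices = qtn_indices, qtn_group_map = qtn_group_map,
                 effect_sizes = NULL, qtn_variance_frac = qtn_variance_frac,
                 loadings = L, mixed_sign = mixed_sign,
                 residual_sd = residual_sd, residual_cov = residual_cov,
                 seed = seed),
            class = "agnep_design")
}

#' @export
print.agnep_design <- function(x, ...) {
  cat(sprintf("agnep_design '%s': d = %d phenotypes in %d groups, %d QTNs, n = %d, m = %d\n",
              x$preset, x$n_phenotypes, length(x$groups),
              length(x$qtn_indices), x$n_individuals, x$n_variants))
  invisible(x)
}

#' Simulate phenotypes from a factor model with causal variants
#'
#' Generates the phenotype matrix under the additive factor model
#' \deqn{y_{ij} = \sum_{q: i \in S_{g(q)}} \beta_q x_{qj}
#'       + \sum_{g: i \in S_g} \lambda_{ig} f_{gj} + e_{ij}}
#' where each group g has a latent factor \eqn{f_g} that is i.i.d. standard
#' normal over individuals, \eqn{S_g} is the set of phenotypes in group g,
#' each QTN q is assigned to one group and affects all its member phenotypes,
#' and residuals are i.i.d. N(0, sigma^2) (or draws from `residual_cov` when
#' the design carries one). Unless explicit `effect_sizes` are set on the
#' design, each QTN's effect is sized as
#' \eqn{\beta_q = \sqrt{h \, v_0 / (2 p_q (1 - p_q))}} with h the design's
#' `qtn_variance_frac` and \eqn{v_0} the baseline (factor + residual)
#' variance of a one-group phenotype.
#'
#' @param genotypes an `agnep_genotypes` object matching the design's
#'   dimensions.
#' @param design an `agnep_design` from [make_design()].
#' @param seed optional integer seed.
#' @return A list with `phenotypes` (d x n matrix, phenotypes as rows) and
#'   `truth` (class `agnep_truth`: QTN ids/indices, per-phenotype realized
#'   effects, group structure).
#' @examples
#' des <- make_design("simI", n_qtn = 10, n = 200, m = 100, seed = 1)
#' g <- simulate_genotypes(200, 100, seed = 1)
#' sim <- simulate_phenotypes(g, des, seed = 2)
#' dim(sim$phenotypes)
#' @export
simulate_phenotypes <- function(genotypes, design, seed = NULL) {
  stopifnot(inherits(genotypes, "agnep_genotypes"),
            inherits(design, "agnep_design"))
  n <- nrow(genotypes$values); m <- ncol(genotypes$values)
  if (n != design$n_individuals) {
    stop(sprintf("individual axis mismatch: genotypes have %d rows, design expects %d",
                 n, design$n_individuals), call. = FALSE)
  }
  if (m != design$n_variants) {
    stop(sprintf("variant axis mismatch: genotypes have %d columns, design expects %d",
                 m, design$n_variants), call. = FALSE)
  }
  if (length(design$qtn_indices) &&
      (max(design$qtn_indices) > m || min(design$qtn_indices) < 1L)) {
    stop("QTN indices fall outside the variant axis", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- design$n_phenotypes
  G <- length(design$groups)

  # latent group factors and residuals
  f <- matrix(rnorm(G * n), nrow = G, ncol = n)
  Y <- design$loadings %*% f
  if (!is.null(design$residual_cov)) {
    ev <- eigen(design$residual_cov, symmetric = TRUE)
    root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    Y <- Y + root %*% matrix(rnorm(d * n), nrow = d)
  } else {
    Y <- Y + design$residual_sd * matrix(rnorm(d * n), nrow = d)
  }

  # genetic effects: QTN q hits every phenotype of its assigned group
  q_idx <- design$qtn_indices
  betas <- numeric(length(q_idx))
  effects <- matrix(0, nrow = length(q_idx), ncol = d)
  if (length(q_idx)) {
    # baseline variance of a phenotype that belongs to exactly one group
    lam <- max(abs(design$loadings))
    v0 <- lam^2 + if (is.null(design$residual_cov)) design$residual_sd^2 else
      mean(diag(design$residual_cov))
    for (k in seq_along(q_idx)) {
      q <- q_idx[k]
      p <- genotypes$maf[q]
      beta <- if (!is.null(design$effect_sizes)) design$effect_sizes[k] else
        sqrt(design$qtn_variance_frac * v0 / (2 * p * (1 - p)))
      betas[k] <- beta
      members <- design$groups[[design$qtn_group_map[k]]]
      x <- as.numeric(genotypes$values[, q])
      Y[members, ] <- Y[members, , drop = FALSE] +
        matrix(beta * x, nrow = length(members), ncol = n, byrow = TRUE)
      effects[k, members] <- beta
    }
  }
  dimnames(Y) <- list(paste0("P", seq_len(d)), genotypes$individual_ids)
  truth <- structure(list(qtn_indices = q_idx,
                          qtn_ids = genotypes$variant_ids[q_idx],
                          qtn_betas = betas,
                          qtn_effects = effects,
                          qtn_group_map = design$qtn_group_map,
                          group_structure = design$groups),
                     class = "agnep_truth")
  list(phenotypes = Y, truth = truth)
}

#' @export
print.agnep_truth <- function(x, ...) {
  cat(sprintf("agnep_truth: %d QTNs across %d groups\n",
              length(x$qtn_indices), length(x$group_structure)))
  invisible(x)
}
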