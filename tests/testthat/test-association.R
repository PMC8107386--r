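test_that("a single representative reduces MANOVA to the univariate F-test", {
  set.seed(51)
  n <- 80; m <- 25
  g <- simulate_genotypes(n, m, seed = 51)
  y <- rnorm(n) + 0.4 * g$values[, 3]
  Y1 <- matrix(y, nrow = 1, dimnames = list("rep1", g$individual_ids))
  mv <- manova_scan(Y1, g)
  uni <- anova_scan(Y1, g)$per_phenotype[[1]]
  expect_equal(mv$p_value, uni$p_value, tolerance = 1e-10)
  # independent oracle: per-variant lm F-test
  for (j in c(1, 3, 10)) {
    fit <- stats::anova(stats::lm(y ~ g$values[, j]))
    expect_equal(mv$p_value[j], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("Wilks' lambda matches hand-built cross-product matrices on a toy set", {
  # n = 12 individuals, r = 2 representatives, one variant
  x <- c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2, 0, 1)
  set.seed(52)
  Y <- rbind(r1 = 0.5 * x + rnorm(12), r2 = -0.3 * x + rnorm(12))
  # oracle: E from the full model fit, T from the intercept-only model
  n <- 12
  Yn <- t(Y)
  Xd <- cbind(1, x)
  B <- solve(crossprod(Xd), crossprod(Xd, Yn))
  E <- crossprod(Yn - Xd %*% B)
  Tm <- crossprod(sweep(Yn, 2, colMeans(Yn)))
  lambda_hand <- det(E) / det(Tm)
  F_hand <- (1 - lambda_hand) / lambda_hand * (n - 1 - 2) / 2
  p_hand <- pf(F_hand, 2, n - 1 - 2, lower.tail = FALSE)

  g <- new_genotypes(matrix(x, ncol = 1), variant_ids = "V1",
                     individual_ids = paste0("I", 1:12))
  colnames(Y) <- paste0("I", 1:12)
  sc <- manova_scan(Y, g)
  expect_equal(sc$statistic, lambda_hand, tolerance = 1e-12)
  expect_equal(sc$p_value, p_hand, tolerance = 1e-12)

  # second oracle: base R manova with Wilks test
  fit <- summary(stats::manova(Yn ~ x), test = "Wilks")
  expect_equal(sc$statistic, fit$stats[1, "Wilks"], tolerance = 1e-10)
  expect_equal(sc$p_value, fit$stats[1, "Pr(>F)"], tolerance = 1e-10)

  # Pillai option: V = 1 - lambda with the same p-value when the hypothesis
  # has one degree of freedom
  scp <- manova_scan(Y, g, statistic = "pillai")
  expect_equal(scp$statistic, 1 - lambda_hand, tolerance = 1e-12)
  expect_equal(scp$p_value, sc$p_value, tolerance = 1e-12)
})

test_that("manova_scan agrees with stats::manova across random variants", {
  s <- tiny_sim("simI", n = 60, m = 15, seed = 53)
  reps <- build_representatives(s$Y, rep(1:5, each = 4), method = "mean")
  sc <- manova_scan(reps, s$geno)
  Yn <- t(reps$values)
  for (j in c(2, 7, 14)) {
    x <- s$geno$values[, j]
    fit <- summary(stats::manova(Yn ~ x), test = "Wilks")
    expect_equal(sc$statistic[j], unname(fit$stats[1, "Wilks"]), tolerance = 1e-10)
    expect_equal(sc$p_value[j], unname(fit$stats[1, "Pr(>F)"]), tolerance = 1e-10)
  }
  expect_equal(sc$neg_log10_p, -log10(sc$p_value))
  expect_true(all(sc$statistic > 0 & sc$statistic <= 1))
})

test_that("monomorphic variants are flagged with p = 1", {
  set.seed(54)
  X <- cbind(rep(1L, 40), rbinom(40, 2, 0.3))
  g <- new_genotypes(X, maf = c(0.5, 0.3))
  Y <- matrix(rnorm(80), nrow = 2, dimnames = list(NULL, rownames(X)))
  sc <- manova_scan(Y, g)
  expect_true(sc$flagged[1])
  expect_equal(sc$p_value[1], 1)
  expect_false(sc$flagged[2])
  av <- anova_scan(Y, g)
  expect_equal(av$per_phenotype[[1]]$p_value[1], 1)
})

test_that("p-values are invariant to joint relabeling and affine response changes", {
  s <- tiny_sim("simI", n = 100, m = 20, seed = 55)
  reps <- build_representatives(s$Y, rep(1:5, each = 4), method = "pca")
  base <- manova_scan(reps, s$geno)

  perm <- sample(100)
  Yp <- reps$values[, perm]
  gp <- new_genotypes(s$geno$values[perm, ],
                      variant_ids = s$geno$variant_ids,
                      individual_ids = s$geno$individual_ids[perm])
  colnames(Yp) <- gp$individual_ids
  expect_equal(manova_scan(Yp, gp)$p_value, base$p_value, tolerance = 1e-10)

  Ya <- reps$values
  Ya[1, ] <- 5 * Ya[1, ] - 3
  Ya[3, ] <- -0.2 * Ya[3, ] + 100
  expect_equal(manova_scan(Ya, s$geno)$p_value, base$p_value, tolerance = 1e-8)
})

test_that("rank-deficient representatives are rejected naming the collinear rows", {
  s <- tiny_sim("simI", n = 50, m = 10, seed = 56)
  R <- rbind(a = rnorm(50), b = rnorm(50))
  R <- rbind(R, dup = R["a", ] + R["b", ])
  colnames(R) <- s$geno$individual_ids
  expect_error(manova_scan(R, s$geno), "rank-deficient")
  expect_error(manova_scan(R[, 1:4], new_genotypes(s$geno$values[1:4, ])),
               "n > r \\+ 2")
})

test_that("anova_scan matches lm oracles, skips flat phenotypes, and min-p summarizes", {
  set.seed(57)
  n <- 70; m <- 12
  g <- simulate_genotypes(n, m, seed = 57)
  Y <- rbind(P1 = rnorm(n) + 0.5 * g$values[, 2],
             P2 = rnorm(n),
             FLAT = rep(1, n))
  colnames(Y) <- g$individual_ids
  expect_warning(av <- anova_scan(Y, g), "FLAT")
  expect_named(av$per_phenotype, c("P1", "P2"))
  for (j in c(2, 5)) {
    fit <- stats::anova(stats::lm(Y["P1", ] ~ g$values[, j]))
    expect_equal(av$per_phenotype$P1$p_value[j], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(av$min_p$p_value,
               pmin(av$per_phenotype$P1$p_value, av$per_phenotype$P2$p_value))
  expect_identical(av$min_p$phenotype_label, "min_p")

  # genotype-as-factor option against the lm factor oracle
  avf <- suppressWarnings(anova_scan(Y, g, genotype_factor = TRUE))
  for (j in c(1, 4, 9)) {
    fit <- stats::anova(stats::lm(Y["P1", ] ~ factor(g$values[, j])))
    expect_equal(avf$per_phenotype$P1$p_value[j], fit$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("missing genotype calls are dropped per variant", {
  set.seed(58)
  n <- 60
  g0 <- simulate_genotypes(n, 6, seed = 58)
  X <- g0$values
  X[c(3, 10, 20), 2] <- NA
  g <- new_genotypes(X, maf = g0$maf)
  Y <- rbind(r1 = rnorm(n), r2 = rnorm(n))
  colnames(Y) <- g$individual_ids
  sc <- manova_scan(Y, g)
  ok <- !is.na(X[, 2])
  fit <- summary(stats::manova(t(Y[, ok]) ~ X[ok, 2]), test = "Wilks")
  expect_equal(sc$p_value[2], unname(fit$stats[1, "Pr(>F)"]), tolerance = 1e-10)

  av <- anova_scan(Y, g)
  fit1 <- stats::anova(stats::lm(Y["r1", ok] ~ X[ok, 2]))
  expect_equal(av$per_phenotype$r1$p_value[2], fit1$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("null ANOVA p-values are approximately uniform", {
  set.seed(59)
  n <- 400; m <- 2000
  g <- simulate_genotypes(n, m, seed = 59)
  Y <- matrix(rnorm(n), nrow = 1, dimnames = list("P1", g$individual_ids))
  av <- anova_scan(Y, g)
  ks <- suppressWarnings(stats::ks.test(av$min_p$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("bonferroni_threshold follows -log10(alpha / n)", {
  expect_equal(bonferroni_threshold(0.05, 1), 1.3010, tolerance = 1e-4)
  t1 <- bonferroni_threshold(0.01, 1000)
  t2 <- bonferroni_threshold(0.01, 2000)
  expect_equal(t2 - t1, log10(2), tolerance = 1e-12)
  expect_error(bonferroni_threshold(1.5, 10), "fraction")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})
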