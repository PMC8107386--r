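test_that("simulate_genotypes draws HWE genotypes with MAF in range", {
  g <- simulate_genotypes(5000, 50, maf_range = c(0.1, 0.5), seed = 7)
  expect_true(all(g$values %in% 0:2))
  expect_true(all(g$maf >= 0.1 & g$maf <= 0.5))
  expect_identical(dim(g$values), c(5000L, 50L))
  expect_length(g$variant_ids, 50)

  # p = 0.5 variant: realized genotype counts pass a HWE chi-square GOF
  g5 <- simulate_genotypes(5000, 1, maf_range = c(0.5, 0.5), seed = 11)
  counts <- tabulate(g5$values + 1L, nbins = 3L)
  expected <- 5000 * c(0.25, 0.5, 0.25)
  chisq <- sum((counts - expected)^2 / expected)
  expect_gt(stats::pchisq(chisq, df = 2, lower.tail = FALSE), 0.01)
})

test_that("genotype column frequencies converge to the drawn maf", {
  g <- simulate_genotypes(2000, 100, seed = 3)
  freq <- colMeans(g$values) / 2
  sds <- sqrt(g$maf * (1 - g$maf) / (2 * 2000))
  z <- abs(freq - g$maf) / sds
  # per-variant z-scores behave like half-normals: ~99.7% inside 3 SDs
  expect_gte(mean(z <= 3), 0.97)
  expect_true(all(z <= 5))
})

test_that("simulate_genotypes is deterministic and validates maf_range", {
  a <- simulate_genotypes(100, 30, seed = 5)
  b <- simulate_genotypes(100, 30, seed = 5)
  expect_identical(a$values, b$values)
  expect_identical(a$maf, b$maf)
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.5)), "lower bound")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0.1, 0.6)), "upper bound")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0.4, 0.2)), "empty")
})

test_that("make_design reproduces the three group structures", {
  d1 <- make_design("simI", n_qtn = 10, seed = 1)
  expect_length(d1$groups, 5)
  expect_true(all(lengths(d1$groups) == 4))
  expect_identical(d1$groups, list(1:4, 5:8, 9:12, 13:16, 17:20))
  expect_equal(d1$n_phenotypes, 20)

  d2 <- make_design("simII", n_qtn = 10, seed = 1)
  expect_identical(intersect(d2$groups[[1]], d2$groups[[2]]), 4:5)
  expect_identical(intersect(d2$groups[[4]], d2$groups[[5]]), 16:18)
  expect_true(all(vapply(seq_along(d2$groups)[-3], function(g)
    length(intersect(d2$groups[[3]], d2$groups[[g]])) == 0, logical(1))))

  d3 <- make_design("simIII", n_qtn = 50, seed = 1)
  expect_length(d3$groups, 8)
  expect_identical(sort(unique(unlist(d3$groups))), 1:100)
  expect_identical(d3$groups[[1]], 1:15)
  expect_identical(d3$groups[[2]], 10:30)
  expect_identical(d3$groups[[8]], 90:100)

  expect_error(make_design("simIV", 10), "simI, simII, simIII")
})

test_that("QTNs are distinct, in range, and spread round-robin over groups", {
  for (nq in c(10L, 50L)) {
    d <- make_design("simII", n_qtn = nq, m = 200, seed = 2)
    expect_length(unique(d$qtn_indices), nq)
    expect_true(all(d$qtn_indices >= 1 & d$qtn_indices <= 200))
    expect_identical(d$qtn_group_map, rep_len(1:5, nq))
    expect_true(all(table(factor(d$qtn_group_map, levels = 1:5)) >= 1))
  }
})

test_that("zero loadings and no genetic effect give independent phenotypes", {
  des <- make_design("simI", n_qtn = 1, n = 2000, m = 20, loading = 0,
                     qtn_variance_frac = 0, seed = 4)
  g <- simulate_genotypes(2000, 20, seed = 4)
  sim <- simulate_phenotypes(g, des, seed = 5)
  C <- cor(t(sim$phenotypes))
  expect_true(max(abs(C[upper.tri(C)])) < 0.1)
})

test_that("simI phenotypes have within-group correlation exceeding between-group", {
  s <- tiny_sim("simI", n = 1000, m = 40, seed = 9)
  C <- cor(t(s$Y))
  groups <- s$design$groups
  within <- unlist(lapply(groups, function(gr) {
    cc <- C[gr, gr]; cc[upper.tri(cc)]
  }))
  between <- c()
  for (a in 1:4) for (b in (a + 1):5) {
    between <- c(between, as.vector(C[groups[[a]], groups[[b]]]))
  }
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.4)
})

test_that("phenotype variance matches the closed-form decomposition", {
  # single phenotype, one group, one QTN: var = beta^2 2p(1-p) + lambda^2 + sigma^2
  beta <- 0.4; lambda <- 0.7; sigma <- 0.5; n <- 5000
  des <- structure(list(preset = "custom", n_individuals = n, n_variants = 3L,
                        n_phenotypes = 1L, maf_range = c(0.3, 0.3),
                        groups = list(1L), qtn_indices = 2L, qtn_group_map = 1L,
                        effect_sizes = beta, qtn_variance_frac = NA,
                        loadings = matrix(lambda, 1, 1), mixed_sign = FALSE,
                        residual_sd = sigma, residual_cov = NULL, seed = 1L),
                   class = "agnep_design")
  g <- simulate_genotypes(n, 3, maf_range = c(0.3, 0.3), seed = 21)
  sim <- simulate_phenotypes(g, des, seed = 22)
  p <- g$maf[2]
  expected <- beta^2 * 2 * p * (1 - p) + lambda^2 + sigma^2
  expect_lt(abs(var(as.numeric(sim$phenotypes)) - expected) / expected, 0.05)
  # realized truth records the effect on the right phenotype
  expect_identical(sim$truth$qtn_ids, g$variant_ids[2])
  expect_equal(sim$truth$qtn_effects[1, 1], beta)
})

test_that("mixed-sign loadings induce negative between-phenotype correlations", {
  s <- tiny_sim("simII", n = 500, m = 30, seed = 12, mixed_sign = TRUE)
  C <- cor(t(s$Y))
  expect_lt(min(C[upper.tri(C)]), -0.2)
})

test_that("phenotype simulation is reproducible and checks dimensions", {
  des <- make_design("simI", n_qtn = 3, n = 100, m = 30, seed = 1)
  g <- simulate_genotypes(100, 30, seed = 1)
  a <- simulate_phenotypes(g, des, seed = 9)
  b <- simulate_phenotypes(g, des, seed = 9)
  expect_identical(a$phenotypes, b$phenotypes)
  g_bad <- simulate_genotypes(90, 30, seed = 1)
  expect_error(simulate_phenotypes(g_bad, des), "individual axis")
  g_bad2 <- simulate_genotypes(100, 29, seed = 1)
  expect_error(simulate_phenotypes(g_bad2, des), "variant axis")
})

test_that("residual covariance must be symmetric positive semi-definite", {
  V_bad <- matrix(rnorm(400), 20, 20)
  expect_error(make_design("simI", 10, residual_cov = V_bad), "symmetric")
  V_nsd <- diag(20); V_nsd[1, 1] <- -1
  expect_error(make_design("simI", 10, residual_cov = V_nsd),
               "positive semi-definite")
  V_ok <- diag(0.25, 20)
  des <- make_design("simI", n_qtn = 2, n = 2000, m = 10, loading = 0,
                     qtn_variance_frac = 0, residual_cov = V_ok, seed = 3)
  g <- simulate_genotypes(2000, 10, seed = 3)
  sim <- simulate_phenotypes(g, des, seed = 4)
  v <- apply(sim$phenotypes, 1, var)
  expect_true(all(abs(v - 0.25) / 0.25 < 0.2))
})
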