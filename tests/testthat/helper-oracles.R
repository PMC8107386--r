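# independent brute-force oracles used across the suite; each is a direct,
# unoptimized transcription of the defining formula, never sharing code with
# the implementation it checks.

# elementwise double-loop Euclidean distance between matrix rows
brute_distance <- function(Y) {
  d <- nrow(Y)
  D <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      D[i, j] <- sqrt(sum((Y[i, ] - Y[j, ])^2))
    }
  }
  D
}

# silhouette per sample from the definition; `singleton` as in silhouette()
brute_silhouette <- function(D, labels, singleton = "unit") {
  d <- nrow(D)
  s <- numeric(d)
  for (i in seq_len(d)) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- if (length(own) == 0L) 0 else sum(D[i, own]) / length(own)
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == k)
      b <- min(b, sum(D[i, mem]) / length(mem))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(b, a)
    if (singleton == "zero" && length(own) == 0L) s[i] <- 0
  }
  s
}

# exhaustive power-at-FDR from scratch: enumerate every cut rank
brute_power_curve <- function(p, is_qtn, fdr_grid) {
  ord <- order(p)
  n_qtn <- sum(is_qtn)
  vapply(fdr_grid, function(f) {
    best <- 0
    for (t in seq_along(ord)) {
      top <- ord[seq_len(t)]
      fdr <- sum(!is_qtn[top]) / t
      if (fdr <= f) best <- max(best, sum(is_qtn[top]) / n_qtn)
    }
    best
  }, numeric(1L))
}

# canonical form of a partition label vector: clusters numbered by first
# appearance, so label-permuted partitions compare equal
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

# a random phenotype matrix whose rows give all-distinct pairwise distances
random_phenotypes <- function(d, n, seed) {
  set.seed(seed)
  matrix(rnorm(d * n), nrow = d,
         dimnames = list(paste0("P", seq_len(d)), paste0("I", seq_len(n))))
}

# small simulated dataset used by several files
tiny_sim <- function(preset = "simI", n = 300, m = 60, n_qtn = 5, seed = 42, ...) {
  design <- make_design(preset, n_qtn = n_qtn, n = n, m = m, seed = seed, ...)
  geno <- simulate_genotypes(n, m, design$maf_range, seed = seed + 1L)
  sim <- simulate_phenotypes(geno, design, seed = seed + 2L)
  list(design = design, geno = geno, Y = sim$phenotypes, truth = sim$truth)
}
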