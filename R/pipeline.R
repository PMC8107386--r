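# run configuration and the orchestrating pipeline:
# cluster -> represent -> scan (-> permutation threshold), with provenance
# headers (seed + config hash) on every output file.

#' Build a validated run configuration
#'
#' @param genotype_path,phenotype_path input files (see [read_genotypes()],
#'   [read_phenotypes()]).
#' @param out_dir output directory, created if needed.
#' @param method representative construction: `"pca"`, `"mean"`, `"median"`.
#' @param linkage clustering linkage.
#' @param K `"auto"` (silhouette selection) or a fixed integer.
#' @param cum_threshold cumulative explained-variance threshold for PCA
#'   representatives.
#' @param statistic MANOVA statistic, `"wilks"` or `"pillai"`.
#' @param alpha significance level used for the permutation threshold.
#' @param n_perm permutations for the genome-wide threshold; 0 disables the
#'   permutation stage.
#' @param filter_maf,maf_min genotype MAF filtering (see [read_genotypes()]).
#' @param seed integer seed recorded in every output header.
#' @return A validated list of class `agnep_config`.
#' @export
agnep_config <- function(genotype_path, phenotype_path, out_dir,
                         method = c("pca", "mean", "median"),
                         linkage = c("single", "complete", "average"),
                         K = "auto", cum_threshold = 0.85,
                         statistic = c("wilks", "pillai"),
                         alpha = 0.05, n_perm = 10,
                         filter_maf = FALSE, maf_min = 0.05, seed = 1L) {
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  statistic <- match.arg(statistic)
  cum_threshold <- .assert_fraction(cum_threshold, "cum_threshold")
  alpha <- .assert_fraction(alpha, "alpha")
  if (!identical(K, "auto")) K <- .assert_scalar_count(K, "K")
  n_perm <- .assert_scalar_count(n_perm, "n_perm", min = 0L)
  seed <- .assert_scalar_count(seed, "seed", min = 0L)
  structure(list(genotype_path = genotype_path, phenotype_path = phenotype_path,
                 out_dir = out_dir, method = method, linkage = linkage, K = K,
                 cum_threshold = cum_threshold, statistic = statistic,
                 alpha = alpha, n_perm = n_perm, filter_maf = filter_maf,
                 maf_min = maf_min, seed = seed),
            class = "agnep_config")
}

#' Read a run configuration from a JSON file
#'
#' Missing fields take the [agnep_config()] defaults.
#'
#' @param path JSON file with `agnep_config` fields.
#' @return An `agnep_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(agnep_config, raw)
}

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL     # identical analyses into different directories hash equal
  .fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE))
}

#' Run the full association pipeline
#'
#' Executes, in order: read and align inputs, cluster the phenotypes
#' (silhouette-selected K unless fixed), build representative phenotypes,
#' scan every variant with MANOVA, and (when `n_perm > 0`) compute the
#' permutation genome-wide threshold. Writes `clusters.tsv`,
#' `silhouette.tsv`, `reps.tsv`, `scan.tsv`, `threshold.txt`, and
#' `manifest.json` into the output directory; every TSV carries a header
#' comment with the seed and the configuration hash, so reruns with an
#' identical manifest are byte-identical.
#'
#' @param config an `agnep_config`.
#' @return The output directory, invisibly; the stage results are attached
#'   as the attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "agnep_config"))
  stage <- "read inputs"
  res <- tryCatch({
    geno <- read_genotypes(config$genotype_path, filter_maf = config$filter_maf,
                           maf_min = config$maf_min)
    Y <- read_phenotypes(config$phenotype_path)
    shared <- intersect(colnames(Y), geno$individual_ids)
    if (length(shared) < 4L) {
      stop("fewer than 4 individuals shared between genotype and phenotype files",
           call. = FALSE)
    }
    n_unmatched <- (ncol(Y) - length(shared)) +
      (length(geno$individual_ids) - length(shared))
    if (n_unmatched > 0L) {
      message(sprintf("dropped %d unmatched individual id(s); %d shared retained",
                      n_unmatched, length(shared)))
    }
    Y <- Y[, shared, drop = FALSE]
    geno <- new_genotypes(geno$values[match(shared, geno$individual_ids), ,
                                      drop = FALSE],
                          variant_ids = geno$variant_ids,
                          individual_ids = shared)

    stage <- "cluster"
    D <- phenotype_distance_matrix(Y)
    if (identical(config$K, "auto")) {
      sel <- select_k(D, linkage = config$linkage)
      part <- sel$partition; s_by_k <- sel$s_by_k
    } else {
      part <- agnes(D, config$K, linkage = config$linkage)
      s_by_k <- stats::setNames(silhouette(D, part)$mean_s, config$K)
    }

    stage <- "represent"
    reps <- build_representatives(Y, part, method = config$method,
                                  cum_threshold = config$cum_threshold)

    stage <- "scan"
    scan <- manova_scan(reps, geno, statistic = config$statistic)

    stage <- "permutation threshold"
    thr <- if (config$n_perm > 0L) {
      permutation_threshold(reps, geno, n_perm = config$n_perm,
                            alpha = config$alpha, seed = config$seed,
                            statistic = config$statistic)
    } else NULL
    list(genotypes = geno, phenotypes = Y, partition = part, s_by_k = s_by_k,
         representatives = reps, scan = scan, threshold = thr)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("agnep %s | seed=%d | config=%s", packageVersion("agnep"),
                 config$seed, .config_hash(config))
  out <- function(f) file.path(config$out_dir, f)
  .write_tsv(data.frame(phenotype_id = names(res$partition$assignment),
                        cluster_label = unname(res$partition$assignment)),
             out("clusters.tsv"), hdr)
  .write_tsv(data.frame(K = as.integer(names(res$s_by_k)),
                        mean_silhouette = unname(res$s_by_k)),
             out("silhouette.tsv"), hdr)
  .write_tsv(data.frame(representative = rownames(res$representatives$values),
                        cluster = res$representatives$source_cluster,
                        as.data.frame(res$representatives$values),
                        check.names = FALSE),
             out("reps.tsv"), hdr)
  write_scan(res$scan, out("scan.tsv"), hdr)
  if (!is.null(res$threshold)) {
    writeLines(c(paste0("# ", hdr),
                 sprintf("neg_log10_threshold\t%.10g", as.numeric(res$threshold))),
               out("threshold.txt"))
  }
  manifest <- list(package_version = as.character(packageVersion("agnep")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = unclass(config), config_hash = .config_hash(config))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(structure(config$out_dir, results = res))
}

#' Simulate a full dataset and write it to disk
#'
#' Convenience wrapper pairing [make_design()], [simulate_genotypes()] and
#' [simulate_phenotypes()], writing `genotypes.tsv` (dosage),
#' `phenotypes.tsv`, and `truth.tsv` into a directory.
#'
#' @param preset,n_qtn,n,m,seed passed to the simulator.
#' @param out_dir output directory.
#' @param format `"dosage"` or `"plink"` genotype output.
#' @param ... further [make_design()] arguments.
#' @return The output directory, invisibly.
#' @export
simulate_dataset <- function(preset, n_qtn = 10, n = 5000, m = 10000,
                             seed = 1L, out_dir, format = c("dosage", "plink"),
                             ...) {
  format <- match.arg(format)
  design <- make_design(preset, n_qtn = n_qtn, n = n, m = m, seed = seed, ...)
  geno <- simulate_genotypes(n, m, design$maf_range, seed = .child_seed(seed, 1L))
  sim <- simulate_phenotypes(geno, design, seed = .child_seed(seed, 2L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("agnep %s | preset=%s | seed=%d", packageVersion("agnep"),
                 preset, seed)
  if (format == "dosage") {
    write_dosage(geno, file.path(out_dir, "genotypes.tsv"), hdr)
  } else {
    write_plink(geno, file.path(out_dir, "genotypes"))
  }
  write_phenotypes(sim$phenotypes, file.path(out_dir, "phenotypes.tsv"), hdr)
  write_truth(sim$truth, file.path(out_dir, "truth.tsv"), hdr)
  invisible(out_dir)
}
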