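# readers and writers for the on-disk formats: dosage TSV (individuals as
# rows, variant ids as header), PLINK 1 bed/bim/fam (SNP-major), phenotype
# TSV (individuals as rows), and the simulation-truth table.

#' Read a genotype matrix
#'
#' Reads either a dosage TSV (first column individual id, remaining columns
#' minor-allele counts with variant ids in the header) or a PLINK 1
#' bed/bim/fam fileset (pass the path of the `.bed` file or the prefix).
#' Columns whose allele frequency exceeds 0.5 are flipped to minor-allele
#' counts and flagged in the returned object's `flipped` attribute. With
#' `filter_maf = TRUE`, variants with minor-allele frequency strictly below
#' `maf_min` (default 0.05) are removed.
#'
#' @param path file path (`.tsv` dosage table, or `.bed`/prefix for PLINK).
#' @param format `"auto"` (by extension), `"dosage"`, or `"plink"`.
#' @param filter_maf apply the MAF filter (default FALSE).
#' @param maf_min MAF cutoff used when filtering.
#' @return An `agnep_genotypes`; attribute `flipped` lists re-oriented
#'   variant ids, attribute `n_filtered` the number removed by the filter.
#' @export
read_genotypes <- function(path, format = c("auto", "dosage", "plink"),
                           filter_maf = FALSE, maf_min = 0.05) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed")))
      "plink" else "dosage"
  }
  g <- if (format == "plink") .read_plink(path) else .read_dosage(path)
  X <- g$values
  freq <- colMeans(X, na.rm = TRUE) / 2
  flip <- which(freq > 0.5)
  if (length(flip)) {
    X[, flip] <- 2L - X[, flip]
    freq[flip] <- 1 - freq[flip]
  }
  keep <- seq_len(ncol(X))
  n_filtered <- 0L
  if (filter_maf) {
    keep <- which(freq >= maf_min)
    n_filtered <- ncol(X) - length(keep)
    if (!length(keep)) stop("MAF filter removed every variant", call. = FALSE)
  }
  out <- new_genotypes(X[, keep, drop = FALSE], maf = freq[keep],
                       variant_ids = g$variant_ids[keep],
                       individual_ids = g$individual_ids)
  attr(out, "flipped") <- g$variant_ids[flip]
  attr(out, "n_filtered") <- n_filtered
  out
}

.read_dosage <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop(sprintf("malformed dosage file '%s': need an id column plus variants", path),
                           call. = FALSE)
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  # read.table already maps the "NA" token to NA; only other unparsable
  # strings are malformed
  bad <- which(is.na(num) & !is.na(vals) & vals != "", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed dosage file '%s': non-numeric value '%s' at row %d, variant '%s'",
                 path, vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 colnames(vals)[bad[1L, 2L]]), call. = FALSE)
  }
  if (all(num == floor(num), na.rm = TRUE)) storage.mode(num) <- "integer"
  list(values = num, variant_ids = colnames(vals), individual_ids = ids)
}

#' Write a genotype matrix as a dosage TSV
#'
#' @param genotypes an `agnep_genotypes`.
#' @param path output path.
#' @param header_comment optional `#`-prefixed provenance line(s).
#' @return `path`, invisibly.
#' @export
write_dosage <- function(genotypes, path, header_comment = NULL) {
  stopifnot(inherits(genotypes, "agnep_genotypes"))
  df <- data.frame(individual_id = genotypes$individual_ids,
                   genotypes$values, check.names = FALSE)
  .write_tsv(df, path, header_comment)
}

.write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- PLINK 1 binary (SNP-major) -------------------------------------------
# two bits per call: 00 = two A1 alleles, 10 = het, 11 = zero A1, 01 = NA.
# A1 is taken as the counted (minor) allele.

.read_plink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop(sprintf("PLINK file '%s' not found", f), call. = FALSE)
  }
  bim_t <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  fam_t <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(bim_t); n <- nrow(fam_t)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop(sprintf("malformed PLINK bed file '%s': bad magic number", bed), call. = FALSE)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop(sprintf("PLINK bed file '%s' is not SNP-major", bed), call. = FALSE)
  }
  bpv <- ceiling(n / 4)               # bytes per variant
  if (length(raw) - 3L != bpv * m) {
    stop(sprintf("malformed PLINK bed file '%s': %d data bytes, expected %d",
                 bed, length(raw) - 3L, bpv * m), call. = FALSE)
  }
  body <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit fields of every byte
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  lookup <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  calls <- lookup[codes + 1L]
  X <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    X[, j] <- calls[((j - 1L) * bpv * 4L) + seq_len(n)]
  }
  list(values = X, variant_ids = as.character(bim_t[[2L]]),
       individual_ids = as.character(fam_t[[2L]]))
}

#' Write a genotype matrix as a PLINK 1 bed/bim/fam fileset
#'
#' A1 in the bim file is the counted minor allele (coded "A"), A2 the major
#' allele ("G"). Synthetic variants get chromosome 1 and positions equal to
#' their column index.
#'
#' @param genotypes an `agnep_genotypes`.
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "agnep_genotypes"))
  X <- genotypes$values
  n <- nrow(X); m <- ncol(X)
  bim <- data.frame(chrom = 1L, id = genotypes$variant_ids, cm = 0L,
                    pos = seq_len(m), a1 = "A", a2 = "G")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = genotypes$individual_ids,
                    iid = genotypes$individual_ids,
                    pid = 0L, mid = 0L, sex = 0L, pheno = -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # re-encode allele counts as 2-bit fields, individuals packed 4 per byte
  code <- matrix(1L, nrow = n, ncol = m)   # 01 = missing
  code[which(X == 2L)] <- 0L
  code[which(X == 1L)] <- 2L
  code[which(X == 0L)] <- 3L
  bpv <- ceiling(n / 4)
  padded <- matrix(0L, nrow = bpv * 4L, ncol = m)  # zero padding bits, as PLINK does
  padded[seq_len(n), ] <- code
  b1 <- padded[seq(1L, bpv * 4L, by = 4L), , drop = FALSE]
  b2 <- padded[seq(2L, bpv * 4L, by = 4L), , drop = FALSE]
  b3 <- padded[seq(3L, bpv * 4L, by = 4L), , drop = FALSE]
  b4 <- padded[seq(4L, bpv * 4L, by = 4L), , drop = FALSE]
  bytes <- as.raw(b1 + 4L * b2 + 16L * b3 + 64L * b4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read a phenotype table
#'
#' Expects a delimited table with a header row, individuals as rows, and
#' the first column holding individual ids. Individuals with any missing
#' phenotype are dropped (complete-case rule) with a message reporting the
#' count.
#'
#' @param path input TSV path.
#' @return A d x n phenotype matrix (phenotypes as rows, individuals as
#'   columns).
#' @export
read_phenotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop(sprintf("malformed phenotype file '%s': need an id column plus phenotypes",
                                   path), call. = FALSE)
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric phenotype value '%s' at individual '%s', phenotype '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]), call. = FALSE)
  }
  complete <- rowSums(is.na(num)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(sprintf("dropped %d individual(s) with missing phenotypes; %d retained",
                    n_dropped, sum(complete)))
  }
  Y <- t(num[complete, , drop = FALSE])
  colnames(Y) <- ids[complete]
  Y
}

#' Write a phenotype matrix as a TSV
#'
#' @param Y d x n phenotype matrix (phenotypes as rows).
#' @param path output path.
#' @param header_comment optional `#`-prefixed provenance line(s).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(Y, path, header_comment = NULL) {
  Y <- as.matrix(Y)
  df <- data.frame(individual_id = colnames(Y) %||% paste0("I", seq_len(ncol(Y))),
                   t(Y), check.names = FALSE)
  .write_tsv(df, path, header_comment)
}

#' Write the simulation truth table
#'
#' One row per QTN: variant id, assigned group, allele effect.
#'
#' @param truth an `agnep_truth`.
#' @param path output path.
#' @param header_comment optional provenance line(s).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, header_comment = NULL) {
  stopifnot(inherits(truth, "agnep_truth"))
  df <- data.frame(variant_id = truth$qtn_ids, group = truth$qtn_group_map,
                   effect = truth$qtn_betas)
  .write_tsv(df, path, header_comment)
}

#' Write a scan result as a TSV
#'
#' @param scan an `agnep_scan`.
#' @param path output path.
#' @param header_comment optional provenance line(s).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, header_comment = NULL) {
  stopifnot(inherits(scan, "agnep_scan"))
  .write_tsv(as.data.frame(scan), path, header_comment)
}
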