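# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

#' @noRd
.assert_fraction <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    stop(sprintf("`%s` must be a fraction in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  as.numeric(x)
}

# standardize matrix rows to mean 0, sd 1 (denominator n - 1);
# errors naming the offending row when a row has zero variance
.standardize_rows <- function(Y, context = "phenotype") {
  sds <- apply(Y, 1L, sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- rownames(Y)[which(sds == 0 | is.na(sds))[1L]] %||% which(sds == 0)[1L]
    stop(sprintf("%s '%s' has zero variance and cannot be scaled", context, bad),
         call. = FALSE)
  }
  (Y - rowMeans(Y)) / sds
}

# 32-bit FNV-1a over a character string; used for config provenance hashes
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # multiply by the FNV prime modulo 2^32 in two 16-bit halves (doubles
    # cannot hold the full 56-bit product exactly)
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * p + ((h_hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# derive a child seed below 2^31 from a base seed and an offset
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 + 97 * as.numeric(i)) %% 2147483647)
}
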