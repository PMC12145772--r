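# Nucleotide descriptor families. All encoders are pure functions from a
# canonical ACGT window to a named numeric vector; counts are reported as
# frequencies so feature scales are window-length independent. Alphabet
# order is (A, C, G, T) everywhere.

NUC <- c("A", "C", "G", "T")

# integer codes 1..4 for one sequence; errors on anything outside ACGT
seq_codes <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("expected a single non-empty sequence string")
  }
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], NUC)
  if (anyNA(codes)) stop("sequence contains non-ACGT characters: ", seq)
  codes
}

# all k-mer strings in alphabetical order (first character most significant)
kmer_strings <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(NUC), k), stringsAsFactors = FALSE)))
}

# k-mer index (1-based, alphabetical order) of each window of `codes`
window_kmer_index <- function(codes, k) {
  L <- length(codes)
  n <- L - k + 1L
  idx <- integer(n)
  for (j in 0:(k - 1L)) {
    idx <- idx + (codes[(1L + j):(n + j)] - 1L) * 4L^(k - 1L - j)
  }
  idx + 1L
}

#' Nucleotide composition encoders
#'
#' The eleven descriptor families used by the base-model grid. Each maps a
#' canonical cytosine-centered window of length `L` to a fixed-length named
#' numeric vector:
#'
#' * `encode_nac()` — mononucleotide frequencies (4 features).
#' * `encode_kmer()` — overlapping k-mer frequencies over the `L - k + 1`
#'   windows (`4^k` features, default k = 3).
#' * `encode_cksnap()` — composition of k-spaced nucleotide pairs: for each
#'   gap `g` in `0..max_gap`, frequencies of the 16 ordered pairs
#'   `(seq[i], seq[i + g + 1])` (default `max_gap = 5`, 96 features).
#' * `encode_enac()` — nucleotide frequencies inside each sliding window of
#'   width `window` (default 5; 148 features at L = 41).
#' * `encode_ncp()` — per-position chemical-property triple
#'   (ring structure, hydrogen bonding, functional group):
#'   A = (1,1,1), C = (0,1,0), G = (1,0,0), T = (0,0,1); `3 L` features.
#' * `encode_dbe()` — each adjacent dinucleotide as its 4-bit binary code,
#'   concatenating the 2-bit nucleotide codes A=00, C=01, G=10, T=11;
#'   `4 (L - 1)` features.
#' * `encode_ps2()` — position-specific one-hot of each adjacent
#'   dinucleotide (`16 (L - 1)` features; feature `PS2_<i>` with
#'   `i = 16 (p - 1) + rank`, rank AA=0 ... TT=15).
#' * `encode_zcurve()` — the three Z-curve balance coordinates
#'   purine/pyrimidine, amino/keto, weak/strong hydrogen bonding.
#' * `encode_mismatch()` — mismatch profile: for every k-mer `v`, the
#'   fraction of sequence windows within Hamming distance `m` of `v`
#'   (defaults k = 3, m = 1; `4^k` features).
#' * `encode_mmi()` — multivariate mutual information over the 10 unordered
#'   nucleotide pairs and 20 unordered triples of adjacent positions
#'   (30 features; zero-log convention for vanishing frequencies).
#' * `encode_asdc()` — adaptive skip dinucleotide composition: frequencies
#'   of ordered pairs `(seq[i], seq[j])` over all `i < j` (16 features).
#'
#' @param seq a single canonical window (string over ACGT).
#' @param k k-mer length (`encode_kmer`, `encode_mismatch`).
#' @param m maximum Hamming mismatches allowed (`encode_mismatch`).
#' @param max_gap largest gap between paired positions (`encode_cksnap`).
#' @param window sliding-window width (`encode_enac`).
#' @return a named numeric feature vector.
#' @name encoders
NULL

#' @rdname encoders
#' @export
encode_nac <- function(seq) {
  codes <- seq_codes(seq)
  out <- tabulate(codes, nbins = 4L) / length(codes)
  names(out) <- paste0("NAC_", NUC)
  out
}

#' @rdname encoders
#' @export
encode_kmer <- function(seq, k = 3L) {
  codes <- seq_codes(seq)
  k <- as.integer(k)
  if (k < 1L || k > length(codes)) stop("k must satisfy 1 <= k <= L")
  idx <- window_kmer_index(codes, k)
  out <- tabulate(idx, nbins = 4L^k) / length(idx)
  names(out) <- paste0("Kmer_", kmer_strings(k))
  out
}

#' @rdname encoders
#' @export
encode_cksnap <- function(seq, max_gap = 5L) {
  codes <- seq_codes(seq)
  L <- length(codes)
  max_gap <- as.integer(max_gap)
  if (max_gap < 0L || max_gap + 2L > L) stop("need 0 <= max_gap and max_gap + 2 <= L")
  din <- kmer_strings(2L)
  out <- numeric(16L * (max_gap + 1L))
  nm <- character(length(out))
  for (g in 0:max_gap) {
    a <- codes[1:(L - g - 1L)]
    b <- codes[(g + 2L):L]
    cnt <- tabulate((a - 1L) * 4L + b, nbins = 16L) / (L - g - 1L)
    out[g * 16L + 1:16] <- cnt
    nm[g * 16L + 1:16] <- paste0("CKSNAP_", g, "_", din)
  }
  names(out) <- nm
  out
}

#' @rdname encoders
#' @export
encode_enac <- function(seq, window = 5L) {
  codes <- seq_codes(seq)
  L <- length(codes)
  window <- as.integer(window)
  if (window < 1L || window > L) stop("need 1 <= window <= L")
  ind <- matrix(0L, nrow = L, ncol = 4L)
  ind[cbind(seq_len(L), codes)] <- 1L
  cs <- rbind(0L, apply(ind, 2L, cumsum))
  n_win <- L - window + 1L
  counts <- cs[(window + 1L):(L + 1L), , drop = FALSE] - cs[1:n_win, , drop = FALSE]
  freq <- t(counts) / window              # 4 x n_win, column = one window
  out <- as.numeric(freq)
  names(out) <- paste0("ENAC_sw.", rep(seq_len(n_win), each = 4L), ".", NUC)
  out
}

NCP_TABLE <- matrix(c(1, 1, 1,   # A
                      0, 1, 0,   # C
                      1, 0, 0,   # G
                      0, 0, 1),  # T
                    nrow = 4L, byrow = TRUE,
                    dimnames = list(NUC, c("ring", "hbond", "func")))

#' @rdname encoders
#' @export
encode_ncp <- function(seq) {
  codes <- seq_codes(seq)
  L <- length(codes)
  out <- as.numeric(t(NCP_TABLE[codes, , drop = FALSE]))
  names(out) <- paste0("NCP_", rep(seq_len(L), each = 3L), "_",
                       colnames(NCP_TABLE))
  out
}

# 2-bit codes A=00, C=01, G=10, T=11 (rows indexed by seq_codes)
DBE_BITS <- matrix(c(0, 0,  0, 1,  1, 0,  1, 1), nrow = 4L, byrow = TRUE)

#' @rdname encoders
#' @export
encode_dbe <- function(seq) {
  codes <- seq_codes(seq)
  L <- length(codes)
  if (L < 2L) stop("DBE requires L >= 2")
  a <- codes[-L]; b <- codes[-1L]
  blocks <- cbind(DBE_BITS[a, , drop = FALSE], DBE_BITS[b, , drop = FALSE])
  out <- as.numeric(t(blocks))
  names(out) <- paste0("DBE_", rep(seq_len(L - 1L), each = 4L), "_", 1:4)
  out
}

#' @rdname encoders
#' @export
encode_ps2 <- function(seq) {
  codes <- seq_codes(seq)
  L <- length(codes)
  if (L < 2L) stop("PS2 requires L >= 2")
  rank <- (codes[-L] - 1L) * 4L + (codes[-1L] - 1L)   # 0..15, AA=0 ... TT=15
  out <- numeric(16L * (L - 1L))
  out[16L * (seq_len(L - 1L) - 1L) + rank + 1L] <- 1
  names(out) <- paste0("PS2_", 0:(16L * (L - 1L) - 1L))
  out
}

#' @rdname encoders
#' @export
encode_zcurve <- function(seq) {
  codes <- seq_codes(seq)
  n <- tabulate(codes, nbins = 4L)
  L <- length(codes)
  out <- c(((n[1] + n[3]) - (n[2] + n[4])) / L,   # purine - pyrimidine
           ((n[1] + n[2]) - (n[3] + n[4])) / L,   # amino - keto
           ((n[1] + n[4]) - (n[3] + n[2])) / L)   # weak - strong H-bond
  names(out) <- paste0("Zcurve_", c("x", "y", "z"))
  out
}

# pairwise Hamming-distance matrix between all 4^k k-mers
kmer_hamming <- function(k) {
  digits <- as.matrix(rev(expand.grid(rep(list(1:4), k))))
  H <- matrix(0L, nrow = 4L^k, ncol = 4L^k)
  for (j in seq_len(k)) H <- H + outer(digits[, j], digits[, j], "!=")
  H
}

#' @rdname encoders
#' @export
encode_mismatch <- function(seq, k = 3L, m = 1L) {
  codes <- seq_codes(seq)
  k <- as.integer(k); m <- as.integer(m)
  if (m < 0L || m > k || k > length(codes)) stop("need 0 <= m <= k <= L")
  if (k > 6L) stop("mismatch profile supported for k <= 6")
  n_win <- length(codes) - k + 1L
  win_counts <- tabulate(window_kmer_index(codes, k), nbins = 4L^k)
  A <- kmer_hamming(k) <= m
  out <- as.numeric(A %*% win_counts) / n_win
  names(out) <- paste0("Mismatch_", kmer_strings(k))
  out
}

# x*ln(x / (y*z)) with the zero convention: 0 whenever any argument is 0
safe_ilog <- function(x, y, z) {
  if (x == 0 || y == 0 || z == 0) return(0)
  x * log(x / (y * z))
}

#' @rdname encoders
#' @export
encode_mmi <- function(seq) {
  codes <- seq_codes(seq)
  L <- length(codes)
  if (L < 3L) stop("MMI requires L >= 3")
  f1 <- tabulate(codes, nbins = 4L) / L
  # unordered adjacent pair frequencies over the L-1 adjacent positions
  a <- codes[-L]; b <- codes[-1L]
  tab <- tabulate((pmin(a, b) - 1L) * 4L + pmax(a, b), nbins = 16L)
  f2 <- matrix(0, 4L, 4L)
  for (x in 1:4) for (y in x:4) {
    f2[x, y] <- f2[y, x] <- tab[(x - 1L) * 4L + y] / (L - 1L)
  }
  # unordered adjacent triple frequencies over the L-2 adjacent positions
  t1 <- codes[1:(L - 2L)]; t2 <- codes[2:(L - 1L)]; t3 <- codes[3:L]
  lo <- pmin(t1, t2, t3); hi <- pmax(t1, t2, t3); mid <- t1 + t2 + t3 - lo - hi
  tt <- tabulate((lo - 1L) * 16L + (mid - 1L) * 4L + hi, nbins = 64L)
  f3_at <- function(x, y, z) {           # x <= y <= z sorted multiset
    tt[(x - 1L) * 16L + (y - 1L) * 4L + z] / (L - 2L)
  }

  pairs <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  i2 <- numeric(nrow(pairs)); i2_nm <- character(nrow(pairs))
  i2_lookup <- matrix(0, 4L, 4L)
  for (p in seq_len(nrow(pairs))) {
    x <- pairs[p, 1L]; y <- pairs[p, 2L]
    i2[p] <- safe_ilog(f2[x, y], f1[x], f1[y])
    i2_lookup[x, y] <- i2_lookup[y, x] <- i2[p]
    i2_nm[p] <- paste0("MMI_", NUC[x], NUC[y])
  }

  trips <- list(); nm3 <- character(0); i3 <- numeric(0)
  for (x in 1:4) for (y in x:4) for (z in y:4) {
    # convention: pair = first two letters of the sorted triple, condition on z
    fxyz <- f3_at(x, y, z)
    i2cond <- if (fxyz == 0 || f1[z] == 0 || f2[x, z] == 0 || f2[y, z] == 0) 0 else
      fxyz * log(fxyz * f1[z] / (f2[x, z] * f2[y, z]))
    i3 <- c(i3, i2_lookup[x, y] - i2cond)
    nm3 <- c(nm3, paste0("MMI_", NUC[x], NUC[y], NUC[z]))
  }
  out <- c(i2, i3)
  names(out) <- c(i2_nm, nm3)
  out
}

#' @rdname encoders
#' @export
encode_asdc <- function(seq) {
  codes <- seq_codes(seq)
  L <- length(codes)
  if (L < 2L) stop("ASDC requires L >= 2")
  ind <- matrix(0L, nrow = L, ncol = 4L)
  ind[cbind(seq_len(L), codes)] <- 1L
  cs <- apply(ind, 2L, cumsum)           # counts of each nt up to position j
  counts <- matrix(0, 4L, 4L, dimnames = list(NUC, NUC))
  for (b in 1:4) {
    js <- which(codes == b)
    js <- js[js > 1L]
    if (length(js)) counts[, b] <- colSums(cs[js - 1L, , drop = FALSE])
  }
  out <- as.numeric(t(counts)) / (L * (L - 1L) / 2)
  names(out) <- paste0("ASDC_", rep(NUC, each = 4L), NUC)
  out
}

# ---------------------------------------------------------------------------
# encoder specifications and dataset-level encoding

ENCODER_REGISTRY <- list(
  nac      = list(fun = "encode_nac",      params = list()),
  kmer     = list(fun = "encode_kmer",     params = list(k = 3L)),
  cksnap   = list(fun = "encode_cksnap",   params = list(max_gap = 5L)),
  enac     = list(fun = "encode_enac",     params = list(window = 5L)),
  ncp      = list(fun = "encode_ncp",      params = list()),
  dbe      = list(fun = "encode_dbe",      params = list()),
  ps2      = list(fun = "encode_ps2",      params = list()),
  zcurve   = list(fun = "encode_zcurve",   params = list()),
  mismatch = list(fun = "encode_mismatch", params = list(k = 3L, m = 1L)),
  mmi      = list(fun = "encode_mmi",      params = list()),
  asdc     = list(fun = "encode_asdc",     params = list())
)

normalize_encoder_name <- function(name) {
  nm <- tolower(gsub("[_\\.]", "", name))
  map <- c(nac = "nac", kmer = "kmer", cksnap = "cksnap", enac = "enac",
           ncp = "ncp", dbe = "dbe", ps2 = "ps2", zcurve = "zcurve",
           mismatch = "mismatch", mmi = "mmi", asdc = "asdc")
  if (!nm %in% names(map)) {
    stop("unknown encoder '", name, "'; available: ",
         paste(names(ENCODER_REGISTRY), collapse = ", "))
  }
  map[[nm]]
}

#' Encoder specification
#'
#' @param name one of `"nac"`, `"kmer"`, `"cksnap"`, `"enac"`, `"ncp"`,
#'   `"dbe"`, `"ps2"`, `"zcurve"` (alias `"Z_curve"`), `"mismatch"`,
#'   `"mmi"`, `"asdc"` (case-insensitive).
#' @param ... encoder parameters overriding the documented defaults
#'   (`k`, `m`, `max_gap`, `window`).
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(name, ...) {
  name <- normalize_encoder_name(name)
  params <- utils::modifyList(ENCODER_REGISTRY[[name]]$params, list(...))
  extra <- setdiff(names(params), names(ENCODER_REGISTRY[[name]]$params))
  if (length(extra)) {
    stop("encoder '", name, "' has no parameter(s): ", paste(extra, collapse = ", "))
  }
  structure(list(name = name, params = params), class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0("(", paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "), ")")
  } else ""
  cat("encoder_spec: ", x$name, p, "\n", sep = "")
  invisible(x)
}

#' Default encoder roster
#'
#' The eleven descriptor families with their default parameters, in the
#' fixed roster order used for grid column naming.
#'
#' @return a named list of [encoder_spec()] objects.
#' @export
default_encoders <- function() {
  nm <- c("cksnap", "zcurve", "kmer", "mismatch", "dbe", "enac",
          "nac", "mmi", "ncp", "ps2", "asdc")
  stats::setNames(lapply(nm, encoder_spec), nm)
}

#' Apply one encoder to a single sequence
#'
#' @param seq canonical window string.
#' @param spec an [encoder_spec()] (or encoder name).
#' @return named numeric vector.
#' @export
encode_sequence <- function(seq, spec) {
  if (is.character(spec)) spec <- encoder_spec(spec)
  fun <- get(ENCODER_REGISTRY[[spec$name]]$fun, mode = "function")
  do.call(fun, c(list(seq), spec$params))
}

#' Encode a whole dataset under one encoder
#'
#' @param dataset an [m5c_dataset].
#' @param spec an [encoder_spec()] (or encoder name).
#' @return a numeric matrix (class `m5c_features`) with one row per record
#'   (rownames = record ids, in dataset order) and the encoder's named
#'   feature columns; the encoder specification is attached as attribute
#'   `encoder`.
#' @export
encode_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "m5c_dataset"))
  if (is.character(spec)) spec <- encoder_spec(spec)
  rows <- lapply(seq_along(dataset$seq), function(i) {
    tryCatch(encode_sequence(dataset$seq[i], spec),
             error = function(e) {
               stop("record '", dataset$id[i], "': ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  mat <- do.call(rbind, rows)
  if (is.null(mat)) {
    mat <- matrix(numeric(0), nrow = 0L,
                  ncol = length(encode_sequence(strrep("C", dataset$window_length), spec)))
  }
  rownames(mat) <- dataset$id
  structure(mat, encoder = spec, class = c("m5c_features", class(mat)))
}

#' Concatenate feature matrices column-wise
#'
#' Mirrors the single-vector baseline in which all encoder outputs are
#' joined into one feature space.
#'
#' @param matrices list of matrices produced by [encode_dataset()], all
#'   over the same records in the same order.
#' @return one combined feature matrix.
#' @export
concatenate_features <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ids <- rownames(matrices[[1L]])
  for (m in matrices[-1L]) {
    if (!identical(rownames(m), ids)) stop("record ids differ between feature matrices")
  }
  out <- do.call(cbind, matrices)
  if (anyDuplicated(colnames(out))) {
    stop("duplicate feature names after concatenation")
  }
  class(out) <- c("m5c_features", class(matrix(0)))
  out
}
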