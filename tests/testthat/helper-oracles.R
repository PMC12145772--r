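# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use naive substring / double-loop enumeration so they share
# no code path with the package's vectorized encoders and metrics.

BASES <- c("A", "C", "G", "T")

# random window of odd length L with the center fixed to C
rand_window <- function(L = 41L) {
  s <- sample(BASES, L, replace = TRUE)
  s[(L - 1L) %/% 2L + 1L] <- "C"
  paste(s, collapse = "")
}

rand_dataset <- function(n, L = 41L, labeled = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m5c_dataset(sprintf("r%03d", seq_len(n)),
              vapply(seq_len(n), function(i) rand_window(L), character(1L)),
              label = if (labeled) rep_len(c(1L, 0L), n) else NULL,
              window_length = L)
}

# reduced rosters used for the desk-scale end-to-end runs
reduced_encoders <- function() c("nac", "ncp", "kmer")
reduced_classifiers <- function() c("LR", "NB", "RF")

chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# strip feature-matrix attributes for pure numeric comparison
bare <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

# --- encoder oracles -------------------------------------------------------

oracle_nac <- function(seq) {
  x <- chars(seq)
  vapply(BASES, function(b) sum(x == b), numeric(1L)) / length(x)
}

oracle_kmer <- function(seq, k) {
  kmers <- apply(expand.grid(rep(list(BASES), k))[, k:1, drop = FALSE],
                 1L, paste, collapse = "")
  L <- nchar(seq)
  counts <- setNames(numeric(length(kmers)), sort(kmers))
  for (i in 1:(L - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    counts[w] <- counts[w] + 1
  }
  counts / (L - k + 1L)
}

oracle_cksnap <- function(seq, max_gap) {
  x <- chars(seq); L <- length(x)
  out <- numeric(0)
  for (g in 0:max_gap) {
    block <- setNames(numeric(16L),
                      apply(expand.grid(b = BASES, a = BASES)[, 2:1], 1L,
                            paste, collapse = ""))
    for (i in 1:(L - g - 1L)) {
      p <- paste0(x[i], x[i + g + 1L])
      block[p] <- block[p] + 1
    }
    out <- c(out, block / (L - g - 1L))
  }
  out
}

oracle_enac <- function(seq, window) {
  x <- chars(seq); L <- length(x)
  out <- numeric(0)
  for (s in 1:(L - window + 1L)) {
    w <- x[s:(s + window - 1L)]
    out <- c(out, vapply(BASES, function(b) sum(w == b), numeric(1L)) / window)
  }
  out
}

oracle_zcurve <- function(seq) {
  x <- chars(seq); L <- length(x)
  n <- vapply(BASES, function(b) sum(x == b), numeric(1L))
  c(((n["A"] + n["G"]) - (n["C"] + n["T"])) / L,
    ((n["A"] + n["C"]) - (n["G"] + n["T"])) / L,
    ((n["A"] + n["T"]) - (n["G"] + n["C"])) / L)
}

oracle_mismatch <- function(seq, k, m) {
  L <- nchar(seq)
  kmers <- sort(apply(expand.grid(rep(list(BASES), k)), 1L, paste, collapse = ""))
  wins <- vapply(1:(L - k + 1L), function(i) substr(seq, i, i + k - 1L),
                 character(1L))
  hamming <- function(a, b) sum(chars(a) != chars(b))
  vapply(kmers, function(v) {
    sum(vapply(wins, function(w) hamming(w, v) <= m, logical(1L)))
  }, numeric(1L)) / length(wins)
}

oracle_asdc <- function(seq) {
  x <- chars(seq); L <- length(x)
  pairs <- apply(expand.grid(b = BASES, a = BASES)[, 2:1], 1L, paste, collapse = "")
  counts <- setNames(numeric(16L), pairs)
  for (i in 1:(L - 1L)) for (j in (i + 1L):L) {
    p <- paste0(x[i], x[j])
    counts[p] <- counts[p] + 1
  }
  counts / (L * (L - 1L) / 2)
}

# independent MMI computation by explicit enumeration over letters
oracle_mmi <- function(seq) {
  x <- chars(seq); L <- length(x)
  f1 <- setNames(vapply(BASES, function(b) sum(x == b), numeric(1L)) / L, BASES)
  pair_freq <- function(a, b) {
    hits <- 0
    for (i in 1:(L - 1L)) {
      s <- sort(c(x[i], x[i + 1L]))
      if (identical(s, sort(c(a, b)))) hits <- hits + 1
    }
    hits / (L - 1L)
  }
  trip_freq <- function(a, b, c) {
    hits <- 0
    for (i in 1:(L - 2L)) {
      if (identical(sort(c(x[i], x[i + 1L], x[i + 2L])), sort(c(a, b, c)))) {
        hits <- hits + 1
      }
    }
    hits / (L - 2L)
  }
  ilog <- function(num, d1, d2) if (num == 0 || d1 == 0 || d2 == 0) 0 else
    num * log(num / (d1 * d2))
  out <- numeric(0); nm <- character(0)
  for (i in 1:4) for (j in i:4) {
    out <- c(out, ilog(pair_freq(BASES[i], BASES[j]), f1[i], f1[j]))
    nm <- c(nm, paste0("MMI_", BASES[i], BASES[j]))
  }
  for (i in 1:4) for (j in i:4) for (k in j:4) {
    i2 <- ilog(pair_freq(BASES[i], BASES[j]), f1[i], f1[j])
    f3 <- trip_freq(BASES[i], BASES[j], BASES[k])
    fik <- pair_freq(BASES[i], BASES[k]); fjk <- pair_freq(BASES[j], BASES[k])
    i2c <- if (f3 == 0 || f1[k] == 0 || fik == 0 || fjk == 0) 0 else
      f3 * log(f3 * f1[k] / (fik * fjk))
    out <- c(out, i2 - i2c)
    nm <- c(nm, paste0("MMI_", BASES[i], BASES[j], BASES[k]))
  }
  setNames(out, nm)
}

# --- metric oracles --------------------------------------------------------

oracle_confusion <- function(labels, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && pred[i] == 1) tp <- tp + 1L
    else if (labels[i] == 0 && pred[i] == 0) tn <- tn + 1L
    else if (labels[i] == 0 && pred[i] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_metrics <- function(TP, TN, FP, FN) {
  c(accuracy = (TP + TN) / (TP + TN + FP + FN),
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    f1 = 2 * TP / (2 * TP + FN + FP),
    mcc = (TP * TN - FP * FN) /
      sqrt((TP + FP) * (TP + FN)) / sqrt((TN + FP) * (TN + FN)))
}

# O(n^2) pairwise Mann-Whitney AUC with ties counted one half
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
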