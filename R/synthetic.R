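# Synthetic data generator: labeled cytosine-centered windows in which
# the positive class carries a positionally biased nucleotide composition
# around the center (the kind of signal most of the descriptor families
# can express), with a tunable effect size. A dinucleotide-correlation
# mode is included to exercise the pair-based encoders specifically.

#' Position-specific motif model for synthetic windows
#'
#' Builds the generating model for one synthetic "species": a 4 x L
#' position-specific probability table for the positive class and a
#' global background distribution for the negative class. The center
#' column is a point mass on C in both classes (every window is a
#' candidate cytosine site). Under the positional mode, `signal_positions`
#' emit `signal_nt` with probability `signal_prob` in positives
#' (remaining mass spread evenly over the other nucleotides); effect
#' sizes map to `signal_prob` 0.25 (null: positives exchangeable with
#' background), 0.45 (weak) and 0.9 (strong) against the uniform 0.25
#' background. Under the dinucleotide mode, positives are generated by a
#' first-order Markov chain whose stay probability (chance of repeating
#' the previous nucleotide) is 0.25 (null), 0.4 (weak) or 0.7 (strong),
#' leaving all single-position compositions uniform.
#'
#' @param L window length (odd, default 41).
#' @param effect_size `"null"`, `"weak"` or `"strong"`.
#' @param background length-4 nucleotide distribution (A, C, G, T);
#'   default uniform.
#' @param signal_positions 1-based positions carrying the signal; default
#'   the three positions on each side of the center.
#' @param signal_nt the enriched nucleotide (default `"G"`).
#' @param signal_prob override the effect-size mapping.
#' @param mode `"positional"` (default) or `"dinucleotide"`.
#' @return object of class `motif_model` with the probability table
#'   (`pwm`, 4 x L), `background`, and the generation mode.
#' @export
motif_model <- function(L = 41L, effect_size = c("null", "weak", "strong"),
                        background = rep(0.25, 4),
                        signal_positions = NULL, signal_nt = "G",
                        signal_prob = NULL,
                        mode = c("positional", "dinucleotide")) {
  effect_size <- match.arg(effect_size)
  mode <- match.arg(mode)
  L <- as.integer(L)
  if (L %% 2L == 0L || L < 3L) stop("L must be odd and >= 3")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be a length-4 distribution summing to 1")
  }
  center <- (L - 1L) %/% 2L + 1L
  if (is.null(signal_positions)) {
    signal_positions <- center + c(-3L, -2L, -1L, 1L, 2L, 3L)
  }
  if (any(signal_positions < 1L | signal_positions > L) ||
      center %in% signal_positions) {
    stop("signal positions must lie in 1..L and exclude the center")
  }
  nt_idx <- match(signal_nt, NUC)
  if (is.na(nt_idx)) stop("signal_nt must be one of A, C, G, T")
  if (is.null(signal_prob)) {
    signal_prob <- switch(effect_size, null = background[nt_idx],
                          weak = 0.45, strong = 0.9)
  }
  signal_prob <- rep(signal_prob, length.out = length(signal_positions))
  if (any(signal_prob < 0 | signal_prob > 1)) {
    stop("signal_prob values must lie in [0, 1]")
  }
  stay_prob <- switch(effect_size, null = 0.25, weak = 0.4, strong = 0.7)

  pwm <- matrix(background, nrow = 4L, ncol = L,
                dimnames = list(NUC, NULL))
  if (mode == "positional") {
    for (i in seq_along(signal_positions)) {
      p <- signal_positions[i]; pr <- signal_prob[i]
      pwm[nt_idx, p] <- pr
      pwm[-nt_idx, p] <- background[-nt_idx] / sum(background[-nt_idx]) * (1 - pr)
    }
  }
  pwm[, center] <- c(0, 1, 0, 0)         # point mass on C
  if (any(abs(colSums(pwm) - 1) > 1e-9)) stop("invalid motif table")
  structure(list(pwm = pwm, background = background, L = L,
                 effect_size = effect_size, mode = mode,
                 signal_positions = signal_positions,
                 signal_nt = signal_nt, signal_prob = signal_prob,
                 stay_prob = stay_prob, center = center),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: L = %d, effect = %s, mode = %s\n",
              x$L, x$effect_size, x$mode))
  if (x$mode == "positional") {
    cat(sprintf("  signal: %s with p = {%s} at positions %s\n",
                x$signal_nt, paste(unique(x$signal_prob), collapse = ", "),
                paste(x$signal_positions, collapse = ", ")))
  } else {
    cat(sprintf("  dinucleotide stay probability: %.2f\n", x$stay_prob))
  }
  invisible(x)
}

sample_windows <- function(n, motif, positive) {
  L <- motif$L
  out <- character(n)
  if (motif$mode == "dinucleotide" && positive) {
    for (i in seq_len(n)) {
      codes <- integer(L)
      codes[1L] <- sample.int(4L, 1L, prob = motif$background)
      for (p in 2:L) {
        pr <- rep((1 - motif$stay_prob) / 3, 4L)
        pr[codes[p - 1L]] <- motif$stay_prob
        codes[p] <- sample.int(4L, 1L, prob = pr)
      }
      codes[motif$center] <- 2L
      out[i] <- paste(NUC[codes], collapse = "")
    }
    return(out)
  }
  pwm <- if (positive) motif$pwm else {
    bg <- matrix(motif$background, 4L, L)
    bg[, motif$center] <- c(0, 1, 0, 0)
    bg
  }
  for (i in seq_len(n)) {
    codes <- vapply(seq_len(L),
                    function(p) sample.int(4L, 1L, prob = pwm[, p]), integer(1L))
    out[i] <- paste(NUC[codes], collapse = "")
  }
  out
}

#' Generate a labeled synthetic window dataset
#'
#' Positives are drawn from the motif model's position-specific table
#' (or Markov chain), negatives from the background with the center
#' forced to C. Generation is fully reproducible under `seed`.
#'
#' @param n_pos,n_neg number of positive / negative windows (>= 1).
#' @param motif a [motif_model()]; default strong positional signal.
#' @param seed integer seed.
#' @param species_tag,split passed to [m5c_dataset()].
#' @param id_prefix prefix for generated record ids.
#' @return an [m5c_dataset] with `n_pos + n_neg` records (positives
#'   first).
#' @export
generate_dataset <- function(n_pos, n_neg,
                             motif = motif_model(effect_size = "strong"),
                             seed = 1L, species_tag = "synthetic",
                             split = "unspecified", id_prefix = "syn") {
  stopifnot(inherits(motif, "motif_model"), n_pos >= 1L, n_neg >= 1L)
  set.seed(seed %% .Machine$integer.max)
  seqs <- c(sample_windows(n_pos, motif, positive = TRUE),
            sample_windows(n_neg, motif, positive = FALSE))
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  ids <- paste0(id_prefix, "_", seq_along(seqs))
  m5c_dataset(ids, seqs, labels, window_length = motif$L,
              species_tag = species_tag, split = split)
}

#' Generate two synthetic "species" with shared or independent motifs
#'
#' Each species gets a training and an independent set drawn from its own
#' motif model. With `shared_motif = TRUE` both species use the same
#' motif, so a model trained on one should transfer to the other. With
#' `shared_motif = FALSE` each species' signal positions are drawn
#' independently from disjoint flank pools (upstream of the center for
#' the first species, downstream for the second) with independently drawn
#' signal nucleotides, and each motif is composition balanced: half of
#' its positions enrich the signal nucleotide (p = 0.5) and half deplete
#' it (p = 0), so the positives' expected global composition equals the
#' background. Each species is then background-distributed in every
#' statistic of the other's informative features - positional and global
#' alike - and no transfer signal exists.
#'
#' @param shared_motif logical.
#' @param n_train,n_independent per-class sizes of each split.
#' @param L window length.
#' @param effect_size effect size of both motifs.
#' @param seed integer seed.
#' @return named list of two species, each a list with `train` and
#'   `independent` [m5c_dataset]s.
#' @export
generate_species_pair <- function(shared_motif = TRUE,
                                  n_train = 200L, n_independent = 200L,
                                  L = 41L, effect_size = "strong", seed = 1L) {
  center <- (L - 1L) %/% 2L + 1L
  if (shared_motif) {
    m <- motif_model(L = L, effect_size = effect_size)
    motifs <- list(speciesA = m, speciesB = m)
  } else {
    set.seed(seed %% .Machine$integer.max)
    pool_a <- seq(max(1L, center - 15L), center - 1L)
    pool_b <- seq(center + 1L, min(L, center + 15L))
    balanced <- c(rep(0.5, 5L), rep(0, 5L))   # composition-neutral signal
    motifs <- list(
      speciesA = motif_model(L = L, effect_size = effect_size,
                             signal_positions = sample(pool_a, 10L),
                             signal_nt = sample(c("A", "G", "T"), 1L),
                             signal_prob = balanced),
      speciesB = motif_model(L = L, effect_size = effect_size,
                             signal_positions = sample(pool_b, 10L),
                             signal_nt = sample(c("A", "G", "T"), 1L),
                             signal_prob = balanced)
    )
  }
  out <- list()
  for (i in seq_along(motifs)) {
    tag <- names(motifs)[i]
    out[[tag]] <- list(
      train = generate_dataset(n_train, n_train, motif = motifs[[i]],
                               seed = seed + 17L * i, species_tag = tag,
                               split = "train",
                               id_prefix = paste0(tag, "_tr")),
      independent = generate_dataset(n_independent, n_independent,
                                     motif = motifs[[i]],
                                     seed = seed + 17L * i + 7L,
                                     species_tag = tag, split = "independent",
                                     id_prefix = paste0(tag, "_ind"))
    )
    out[[tag]]$motif <- motifs[[i]]
  }
  out
}
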