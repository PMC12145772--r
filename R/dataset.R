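#' Labeled datasets of fixed-width cytosine-centered windows
#'
#' An `m5c_dataset` holds an ordered collection of fixed-width nucleotide
#' windows, each centered on a cytosine (the candidate m5C site), together
#' with optional binary labels (1 = methylated, 0 = unmethylated).
#' Sequences are stored canonicalized: uppercase, DNA alphabet (U mapped
#' to T). The window length `L` must be odd so that the center position
#' `(L - 1) / 2` (0-based) is well defined; the default convention is
#' L = 41, i.e. 20 nt of flank on either side of the cytosine.
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of nucleotide windows (same length as `id`).
#' @param label optional integer vector of 0/1 labels (`NA` allowed for
#'   unlabeled records).
#' @param window_length expected window length; defaults to the common
#'   length of `seq`.
#' @param species_tag free-text provenance label.
#' @param split one of `"unspecified"`, `"train"`, `"independent"`.
#' @param skip_invalid if `TRUE`, records failing validation (wrong
#'   length, non-ACGT characters, center not C) are dropped with a
#'   warning instead of raising an error.
#'
#' @return An object of class `m5c_dataset`: a list with elements `id`,
#'   `seq`, `label`, `species_tag`, `split`, `window_length`.
#' @export
m5c_dataset <- function(id, seq, label = NULL,
                        window_length = NULL,
                        species_tag = "unspecified",
                        split = c("unspecified", "train", "independent"),
                        skip_invalid = FALSE) {
  split <- match.arg(split)
  id <- as.character(id)
  seq <- canonicalize_seq(seq)
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  if (is.null(label)) {
    label <- rep(NA_integer_, length(seq))
  } else {
    label <- as.integer(label)
    if (length(label) != length(seq)) {
      stop("'label' must match the number of records")
    }
    if (!all(label %in% c(0L, 1L) | is.na(label))) {
      stop("labels must be 0, 1 or NA")
    }
  }
  if (is.null(window_length)) {
    if (length(seq) == 0L) stop("window_length must be given for an empty dataset")
    window_length <- nchar(seq[1L])
  }
  L <- as.integer(window_length)
  if (L < 1L || L %% 2L == 0L) {
    stop("window_length must be a positive odd integer (got ", L, ")")
  }

  bad <- validate_windows(id, seq, L)
  if (length(bad$idx)) {
    if (skip_invalid) {
      warning(sprintf("dropping %d invalid record(s): %s",
                      length(bad$idx),
                      paste(utils::head(bad$msg, 5L), collapse = "; ")))
      keep <- setdiff(seq_along(seq), bad$idx)
      id <- id[keep]; seq <- seq[keep]; label <- label[keep]
    } else {
      stop(bad$msg[1L])
    }
  }
  if (anyDuplicated(id)) {
    stop("record ids must be unique within a dataset (duplicate: ",
         id[anyDuplicated(id)], ")")
  }
  structure(
    list(id = id, seq = seq, label = label,
         species_tag = species_tag, split = split,
         window_length = L),
    class = "m5c_dataset"
  )
}

canonicalize_seq <- function(seq) {
  seq <- toupper(as.character(seq))
  gsub("U", "T", seq, fixed = TRUE)
}

# Returns indices and messages for records violating the window invariants.
validate_windows <- function(id, seq, L) {
  idx <- integer(0); msg <- character(0)
  center <- (L - 1L) %/% 2L + 1L   # 1-based center position
  n <- nchar(seq)
  wrong_len <- which(n != L)
  for (i in wrong_len) {
    idx <- c(idx, i)
    msg <- c(msg, sprintf("record '%s': length %d, expected %d", id[i], n[i], L))
  }
  ok <- setdiff(seq_along(seq), wrong_len)
  if (length(ok)) {
    bad_chr <- ok[grepl("[^ACGT]", seq[ok])]
    for (i in bad_chr) {
      idx <- c(idx, i)
      msg <- c(msg, sprintf("record '%s': non-ACGT character(s)", id[i]))
    }
    ok <- setdiff(ok, bad_chr)
    not_c <- ok[substr(seq[ok], center, center) != "C"]
    for (i in not_c) {
      idx <- c(idx, i)
      msg <- c(msg, sprintf("record '%s': center position %d is not C", id[i], center))
    }
  }
  list(idx = idx, msg = msg)
}

#' @export
print.m5c_dataset <- function(x, ...) {
  nlab <- sum(!is.na(x$label))
  cat(sprintf("m5c_dataset: %d windows of length %d (%s, split = %s)\n",
              length(x$id), x$window_length, x$species_tag, x$split))
  if (nlab) {
    cat(sprintf("  labels: %d positive / %d negative / %d unlabeled\n",
                sum(x$label == 1L, na.rm = TRUE),
                sum(x$label == 0L, na.rm = TRUE),
                length(x$id) - nlab))
  } else {
    cat("  labels: none\n")
  }
  invisible(x)
}

#' @export
length.m5c_dataset <- function(x) length(x$id)

#' Subset a window dataset by record index
#'
#' @param x an [m5c_dataset].
#' @param i integer or logical index vector.
#' @param ... ignored.
#' @return an `m5c_dataset` containing the selected records in order.
#' @export
`[.m5c_dataset` <- function(x, i, ...) {
  m5c_dataset(x$id[i], x$seq[i], x$label[i],
              window_length = x$window_length,
              species_tag = x$species_tag, split = x$split)
}

#' @export
as.data.frame.m5c_dataset <- function(x, ...) {
  data.frame(id = x$id, seq = x$seq, label = x$label,
             stringsAsFactors = FALSE)
}
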