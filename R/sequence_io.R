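#' Read labeled cytosine-centered windows from a FASTA file
#'
#' Reads fixed-width nucleotide windows from FASTA, canonicalizes them
#' (uppercase, U to T) and validates the window invariants: common length
#' `window_length` (odd), center nucleotide C, alphabet ACGT. Labels can
#' come from the FASTA header (token after the last `|`, parsed as 0/1),
#' from a two-column sidecar TSV (id, label), or be absent.
#'
#' @param path path to a FASTA file.
#' @param label_source one of `"header_token"`, `"sidecar_table"`,
#'   `"unlabeled"`.
#' @param window_length expected window length (default 41).
#' @param sidecar path to a tab-separated file with columns id and label;
#'   required when `label_source = "sidecar_table"`.
#' @param species_tag,split passed to [m5c_dataset()].
#' @param skip_invalid drop invalid records with a warning instead of
#'   erroring.
#'
#' @return an [m5c_dataset] with records in file order.
#' @export
read_fasta <- function(path,
                       label_source = c("header_token", "sidecar_table", "unlabeled"),
                       window_length = 41L,
                       sidecar = NULL,
                       species_tag = "unspecified",
                       split = c("unspecified", "train", "independent"),
                       skip_invalid = FALSE) {
  label_source <- match.arg(label_source)
  split <- match.arg(split)
  if (!file.exists(path)) stop("FASTA file not found: ", path)

  # cheap syntax pre-check so malformed input is reported with a line number
  first <- readLines(path, n = 50L, warn = FALSE)
  first_content <- which(nzchar(trimws(first)))
  if (length(first_content) == 0L) {
    headers <- character(0)
  } else if (!startsWith(trimws(first[first_content[1L]]), ">")) {
    stop(sprintf("malformed FASTA at line %d of '%s': expected '>' header",
                 first_content[1L], path))
  }
  recs <- Biostrings::readBStringSet(path)
  headers <- names(recs)
  seqs <- as.character(recs)

  if (label_source == "header_token") {
    ids <- headers
    labels <- rep(NA_integer_, length(headers))
    has_bar <- grepl("|", headers, fixed = TRUE)
    if (any(has_bar)) {
      tok <- sub(".*\\|", "", headers[has_bar])
      lab <- suppressWarnings(as.integer(tok))
      bad <- is.na(lab) | !(lab %in% c(0L, 1L))
      if (any(bad)) {
        stop("unknown label token '", tok[bad][1L], "' in header '",
             headers[has_bar][bad][1L], "'")
      }
      labels[has_bar] <- lab
      ids[has_bar] <- sub("\\|[^|]*$", "", headers[has_bar])
    }
  } else if (label_source == "sidecar_table") {
    if (is.null(sidecar)) stop("label_source = 'sidecar_table' requires 'sidecar'")
    tab <- utils::read.table(sidecar, header = FALSE, sep = "\t",
                             col.names = c("id", "label"),
                             colClasses = c("character", "integer"))
    ids <- headers
    m <- match(ids, tab$id)
    if (anyNA(m)) stop("sidecar table has no label for record '", ids[which(is.na(m))[1L]], "'")
    labels <- tab$label[m]
    if (!all(labels %in% c(0L, 1L))) {
      stop("unknown label token '", labels[!(labels %in% c(0L, 1L))][1L], "' in sidecar table")
    }
  } else {
    ids <- headers
    labels <- rep(NA_integer_, length(headers))
  }

  m5c_dataset(ids, seqs, labels, window_length = window_length,
              species_tag = species_tag, split = split,
              skip_invalid = skip_invalid)
}

#' Write a window dataset to FASTA
#'
#' Labels, where present, are appended to the header as `id|label` so a
#' read/write round trip preserves (id, canonical sequence, label).
#'
#' @param dataset an [m5c_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "m5c_dataset"))
  hdr <- ifelse(is.na(dataset$label), dataset$id,
                paste0(dataset$id, "|", dataset$label))
  x <- Biostrings::BStringSet(dataset$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write per-record predictions as a tab-separated table
#'
#' Emits columns `id`, `sequence`, `probability`, `predicted_label`
#' (probability greater than or equal to the threshold gives label 1).
#'
#' @param dataset an [m5c_dataset].
#' @param probabilities numeric vector in \[0, 1\], one per record.
#' @param path output file path.
#' @param threshold decision threshold (default 0.5).
#' @return the written data frame, invisibly.
#' @export
write_predictions <- function(dataset, probabilities, path, threshold = 0.5) {
  stopifnot(inherits(dataset, "m5c_dataset"))
  if (length(probabilities) != length(dataset$id)) {
    stop("need exactly one probability per record (",
         length(probabilities), " probabilities for ",
         length(dataset$id), " records)")
  }
  if (length(probabilities) && (min(probabilities) < 0 || max(probabilities) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  out <- data.frame(
    id = dataset$id,
    sequence = dataset$seq,
    probability = as.numeric(probabilities),
    predicted_label = as.integer(probabilities >= threshold),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
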