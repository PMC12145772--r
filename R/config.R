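# Declarative run configuration (YAML) and run manifests (JSON with
# checksums) so every command-line run is reproducible from its output
# directory alone.

#' Default run configuration
#'
#' Every field of the configuration consumed by the command-line
#' interface, with its documented default: window length 41, the full
#' encoder and classifier rosters with default parameters, stacking with
#' a random-forest meta-classifier, 5 folds, seed 1, threshold 0.5.
#'
#' @return a named list.
#' @export
default_run_config <- function() {
  list(
    window_length = 41L,
    encoders = lapply(default_encoders(), function(s) s$params),
    classifiers = lapply(default_classifiers(), function(s) s$params),
    ensemble = "stacking",
    meta = "RF",
    n_folds = 5L,
    seed = 1L,
    threshold = 0.5
  )
}

#' Read a run configuration file
#'
#' Reads a YAML file and fills unspecified fields from
#' [default_run_config()]. Listing a subset of encoders or classifiers
#' restricts the roster to that subset.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    for (nm in c("encoders", "classifiers")) {
      if (!is.null(user[[nm]])) {
        if (is.character(user[[nm]])) {      # bare roster list
          user[[nm]] <- stats::setNames(
            rep(list(list()), length(user[[nm]])), user[[nm]])
        }
        cfg[[nm]] <- lapply(user[[nm]], function(p) if (is.null(p)) list() else p)
      }
    }
    for (nm in setdiff(names(user), c("encoders", "classifiers"))) {
      if (!nm %in% names(cfg)) stop("unknown config key '", nm, "'")
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!cfg$ensemble %in% c("stacking", "voting-soft", "voting-hard")) {
    stop("config: ensemble must be stacking, voting-soft or voting-hard")
  }
  cfg$window_length <- as.integer(cfg$window_length)
  cfg$n_folds <- as.integer(cfg$n_folds)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Build encoder specs from a configuration
#' @param cfg a configuration list.
#' @return named list of [encoder_spec()].
#' @export
config_encoders <- function(cfg) {
  stats::setNames(
    lapply(names(cfg$encoders), function(nm) {
      do.call(encoder_spec, c(list(nm), cfg$encoders[[nm]]))
    }),
    vapply(names(cfg$encoders), normalize_encoder_name, character(1L)))
}

#' Build classifier specs from a configuration
#' @param cfg a configuration list.
#' @return named list of [classifier_spec()].
#' @export
config_classifiers <- function(cfg) {
  stats::setNames(
    lapply(names(cfg$classifiers), function(nm) {
      do.call(classifier_spec,
              c(list(nm), cfg$classifiers[[nm]], list(seed = cfg$seed)))
    }),
    toupper(names(cfg$classifiers)))
}

#' Write a run manifest
#'
#' Serializes the full configuration, seeds, package version and the md5
#' checksum of every artifact into `manifest.json` inside `dir`.
#'
#' @param dir run output directory.
#' @param config configuration list used for the run.
#' @param files character vector of artifact paths (relative to `dir`).
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, files = character(0)) {
  checksums <- if (length(files)) {
    stats::setNames(as.character(tools::md5sum(file.path(dir, files))), files)
  } else NULL
  manifest <- list(
    package = "methylstack",
    version = as.character(utils::packageVersion("methylstack")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    checksums = as.list(checksums)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Verify a run manifest
#'
#' Recomputes the md5 checksum of every artifact listed in the manifest
#' and errors on any mismatch (tampered or corrupted artifact).
#'
#' @param dir run output directory containing `manifest.json`.
#' @return the parsed manifest, invisibly.
#' @export
verify_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(path)
  for (f in names(manifest$checksums)) {
    actual <- as.character(tools::md5sum(file.path(dir, f)))
    if (!identical(actual, manifest$checksums[[f]])) {
      stop("checksum mismatch for '", f, "': manifest ",
           manifest$checksums[[f]], ", actual ", actual)
    }
  }
  invisible(manifest)
}
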