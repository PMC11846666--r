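#' Construct a measurement set
#'
#' Upstream (source) or downstream (target) molecular activity measurements:
#' a node-to-score map plus a role. Sources are typically perturbed nodes
#' (e.g. a drug's kinase target, signed by the direction of perturbation);
#' targets are downstream readouts such as inferred TF or kinase activities.
#'
#' @param scores named numeric vector, all values finite
#' @param role `"source"` or `"target"`
#' @param condition free-text condition label
#' @return an object of class `measurement_set`
#' @export
measurement_set <- function(scores, role = c("source", "target"),
                            condition = "") {
  role <- match.arg(role)
  scores <- unlist(scores)
  if (length(scores)) {
    if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
      stop("all scores must be named by non-empty node identifiers")
    }
    if (any(!is.finite(scores))) stop("all scores must be finite")
  } else {
    scores <- stats::setNames(numeric(), character())
  }
  structure(list(scores = scores, role = role, condition = condition),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> role=%s, %d node(s)%s\n", x$role,
              length(x$scores),
              if (nzchar(x$condition)) paste0(", condition=", x$condition) else ""))
  invisible(x)
}

#' Read measurements from a TSV file
#'
#' Expects a header line `id<TAB>score`. Duplicated ids keep the last
#' occurrence with a warning.
#'
#' @param path file path
#' @param role `"source"` or `"target"`
#' @param condition free-text condition label
#' @return a `measurement_set`
#' @export
read_measurements <- function(path, role = c("source", "target"),
                              condition = "") {
  role <- match.arg(role)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "score") %in% names(d))) {
    stop("measurement TSV must have header columns id, score")
  }
  if (!nrow(d)) return(measurement_set(numeric(), role, condition))
  sc <- suppressWarnings(as.numeric(d$score))
  bad <- which(!is.finite(sc))
  if (length(bad)) {
    stop(sprintf("line %d: non-numeric or non-finite score '%s'",
                 bad[1L] + 1L, d$score[bad[1L]]))
  }
  if (anyDuplicated(d$id)) {
    warning("duplicate measurement ids; keeping the last occurrence")
    keep <- !duplicated(d$id, fromLast = TRUE)
    d <- d[keep, , drop = FALSE]
    sc <- sc[keep]
  }
  measurement_set(stats::setNames(sc, d$id), role, condition)
}

#' Write measurements to a TSV file
#' @param ms a `measurement_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_measurements <- function(ms, path) {
  lines <- c("id\tscore",
             sprintf("%s\t%.15g", names(ms$scores), ms$scores))
  writeLines(lines, path)
  invisible(path)
}

#' Signs of a measurement set
#'
#' The perturbation/readout sign of each node is the arithmetic sign of its
#' score; zero-score nodes are unsigned and dropped with a warning, since
#' they carry no direction for sign-consistency reasoning.
#'
#' @param ms a `measurement_set`
#' @return named integer vector with values in \{-1, +1\}
#' @export
measurement_signs <- function(ms) {
  sc <- ms$scores
  zero <- sc == 0
  if (any(zero)) {
    warning(sprintf("%d zero-score node(s) dropped (unsigned)", sum(zero)))
    sc <- sc[!zero]
  }
  stats::setNames(as.integer(sign(sc)), names(sc))
}

# ---- dataset descriptor registry -------------------------------------------

#' Describe an omics dataset
#'
#' Descriptors are metadata only: the remote locator is recorded but never
#' fetched, so the registry works fully offline. Users who download a dataset
#' themselves can point `local_path` at the result.
#'
#' @param name unique registry name
#' @param omics_types character vector of omics modalities
#' @param condition_design free-text description of the condition grid
#' @param remote_locator where the preprocessed data lives (not fetched)
#' @param local_path optional local path supplied by the user
#' @return an object of class `dataset_descriptor`
#' @export
dataset_descriptor <- function(name, omics_types, condition_design,
                               remote_locator, local_path = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name,
                 omics_types = as.character(omics_types),
                 condition_design = condition_design,
                 remote_locator = remote_locator,
                 local_path = local_path),
            class = "dataset_descriptor")
}

#' @export
print.dataset_descriptor <- function(x, ...) {
  cat(sprintf("<dataset_descriptor> %s [%s]\n  %s\n  locator: %s\n",
              x$name, paste(x$omics_types, collapse = ", "),
              x$condition_design, x$remote_locator))
  invisible(x)
}

.registry <- new.env(parent = emptyenv())

builtin_descriptors <- function() {
  list(
    dataset_descriptor(
      "decryptm",
      c("phosphoproteomics"),
      "dose-response profiles of drug perturbations; binary responsive labels derivable from curve fits (as preprocessed by the original authors)",
      "https://zenodo.org/communities/decryptm"),
    dataset_descriptor(
      "panacea",
      c("transcriptomics"),
      "single-dose transcriptomic responses to 32 kinase inhibitors across 11 cancer cell lines, with per-drug off-target annotations",
      "https://www.synapse.org/panacea_dream"),
    dataset_descriptor(
      "nci60",
      c("metabolomics", "transcriptomics"),
      "basal multi-omics profiles of the NCI-60 cancer cell line collection",
      "https://discover.nci.nih.gov/cellminer"),
    dataset_descriptor(
      "cptac",
      c("genomics", "transcriptomics", "proteomics", "phosphoproteomics"),
      "harmonized tumor and adjacent-normal multi-omics across cancer types",
      "https://proteomics.cancer.gov/programs/cptac"))
}

reset_registry <- function() {
  rm(list = ls(.registry), envir = .registry)
  for (d in builtin_descriptors()) assign(d$name, d, envir = .registry)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  reset_registry()
}

#' List registered dataset descriptors
#'
#' The default build registers four descriptors (`decryptm`, `panacea`,
#' `nci60`, `cptac`), metadata only; no data is downloaded.
#'
#' @return list of `dataset_descriptor` objects, ordered by name
#' @export
list_datasets <- function() {
  nm <- sort(ls(.registry))
  lapply(nm, get, envir = .registry)
}

#' Register a dataset descriptor
#' @param descriptor a `dataset_descriptor`
#' @return the descriptor, invisibly
#' @export
register_dataset <- function(descriptor) {
  stopifnot(inherits(descriptor, "dataset_descriptor"))
  if (exists(descriptor$name, envir = .registry, inherits = FALSE)) {
    stop(sprintf("dataset '%s' is already registered", descriptor$name))
  }
  assign(descriptor$name, descriptor, envir = .registry)
  invisible(descriptor)
}

#' Retrieve a dataset descriptor by name
#' @param name registry name
#' @return a `dataset_descriptor`
#' @export
get_dataset <- function(name) {
  if (!exists(name, envir = .registry, inherits = FALSE)) {
    stop(sprintf("no dataset named '%s' in the registry", name))
  }
  get(name, envir = .registry)
}
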