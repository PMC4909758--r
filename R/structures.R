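#' Structure registries for basal-ganglia connectivity analysis
#'
#' A structure set maps structure names to integer labels and distinguishes
#' three groups: the five core nuclei (STN, SNc, SNr, GPe, GPi) among which
#' direct connections are defined; the seed structures used for track
#' selection (by default STN, SN, GP, where SN and GP are composites:
#' SN = SNc + SNr and GP = GPe + GPi); and auxiliary target ROIs (internal
#' capsule, red nucleus, named fiber paths, ...) which participate in
#' seed-target connectivity tables but never block directness.
#'
#' @param labels named integer vector mapping structure names to nonzero
#'   labels; names and labels must each be unique.
#' @param core_five character vector of exactly five names from
#'   \code{labels}; defaults to \code{c("STN","SNc","SNr","GPe","GPi")}.
#' @param composites named list of character vectors defining composite
#'   structures as unions of labelled structures; defaults to
#'   \code{list(SN = c("SNc","SNr"), GP = c("GPe","GPi"))}.
#' @param seeds character vector of seed names (labelled or composite);
#'   defaults to \code{c("STN","SN","GP")}.
#' @return An object of class \code{bg_structure_set}.
#' @examples
#' ss <- structure_set(c(STN = 1, SNc = 2, SNr = 3, GPe = 4, GPi = 5,
#'                       capsule = 9))
#' resolve_labels(ss, "GP")   # composite -> c(4, 5)
#' @export
structure_set <- function(labels,
                          core_five = c("STN", "SNc", "SNr", "GPe", "GPi"),
                          composites = list(SN = c("SNc", "SNr"),
                                            GP = c("GPe", "GPi")),
                          seeds = c("STN", "SN", "GP")) {
  labels <- unlist(labels)
  if (is.null(names(labels)) || any(names(labels) == ""))
    stopf("all labels must be named")
  if (anyDuplicated(names(labels))) stopf("structure names must be unique")
  if (anyDuplicated(labels)) stopf("structure labels must be unique")
  if (any(labels == 0)) stopf("label 0 is reserved for background")
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (length(core_five) != 5L)
    stopf("core_five must name exactly 5 structures")
  missing_core <- setdiff(core_five, names(labels))
  if (length(missing_core))
    stopf("core_five structures missing from labels: %s",
          paste(missing_core, collapse = ", "))
  composites <- composites[!duplicated(names(composites))]
  for (nm in names(composites)) {
    if (nm %in% names(labels))
      stopf("composite '%s' collides with a labelled structure", nm)
    bad <- setdiff(composites[[nm]], names(labels))
    if (length(bad))
      stopf("composite '%s' references unknown structures: %s", nm,
            paste(bad, collapse = ", "))
  }
  known <- c(names(labels), names(composites))
  bad_seed <- setdiff(seeds, known)
  if (length(bad_seed))
    stopf("unknown seed structures: %s", paste(bad_seed, collapse = ", "))
  aux <- setdiff(names(labels), core_five)
  structure(list(labels = labels, core_five = core_five,
                 composites = composites, seeds = seeds,
                 aux_targets = aux),
            class = "bg_structure_set")
}

#' @export
print.bg_structure_set <- function(x, ...) {
  cat(sprintf(
    "Structure set: %d labelled (%s core), %d composites, seeds: %s\n",
    length(x$labels), length(x$core_five), length(x$composites),
    paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Resolve structure names to label sets
#'
#' Composite names (e.g. SN, GP) expand to the labels of their parts;
#' labelled names resolve to their single label.
#'
#' @param structures a \code{\link{structure_set}}.
#' @param names character vector of structure or composite names.
#' @return Integer vector of the union of labels.
#' @export
resolve_labels <- function(structures, names) {
  out <- integer(0)
  for (nm in names) {
    if (nm %in% base::names(structures$labels)) {
      out <- c(out, structures$labels[[nm]])
    } else if (nm %in% base::names(structures$composites)) {
      out <- c(out, unname(structures$labels[structures$composites[[nm]]]))
    } else {
      stopf("unknown structure name: %s", nm)
    }
  }
  sort(unique(out))
}

core_labels <- function(structures) {
  unname(structures$labels[structures$core_five])
}

seed_labels <- function(structures) {
  resolve_labels(structures, structures$seeds)
}

#' Read / write a structure set as YAML
#'
#' The YAML schema is a flat \code{name: label} map plus the reserved keys
#' \code{core_five}, \code{seeds} and \code{composites}.
#'
#' @param path a YAML file.
#' @return \code{read_structure_set}: a \code{\link{structure_set}}.
#' @export
read_structure_set <- function(path) {
  y <- yaml::read_yaml(path)
  reserved <- c("core_five", "seeds", "composites")
  labels <- unlist(y[setdiff(names(y), reserved)])
  args <- list(labels = labels)
  if (!is.null(y$core_five)) args$core_five <- unlist(y$core_five)
  if (!is.null(y$seeds)) args$seeds <- unlist(y$seeds)
  if (!is.null(y$composites))
    args$composites <- lapply(y$composites, unlist)
  do.call(structure_set, args)
}

#' @rdname read_structure_set
#' @param structures a \code{\link{structure_set}}.
#' @export
write_structure_set <- function(structures, path) {
  y <- c(as.list(structures$labels),
         list(core_five = structures$core_five,
              seeds = structures$seeds,
              composites = structures$composites))
  yaml::write_yaml(y, path)
  invisible(path)
}
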