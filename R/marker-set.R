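#' Marker set container
#'
#' A `MarkerSet` maps each cell population to an ordered list of feature ids
#' in one identifier namespace. It is the unit the scorer consumes. Feature
#' lists must be non-empty and a feature may belong to at most one
#' population (the defining property of a transcriptomic marker).
#'
#' @param markers Named list, population -> character vector of feature ids.
#' @param namespace Identifier namespace of all features.
#' @return An object of class `MarkerSet`.
#' @export
marker_set <- function(markers,
                       namespace = c("hugo_symbol", "probeset", "entrez")) {
  namespace <- match.arg(namespace)
  if (!is.list(markers) || is.null(names(markers)) ||
      any(!nzchar(names(markers)))) {
    stop("'markers' must be a named list (population -> feature ids)")
  }
  if (!length(markers)) stop("marker set has no populations")
  n <- lengths(markers)
  if (any(n == 0)) {
    stop("empty feature list for population(s): ",
         paste(names(markers)[n == 0], collapse = ", "))
  }
  all_feats <- unlist(markers, use.names = FALSE)
  dup <- unique(all_feats[duplicated(all_feats)])
  if (length(dup)) {
    stop("feature(s) assigned to more than one population: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  structure(list(markers = lapply(markers, as.character),
                 namespace = namespace),
            class = "MarkerSet")
}

#' @export
print.MarkerSet <- function(x, ...) {
  cat(sprintf("MarkerSet: %d populations, %d features [%s]\n",
              length(x$markers), length(unlist(x$markers)), x$namespace))
  invisible(x)
}

#' Read a marker configuration table
#'
#' Three-column TSV: `population`, `feature`, `namespace`. All rows must
#' share one namespace. Feature order within a population is preserved.
#'
#' @param path Path to the TSV file.
#' @return A [marker_set()] object.
#' @export
read_marker_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, colClasses = "character")
  req <- c("population", "feature", "namespace")
  if (!all(req %in% names(df))) {
    stop("marker table ", path, " needs columns ",
         paste(req, collapse = ", "))
  }
  ns <- unique(df$namespace)
  if (length(ns) != 1) {
    stop("marker table mixes namespaces: ", paste(ns, collapse = ", "))
  }
  marker_set(split(df$feature, factor(df$population, unique(df$population))),
             namespace = ns)
}

#' Write a marker set as a three-column TSV
#'
#' @param x A [marker_set()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_set <- function(x, path) {
  stopifnot(inherits(x, "MarkerSet"))
  df <- data.frame(
    population = rep(names(x$markers), lengths(x$markers)),
    feature = unlist(x$markers, use.names = FALSE),
    namespace = x$namespace, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled representative marker configuration
#'
#' Returns the illustrative marker set shipped with the package: a handful
#' of canonical markers per population (e.g. CD3D/CD5 for T cells, CD8B for
#' CD8 T cells, VWF/CDH5 for endothelial cells). It demonstrates the scorer
#' interface and the configuration format; it is NOT a validated screening
#' result, and production analyses should drop in a full marker TSV derived
#' from a purified-cell compendium.
#'
#' @return A [marker_set()] in the `hugo_symbol` namespace.
#' @export
default_markers <- function() {
  read_marker_set(system.file("extdata", "markers_representative.tsv",
                              package = "mcpkit", mustWork = TRUE))
}

#' Read a two-column sample label table
#'
#' @param path TSV with columns `sample_id` and `label`.
#' @return Data frame with character columns `sample_id` and `label`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("label table ", path, " needs columns sample_id, label")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in label table ", path)
  }
  df[c("sample_id", "label")]
}

#' Write a sample label table
#'
#' @param labels Data frame with columns `sample_id`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels[c("sample_id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
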