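#' Build a category pyramid
#'
#' The pyramid is a rooted directed acyclic graph organizing cell-population
#' labels (annotations carried by compendium samples) and categories
#' (screenable population nodes) by inclusion. Directed edges point from the
#' included child to the including parent; the single root is the node with
#' no parent. Positive label/category relations are inferred by transitive
#' closure of the inclusion edges; exclusion ("negative") and partial
#' overlap ("mixed") cannot be derived from inclusion topology and are
#' supplied as an explicit relation table. Any label/category pair that is
#' neither included nor explicitly declared defaults to negative, so the
#' stored relation table is exhaustive.
#'
#' @param labels Character vector of sample labels. A label may coincide
#'   with a category name (a node directly represented by samples).
#' @param categories Character vector of category names (screenable nodes
#'   plus structural nodes such as the root).
#' @param inclusion_edges Data frame with columns `child`, `parent`; each
#'   edge states child is included in parent.
#' @param relations Optional data frame with columns `label`, `category`,
#'   `relation` (one of `"positive"`, `"negative"`, `"mixed"`) overriding
#'   the default for pairs not linked by inclusion. Declaring a pair
#'   `negative` or `mixed` when inclusion implies `positive` is an error.
#' @param non_screenable Categories excluded from marker screening but kept
#'   as negative controls (e.g. tumor cell-line nodes). The root is always
#'   non-screenable.
#' @return An object of class `CategoryPyramid` with the dense relation
#'   matrix in `$relations` (labels x screenable categories).
#' @export
build_pyramid <- function(labels, categories, inclusion_edges,
                          relations = NULL, non_screenable = character()) {
  labels <- unique(as.character(labels))
  categories <- unique(as.character(categories))
  nodes <- union(labels, categories)
  if (!all(c("child", "parent") %in% names(inclusion_edges))) {
    stop("'inclusion_edges' needs columns 'child' and 'parent'")
  }
  ev <- unique(c(inclusion_edges$child, inclusion_edges$parent))
  unknown <- setdiff(ev, nodes)
  if (length(unknown)) {
    stop("inclusion edge references unknown node(s): ",
         paste(unknown, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    inclusion_edges[c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    stop("inclusion graph contains a cycle")
  }
  roots <- nodes[igraph::degree(g, mode = "out") == 0]
  if (length(roots) != 1) {
    stop("pyramid must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  }
  root <- roots
  d <- igraph::distances(g, to = root, mode = "out")
  if (any(is.infinite(d))) {
    stop("node(s) cannot reach the root: ",
         paste(nodes[is.infinite(d[, 1])], collapse = ", "))
  }

  screenable <- setdiff(categories, c(root, non_screenable))
  if (!length(screenable)) stop("no screenable category")

  # transitive closure: every node a label can reach by inclusion
  reach <- lapply(labels, function(l) {
    names(igraph::subcomponent(g, l, mode = "out"))
  })
  names(reach) <- labels

  rel <- matrix("negative", nrow = length(labels), ncol = length(screenable),
                dimnames = list(labels, screenable))
  for (l in labels) {
    pos <- intersect(reach[[l]], screenable)
    rel[l, pos] <- "positive"
  }
  if (!is.null(relations)) {
    req <- c("label", "category", "relation")
    if (!all(req %in% names(relations))) {
      stop("'relations' needs columns ", paste(req, collapse = ", "))
    }
    bad <- setdiff(relations$relation, c("positive", "negative", "mixed"))
    if (length(bad)) stop("unknown relation value(s): ",
                          paste(bad, collapse = ", "))
    unknown <- setdiff(relations$label, labels)
    if (length(unknown)) stop("relation references unknown label(s): ",
                              paste(unknown, collapse = ", "))
    unknown <- setdiff(relations$category, screenable)
    if (length(unknown)) {
      stop("relation references unknown or non-screenable category(s): ",
           paste(unknown, collapse = ", "))
    }
    key <- paste(relations$label, relations$category)
    if (anyDuplicated(key)) {
      stop("duplicated relation for pair(s): ",
           paste(key[duplicated(key)], collapse = "; "))
    }
    for (i in seq_len(nrow(relations))) {
      l <- relations$label[i]; c0 <- relations$category[i]
      r <- relations$relation[i]
      if (rel[l, c0] == "positive" && r != "positive") {
        stop(sprintf(
          "contradictory relation for ('%s', '%s'): inclusion implies positive but table says %s",
          l, c0, r))
      }
      rel[l, c0] <- r
    }
  }
  structure(list(labels = labels, categories = categories, root = root,
                 inclusion_edges = inclusion_edges[c("child", "parent")],
                 relations = rel, screenable = screenable,
                 non_screenable = setdiff(non_screenable, root)),
            class = "CategoryPyramid")
}

#' @export
print.CategoryPyramid <- function(x, ...) {
  cat(sprintf(
    "CategoryPyramid: %d labels, %d categories (%d screenable), root '%s'\n",
    length(x$labels), length(x$categories), length(x$screenable), x$root))
  invisible(x)
}

#' Partition compendium samples for one category
#'
#' Assigns every sample to exactly one of the positive (label included in
#' the category), negative (label strictly non-overlapping) or mixed (label
#' partly overlapping, e.g. PBMC for the CD8 T-cell category) sets. Mixed
#' samples are discarded by the downstream screen.
#'
#' @param pyramid A [build_pyramid()] object.
#' @param labels Data frame with columns `sample_id`, `label`.
#' @param category A screenable category of the pyramid.
#' @return A list of class `SamplePartition` with elements `category`,
#'   `positive_samples`, `negative_samples`, `mixed_samples`.
#' @export
partition_samples <- function(pyramid, labels, category) {
  stopifnot(inherits(pyramid, "CategoryPyramid"))
  if (!category %in% pyramid$screenable) {
    stop("unknown or non-screenable category: ", category)
  }
  unknown <- setdiff(labels$label, pyramid$labels)
  if (length(unknown)) {
    stop("sample label(s) absent from pyramid: ",
         paste(unique(unknown), collapse = ", "))
  }
  rel <- pyramid$relations[labels$label, category]
  structure(list(
    category = category,
    positive_samples = labels$sample_id[rel == "positive"],
    negative_samples = labels$sample_id[rel == "negative"],
    mixed_samples = labels$sample_id[rel == "mixed"]),
    class = "SamplePartition")
}

#' Read a pyramid definition from a TSV trio
#'
#' Expects in `dir`: `labels.tsv` (columns `node`, `is_label`,
#' `screenable`), `edges.tsv` (`child`, `parent`) and `relations.tsv`
#' (`label`, `category`, `relation`; may list only the non-default mixed /
#' negative overrides).
#'
#' @param dir Directory containing the three files.
#' @return A [build_pyramid()] object.
#' @export
read_pyramid <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", check.names = FALSE,
                                      colClasses = "character")
  nodes <- rd("labels.tsv")
  edges <- rd("edges.tsv")
  rels <- rd("relations.tsv")
  is_label <- as.logical(nodes$is_label)
  screenable <- as.logical(nodes$screenable)
  labels <- nodes$node[is_label]
  categories <- nodes$node  # every declared node is a graph node
  build_pyramid(labels, categories, edges,
                relations = if (nrow(rels)) rels else NULL,
                non_screenable = nodes$node[!screenable])
}

#' Bundled example pyramid
#'
#' A schematic pyramid covering the ten scored populations (T cells, CD8 T
#' cells, cytotoxic lymphocytes, NK cells, B lineage, monocytic lineage,
#' myeloid dendritic cells, neutrophils, endothelial cells, fibroblasts),
#' a PBMC mixed label and a tumor cell-line negative-control node. It
#' illustrates the schema; it is not a reconstruction of any full curated
#' compendium annotation.
#'
#' @return A [build_pyramid()] object.
#' @export
example_pyramid <- function() {
  read_pyramid(system.file("extdata", "pyramid", package = "mcpkit",
                           mustWork = TRUE))
}
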