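#' Estimate cell-population abundance scores
#'
#' For each population, the abundance score of a sample is the arithmetic
#' mean of the log2 expression of the population's markers found in the
#' matrix — equivalently the log2 geometric mean of their linear
#' expression. Scores are in arbitrary log2 units: they support comparisons
#' of one population's abundance across samples of one platform, not
#' comparisons between populations or across platforms.
#'
#' Markers absent from the input are dropped per population and reported in
#' the `coverage` field; a population with no matched marker is omitted
#' with a warning.
#'
#' @param expr An [ExpressionMatrix]. Linear-scale input is transformed to
#'   `log2(x + pseudocount)` before scoring.
#' @param markers A [marker_set()] in the same namespace as `expr`.
#' @param pseudocount Pseudocount used for the log2 transform of
#'   linear-scale input.
#' @return An object of class `ScoreMatrix`: `values` (populations x
#'   samples), `coverage` (population -> fraction of configured markers
#'   matched), `markers_used`, `namespace`.
#' @export
mcp_estimate <- function(expr, markers, pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(markers, "MarkerSet"))
  if (expr$namespace != markers$namespace) {
    stop(sprintf("namespace mismatch: expression is '%s', markers are '%s'",
                 expr$namespace, markers$namespace))
  }
  v <- expr$values
  if (expr$scale == "linear") v <- log2(v + pseudocount)
  used <- lapply(markers$markers, intersect, rownames(v))
  matched <- lengths(used) > 0
  if (!any(matched)) stop("no marker of any population found in the matrix")
  if (any(!matched)) {
    warning("population(s) with no matched marker omitted: ",
            paste(names(used)[!matched], collapse = ", "))
  }
  used <- used[matched]
  scores <- t(vapply(used, function(f) colMeans(v[f, , drop = FALSE]),
                     numeric(ncol(v))))
  dimnames(scores) <- list(names(used), colnames(v))
  structure(list(values = scores,
                 coverage = lengths(used) / lengths(markers$markers[matched]),
                 markers_used = used,
                 namespace = markers$namespace),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d populations x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Discriminative power of a population's score
#'
#' ROC AUC of a population's score row for separating the samples positive
#' for a category from the negative ones (per the pyramid partition; mixed
#' samples ignored). Used to check marker sets on labeled validation
#' compendia.
#'
#' @param scores A [mcp_estimate()] result on labeled samples.
#' @param labels Data frame (`sample_id`, `label`).
#' @param pyramid A [build_pyramid()] object.
#' @param category Screenable category whose score row is evaluated; must
#'   be a population present in `scores`.
#' @return A single AUC value.
#' @export
evaluate_markers <- function(scores, labels, pyramid, category) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  if (!category %in% rownames(scores$values)) {
    stop("no score row for population: ", category)
  }
  part <- partition_samples(pyramid, labels, category)
  sid <- colnames(scores$values)
  pos <- match(intersect(part$positive_samples, sid), sid)
  neg <- match(intersect(part$negative_samples, sid), sid)
  if (!length(pos)) stop("no scored positive sample for ", category)
  if (!length(neg)) stop("no scored negative sample for ", category)
  .auc_vec(scores$values[category, ], pos, neg)
}

#' Pairwise correlation of a population's markers
#'
#' Under the proportionality model — a true marker's bulk signal equals its
#' expression in the source population times that population's mRNA
#' proportion — any two markers of one population are proportional across
#' samples, so their Pearson correlation approaches 1 in noiseless data.
#' Strongly off-diagonal-positive correlation blocks are therefore the
#' expected signature of a coherent marker set.
#'
#' @param expr An [ExpressionMatrix].
#' @param markers A [marker_set()] object.
#' @param population Population whose markers are correlated; at least two
#'   must be present in `expr`.
#' @return Symmetric matrix of Pearson correlations with unit diagonal;
#'   rows with zero variance yield `NA` off-diagonal entries.
#' @export
tm_correlation <- function(expr, markers, population) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(markers, "MarkerSet"))
  feats <- intersect(markers$markers[[population]], rownames(expr$values))
  if (length(feats) < 2) {
    stop("need at least two matched markers for ", population)
  }
  v <- expr$values[feats, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[!is.finite(cc)] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Write a score matrix as TSV
#'
#' The header comment records the namespace and marker populations so that
#' score files from different marker configurations are not silently
#' concatenated.
#'
#' @param x A `ScoreMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "ScoreMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mcpkit scores; namespace=%s; populations=%s",
                     x$namespace,
                     paste(rownames(x$values), collapse = ",")), con)
  df <- data.frame(population = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @param path Path to the TSV.
#' @return A `ScoreMatrix` (coverage unknown, set to `NA`).
#' @export
read_score_matrix <- function(path) {
  first <- readLines(path, n = 1)
  ns <- sub(".*namespace=([^;]+);.*", "\\1", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  structure(list(values = vals,
                 coverage = stats::setNames(rep(NA_real_, nrow(vals)),
                                            rownames(vals)),
                 markers_used = NULL, namespace = ns),
            class = "ScoreMatrix")
}
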