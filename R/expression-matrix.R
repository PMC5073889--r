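#' Expression matrix container
#'
#' An `ExpressionMatrix` wraps a numeric matrix of expression values with
#' features in rows and samples in columns, together with the identifier
#' namespace of the features and the scale the values are stored on.
#' Microarray-like input is expected on the log2 scale; RNA-seq style
#' abundances may be stored linear and log-transformed at scoring time.
#'
#' @param values Numeric matrix, features x samples, with unique non-empty
#'   `rownames` (feature ids) and `colnames` (sample ids).
#' @param namespace Feature identifier namespace, one of `"probeset"`,
#'   `"hugo_symbol"`, `"entrez"`.
#' @param scale Scale of the stored values: `"log2"` or `"linear"`.
#'   Linear values must be non-negative.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `namespace` and `scale`.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, namespace = "hugo_symbol", scale = "log2")
ExpressionMatrix <- function(values,
                             namespace = c("probeset", "hugo_symbol", "entrez"),
                             scale = c("log2", "linear")) {
  namespace <- match.arg(namespace)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)")
  }
  fids <- rownames(values)
  sids <- colnames(values)
  if (is.null(fids) || is.null(sids)) {
    stop("'values' must have rownames (feature ids) and colnames (sample ids)")
  }
  dup <- fids[duplicated(fids)]
  if (length(dup)) {
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- sids[duplicated(sids)]
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 fids[bad[1]], sids[bad[2]]))
  }
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be non-negative")
  }
  structure(list(values = values, namespace = namespace, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$namespace, x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from delimited text
#'
#' The canonical dialect is tab-separated with feature ids in the first
#' column and sample ids in the header row.
#'
#' @param path Path to the delimited text file.
#' @inheritParams ExpressionMatrix
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return An [ExpressionMatrix].
#' @export
read_expression_matrix <- function(path,
                                   namespace = c("probeset", "hugo_symbol", "entrez"),
                                   scale = c("log2", "linear"),
                                   sep = "\t") {
  namespace <- match.arg(namespace)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) {
    stop("malformed header in ", path,
         ": need a feature-id column plus at least one sample column")
  }
  fids <- df[[1]]
  dup <- unique(fids[duplicated(fids)])
  if (length(dup)) {
    stop("duplicated feature id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric cell in %s at row '%s', column '%s': \"%s\"",
      path, fids[bad[1]], colnames(vals)[bad[2]], vals[bad[1], bad[2]]))
  }
  dimnames(num) <- list(fids, colnames(vals))
  ExpressionMatrix(num, namespace = namespace, scale = scale)
}

#' Write an expression matrix as delimited text
#'
#' @param x An [ExpressionMatrix].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map features of an expression matrix across identifier namespaces
#'
#' Features are renamed according to a two-column mapping (e.g. probe set to
#' HUGO gene symbol). When several source features map to the same target id,
#' their rows are collapsed by the per-sample arithmetic mean on the matrix's
#' stored scale.
#'
#' @param m An [ExpressionMatrix].
#' @param mapping Data frame with columns `from_id` and `to_id`.
#' @param policy What to do with features absent from the mapping:
#'   `"drop_unmapped"` removes them, `"error"` aborts.
#' @param to_namespace Namespace of the target identifiers.
#' @return An [ExpressionMatrix] in the target namespace.
#' @export
map_features <- function(m, mapping, policy = c("drop_unmapped", "error"),
                         to_namespace = c("hugo_symbol", "probeset", "entrez")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  policy <- match.arg(policy)
  to_namespace <- match.arg(to_namespace)
  if (!all(c("from_id", "to_id") %in% names(mapping))) {
    stop("'mapping' needs columns 'from_id' and 'to_id'")
  }
  mapping <- mapping[!duplicated(mapping[c("from_id", "to_id")]), , drop = FALSE]
  if (anyDuplicated(mapping$from_id)) {
    stop("'mapping' assigns several targets to one source feature")
  }
  hit <- feature_ids(m) %in% mapping$from_id
  if (!any(hit)) stop("no feature of the matrix is covered by the mapping")
  if (policy == "error" && !all(hit)) {
    stop(sum(!hit), " feature(s) not covered by the mapping, e.g. ",
         paste(utils::head(feature_ids(m)[!hit], 3), collapse = ", "))
  }
  sub <- m$values[hit, , drop = FALSE]
  grp <- mapping$to_id[match(rownames(sub), mapping$from_id)]
  # rowsum-then-divide implements the per-sample mean over colliding rows
  sums <- rowsum(sub, group = grp, reorder = FALSE)
  counts <- as.vector(table(factor(grp, levels = rownames(sums))))
  collapsed <- sums / counts
  ExpressionMatrix(collapsed, namespace = to_namespace, scale = m$scale)
}

#' Deduplicate samples by content checksum
#'
#' Samples whose (upstream-computed) file digests are identical are treated
#' as duplicates; within each digest group the sample from the oldest series
#' is kept, ties broken by lexicographic sample id.
#'
#' @param checksums Data frame with columns `sample_id`, `digest` and
#'   `series_date` (coercible with [as.Date()]; may be `NA` for samples
#'   whose digest is unique).
#' @return Character vector of kept sample ids, in input order.
#' @export
dedupe_samples <- function(checksums) {
  req <- c("sample_id", "digest", "series_date")
  if (!all(req %in% names(checksums))) {
    stop("'checksums' needs columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(checksums$sample_id)) {
    stop("duplicated sample_id in checksum table")
  }
  dates <- as.Date(checksums$series_date)
  keep <- vapply(split(seq_len(nrow(checksums)), checksums$digest),
    function(idx) {
      if (length(idx) == 1L) return(checksums$sample_id[idx])
      d <- dates[idx]
      if (anyNA(d)) {
        stop("missing series_date for duplicated digest '",
             checksums$digest[idx[1]], "'")
      }
      idx <- idx[d == min(d)]
      sort(checksums$sample_id[idx])[1]
    }, character(1))
  checksums$sample_id[checksums$sample_id %in% keep]
}
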