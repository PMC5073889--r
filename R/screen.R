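#' Screening thresholds for transcriptomic marker selection
#'
#' The screen retains a feature for a category only if all three criteria
#' hold with strict inequality: log2 fold change above `min_fc`, ROC AUC for
#' recognizing positive samples above `min_auc`, and specific fold change
#' above `min_sfc`. Defaults are the triple threshold used for purified-cell
#' compendium screening (FC > 2, AUC > 0.97, sFC > 1.5); boundary values
#' fail.
#'
#' @param min_fc Minimum log2 fold change (positive minus negative centroid).
#' @param min_auc Minimum area under the ROC curve, in (0.5, 1].
#' @param min_sfc Minimum specific fold change.
#' @return A list of class `ScreeningThresholds`.
#' @export
screening_thresholds <- function(min_fc = 2, min_auc = 0.97, min_sfc = 1.5) {
  if (min_auc <= 0.5 || min_auc > 1) stop("'min_auc' must be in (0.5, 1]")
  structure(list(min_fc = min_fc, min_auc = min_auc, min_sfc = min_sfc),
            class = "ScreeningThresholds")
}

.check_groups <- function(pos, neg) {
  if (!length(pos)) stop("empty positive sample set")
  if (!length(neg)) stop("empty negative sample set")
}

#' Per-feature log2 fold change between positive and negative samples
#'
#' FC is the difference between the positive centroid X (mean log2
#' expression over positive samples) and the grand negative centroid
#' (unweighted mean over all negative samples).
#'
#' @param expr An [ExpressionMatrix] on the log2 scale.
#' @param partition A [partition_samples()] result (mixed samples ignored).
#' @return Named numeric vector, one fold change per feature.
#' @export
fold_change <- function(expr, partition) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "log2") stop("fold_change expects log2-scale expression")
  pos <- intersect(partition$positive_samples, sample_ids(expr))
  neg <- intersect(partition$negative_samples, sample_ids(expr))
  .check_groups(pos, neg)
  rowMeans(expr$values[, pos, drop = FALSE]) -
    rowMeans(expr$values[, neg, drop = FALSE])
}

#' Per-feature specific fold change
#'
#' Negative samples are grouped into classes j = 1..k (their labels); with
#' per-class centroids Xbar_j, the specific fold change is
#' `(X - Xbar_min) / (Xbar_max - Xbar_min)`. It rewards features that are
#' both high in the positive class and homogeneously low across every
#' negative class. With a single negative class the spread is zero and the
#' value is +Inf (positive excess), -Inf (deficit) or 0 (equality).
#'
#' @inheritParams fold_change
#' @param class_of_negative Named character vector or data frame
#'   (`sample_id`, `label`) assigning each negative sample to a class.
#' @return Named numeric vector of specific fold changes.
#' @export
specific_fold_change <- function(expr, partition, class_of_negative) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "log2") {
    stop("specific_fold_change expects log2-scale expression")
  }
  if (is.data.frame(class_of_negative)) {
    class_of_negative <- stats::setNames(class_of_negative$label,
                                         class_of_negative$sample_id)
  }
  pos <- intersect(partition$positive_samples, sample_ids(expr))
  neg <- intersect(partition$negative_samples, sample_ids(expr))
  .check_groups(pos, neg)
  cls <- class_of_negative[neg]
  if (anyNA(cls)) stop("negative sample(s) without a class label")
  X <- rowMeans(expr$values[, pos, drop = FALSE])
  cent <- vapply(split(neg, cls), function(ss) {
    rowMeans(expr$values[, ss, drop = FALSE])
  }, numeric(nrow(expr$values)))
  cent <- matrix(cent, nrow = nrow(expr$values))  # features x k
  xmin <- apply(cent, 1, min)
  xmax <- apply(cent, 1, max)
  num <- X - xmin
  den <- xmax - xmin
  sfc <- ifelse(den > 0, num / den, sign(num) * Inf)
  sfc[den == 0 & num == 0] <- 0
  stats::setNames(sfc, rownames(expr$values))
}

# Mann-Whitney AUC of one numeric vector: P(pos > neg) + 0.5 P(tie),
# computed from midranks.
.auc_vec <- function(x, pos_idx, neg_idx) {
  n1 <- length(pos_idx); n2 <- length(neg_idx)
  r <- rank(c(x[pos_idx], x[neg_idx]))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Per-feature ROC AUC for identifying positive samples
#'
#' Equals the normalized Mann-Whitney U statistic: the probability that a
#' randomly drawn positive sample scores above a randomly drawn negative
#' one, with half credit for ties (midranks).
#'
#' @inheritParams fold_change
#' @return Named numeric vector of AUC values in \[0, 1\].
#' @export
positive_auc <- function(expr, partition) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  pos <- intersect(partition$positive_samples, sample_ids(expr))
  neg <- intersect(partition$negative_samples, sample_ids(expr))
  .check_groups(pos, neg)
  pi <- match(pos, sample_ids(expr))
  ni <- match(neg, sample_ids(expr))
  apply(expr$values, 1, .auc_vec, pos_idx = pi, neg_idx = ni)
}

#' Screen one category for transcriptomic markers
#'
#' Computes the criteria triplet (FC, sFC, AUC) for every feature against
#' the positive/negative partition of `category` (mixed samples discarded)
#' and flags features passing all three strict thresholds.
#'
#' @inheritParams fold_change
#' @param labels Data frame (`sample_id`, `label`) for compendium samples.
#' @param pyramid A [build_pyramid()] object.
#' @param category Screenable category to screen.
#' @param thresholds A [screening_thresholds()] object.
#' @return Data frame with one row per feature: `feature`, `category`, `X`
#'   (positive centroid), `Xbar` (grand negative centroid), `Xbar_min`,
#'   `Xbar_max` (extreme per-class negative centroids), `fc`, `sfc`, `auc`,
#'   `selected`.
#' @export
screen_category <- function(expr, labels, pyramid, category,
                            thresholds = screening_thresholds()) {
  part <- partition_samples(pyramid, labels, category)
  labs <- stats::setNames(labels$label, labels$sample_id)
  fc <- fold_change(expr, part)
  sfc <- specific_fold_change(expr, part, labs)
  auc <- positive_auc(expr, part)
  pos <- intersect(part$positive_samples, sample_ids(expr))
  neg <- intersect(part$negative_samples, sample_ids(expr))
  X <- rowMeans(expr$values[, pos, drop = FALSE])
  Xbar <- rowMeans(expr$values[, neg, drop = FALSE])
  cls <- labs[neg]
  cent <- vapply(split(neg, cls),
                 function(ss) rowMeans(expr$values[, ss, drop = FALSE]),
                 numeric(nrow(expr$values)))
  cent <- matrix(cent, nrow = nrow(expr$values))
  data.frame(
    feature = rownames(expr$values), category = category,
    X = X, Xbar = Xbar,
    Xbar_min = apply(cent, 1, min), Xbar_max = apply(cent, 1, max),
    fc = fc, sfc = sfc, auc = auc,
    selected = fc > thresholds$min_fc & auc > thresholds$min_auc &
      sfc > thresholds$min_sfc,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen every screenable category of the pyramid
#'
#' Applies [screen_category()] exhaustively. Categories with fewer than
#' `min_positive` positive samples, or with no negative samples, are
#' skipped and reported rather than failing the whole screen.
#'
#' @inheritParams screen_category
#' @param min_positive Minimum number of positive samples needed to screen
#'   a category reliably.
#' @return A list of class `ScreeningResult`: `markers` (category ->
#'   selected feature ids), `criteria` (row-bound per-category criteria
#'   tables), `skipped` (data frame `category`, `reason`).
#' @export
screen_all <- function(expr, labels, pyramid,
                       thresholds = screening_thresholds(),
                       min_positive = 30) {
  markers <- list()
  criteria <- list()
  skipped <- list()
  for (cat in pyramid$screenable) {
    part <- partition_samples(pyramid, labels, cat)
    npos <- length(intersect(part$positive_samples, sample_ids(expr)))
    nneg <- length(intersect(part$negative_samples, sample_ids(expr)))
    if (npos < min_positive) {
      skipped[[cat]] <- sprintf("too few (<%d) positive samples (%d)",
                                min_positive, npos)
      next
    }
    if (nneg == 0) {
      skipped[[cat]] <- "no negative samples"
      next
    }
    rec <- screen_category(expr, labels, pyramid, cat, thresholds)
    criteria[[cat]] <- rec
    markers[[cat]] <- rec$feature[rec$selected]
  }
  structure(list(
    markers = markers,
    criteria = if (length(criteria)) do.call(rbind, c(criteria, list(make.row.names = FALSE)))
               else NULL,
    skipped = data.frame(category = names(skipped),
                         reason = unlist(skipped, use.names = FALSE),
                         stringsAsFactors = FALSE)),
    class = "ScreeningResult")
}

#' @export
print.ScreeningResult <- function(x, ...) {
  cat(sprintf("ScreeningResult: %d categories screened, %d skipped\n",
              length(x$markers), nrow(x$skipped)))
  for (cat in names(x$markers)) {
    cat(sprintf("  %-30s %d marker(s)\n", cat, length(x$markers[[cat]])))
  }
  invisible(x)
}

#' Write a screening result to disk
#'
#' Emits the full criteria table and a marker-set TSV consumable by
#' [mcp_estimate()].
#'
#' @param x A [screen_all()] result.
#' @param criteria_path Output path for the criteria TSV.
#' @param markers_path Output path for the marker-set TSV.
#' @param namespace Namespace to record in the marker TSV.
#' @return Invisibly, the marker set written (or `NULL` if no category
#'   selected any feature).
#' @export
write_screening_result <- function(x, criteria_path, markers_path,
                                   namespace = "hugo_symbol") {
  stopifnot(inherits(x, "ScreeningResult"))
  utils::write.table(x$criteria, criteria_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sel <- x$markers[lengths(x$markers) > 0]
  if (!length(sel)) {
    warning("no marker selected for any category; marker TSV not written")
    return(invisible(NULL))
  }
  ms <- marker_set(sel, namespace = namespace)
  write_marker_set(ms, markers_path)
  invisible(ms)
}

#' Reduce marker sets by intersection across series
#'
#' Given marker maps screened independently in several series (e.g. a
#' discovery and validation compendium), keeps per category the features
#' present in every series, in the order of the first. Used to trim
#' oversized marker sets while keeping only reproducible markers.
#'
#' @param sets List (length >= 2) of named lists, category -> feature ids,
#'   in a common namespace.
#' @param mode Reduction rule; only `"intersection"` is defined.
#' @return Named list, category -> intersected features. Categories absent
#'   from any input set are dropped with a warning.
#' @export
reduce_markers <- function(sets, mode = c("intersection")) {
  mode <- match.arg(mode)
  if (length(sets) < 2) stop("need at least two marker sets to reduce")
  cats <- names(sets[[1]])
  common <- Reduce(intersect, lapply(sets, names))
  dropped <- setdiff(cats, common)
  if (length(dropped)) {
    warning("category(s) absent from some set, dropped: ",
            paste(dropped, collapse = ", "))
  }
  out <- lapply(stats::setNames(intersect(cats, common), intersect(cats, common)),
                function(cat) {
    feats <- Reduce(intersect, lapply(sets[-1], `[[`, cat), sets[[1]][[cat]])
    if (!length(feats)) warning("empty intersection for category: ", cat)
    feats
  })
  out
}

#' Significance of the overlap between two marker sets
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' overlap when `setB` is sampled from a universe of `universe_size`
#' features containing `setA`.
#'
#' @param setA,setB Character vectors of feature ids.
#' @param universe_size Number of features both screens could have chosen
#'   from.
#' @return P(overlap >= observed), a single numeric value.
#' @export
overlap_significance <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) > universe_size || length(setB) > universe_size) {
    stop("set larger than universe")
  }
  ov <- length(intersect(setA, setB))
  stats::phyper(ov - 1, length(setA), universe_size - length(setA),
                length(setB), lower.tail = FALSE)
}

#' Type-II error of an AUC cutoff under a normal two-group model
#'
#' Calibration simulation for the AUC threshold: each replicate draws
#' `n_neg` negative values from N(0, s) and `n_pos` positive values from
#' N(delta, s), computes the empirical AUC, and the returned type-II error
#' is the fraction of replicates whose AUC fails to exceed `auc_cutoff`
#' (i.e. a genuinely shifted feature that the screen would reject). The
#' population AUC of this model is `pnorm(delta / (s * sqrt(2)))`.
#'
#' @param n_neg,n_pos Group sizes per replicate.
#' @param delta Log2 effect size separating the groups.
#' @param s Common standard deviation; no default, as it should reflect the
#'   per-feature spread observed in the compendium being screened.
#' @param auc_cutoff AUC selection threshold under evaluation.
#' @param reps Number of replicates.
#' @param seed Integer seed; required for reproducibility.
#' @return A list: `type2_error`, `aucs` (per-replicate empirical AUC),
#'   `theoretical_auc`.
#' @export
screening_power_sim <- function(n_neg = 2000, n_pos = 100, delta = 2, s,
                                auc_cutoff = 0.97, reps = 200, seed) {
  if (missing(s)) stop("'s' is required (per-feature standard deviation)")
  if (missing(seed)) stop("'seed' is required")
  stopifnot(n_neg >= 1, n_pos >= 1, s > 0, reps >= 1)
  set.seed(seed)
  aucs <- vapply(seq_len(reps), function(i) {
    x <- c(stats::rnorm(n_pos, delta, s), stats::rnorm(n_neg, 0, s))
    .auc_vec(x, seq_len(n_pos), n_pos + seq_len(n_neg))
  }, numeric(1))
  list(type2_error = mean(aucs <= auc_cutoff), aucs = aucs,
       theoretical_auc = stats::pnorm(delta / (s * sqrt(2))))
}

#' Diagnostic quantile report for choosing the sFC cutoff
#'
#' Reports the distribution of specific fold changes among features that
#' already pass the FC and AUC thresholds, the view used to place the sFC
#' cutoff at the upper tail of that distribution. This is a diagnostic, not
#' an automatic cutoff chooser.
#'
#' @param criteria A criteria table from [screen_category()] /
#'   [screen_all()].
#' @param thresholds A [screening_thresholds()] object supplying the FC and
#'   AUC filters and the candidate sFC cutoff.
#' @param probs Quantile probabilities to report.
#' @return A list: `n_passing_fc_auc`, `sfc_quantiles`,
#'   `fraction_above_cutoff`.
#' @export
sfc_cutoff_report <- function(criteria, thresholds = screening_thresholds(),
                              probs = seq(0, 1, 0.1)) {
  keep <- criteria$fc > thresholds$min_fc & criteria$auc > thresholds$min_auc
  sfc <- criteria$sfc[keep]
  list(n_passing_fc_auc = sum(keep),
       sfc_quantiles = if (length(sfc)) stats::quantile(sfc, probs) else NULL,
       fraction_above_cutoff = if (length(sfc)) {
         mean(sfc > thresholds$min_sfc)
       } else NA_real_)
}
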