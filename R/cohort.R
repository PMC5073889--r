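#' Z-standardize scores within each dataset
#'
#' Population scores are in arbitrary platform-dependent units, so before
#' pooling cohorts each dataset's score rows are standardized to mean 0 and
#' sample SD 1 (ddof = 1), giving the scores comparable distributions
#' across datasets.
#'
#' @param scores A `ScoreMatrix` (see [mcp_estimate()]).
#' @param dataset_of_sample Named character vector mapping sample id ->
#'   dataset id, covering all scored samples.
#' @return A `ScoreMatrix` with transformed values.
#' @export
z_by_dataset <- function(scores, dataset_of_sample) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  sid <- colnames(scores$values)
  ds <- dataset_of_sample[sid]
  if (anyNA(ds)) {
    stop("sample(s) without dataset assignment: ",
         paste(utils::head(sid[is.na(ds)], 3), collapse = ", "))
  }
  out <- scores$values
  for (d in unique(ds)) {
    cols <- which(ds == d)
    if (length(cols) < 2) {
      stop("dataset '", d, "' has fewer than 2 samples")
    }
    block <- out[, cols, drop = FALSE]
    mu <- rowMeans(block)
    sdv <- apply(block, 1, stats::sd)
    if (any(sdv == 0)) {
      stop(sprintf("zero-variance score row '%s' in dataset '%s'",
                   rownames(block)[sdv == 0][1], d))
    }
    out[, cols] <- (block - mu) / sdv
  }
  scores$values <- out
  scores
}

#' Cross-platform pan-cancer score summary
#'
#' Combines per-platform matrices of median population scores by cancer
#' type into one representative matrix. For each platform and each
#' population column, values are centered at the platform's column mean,
#' divided by the platform's column SD, and rescaled by the average of the
#' column SDs across the platforms carrying that column; aligned cells are
#' then averaged across platforms, omitting platforms missing a given
#' cancer type.
#'
#' @param median_matrices List of numeric matrices (cancer types x
#'   populations) sharing population columns; cancer rows may differ.
#' @param platform_ids Optional names for the matrices (used in messages).
#' @return A matrix over the union of cancer types and of population
#'   columns. Columns present on a single platform are centered only (the
#'   averaged SD then equals that platform's own) and flagged with a
#'   warning.
#' @export
pan_summary <- function(median_matrices, platform_ids = NULL) {
  if (!length(median_matrices)) stop("no matrix given")
  if (is.null(platform_ids)) {
    platform_ids <- names(median_matrices)
    if (is.null(platform_ids)) {
      platform_ids <- paste0("platform", seq_along(median_matrices))
    }
  }
  all_pops <- unique(unlist(lapply(median_matrices, colnames)))
  all_cancers <- unique(unlist(lapply(median_matrices, rownames)))
  # per-platform column SDs, NA where the column is absent
  sds <- vapply(median_matrices, function(m) {
    out <- rep(NA_real_, length(all_pops))
    names(out) <- all_pops
    common <- intersect(all_pops, colnames(m))
    out[common] <- apply(m[, common, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    out
  }, numeric(length(all_pops)))
  sds <- matrix(sds, nrow = length(all_pops),
                dimnames = list(all_pops, platform_ids))
  n_platforms <- rowSums(!is.na(sds))
  single <- all_pops[n_platforms == 1]
  if (length(single)) {
    warning("column(s) present on a single platform: ",
            paste(single, collapse = ", "))
  }
  avg_sd <- rowMeans(sds, na.rm = TRUE)

  acc <- matrix(0, length(all_cancers), length(all_pops),
                dimnames = list(all_cancers, all_pops))
  cnt <- acc
  for (k in seq_along(median_matrices)) {
    m <- median_matrices[[k]]
    for (p in colnames(m)) {
      x <- m[, p]
      ok <- !is.na(x)
      if (!any(ok)) next
      z <- (x[ok] - mean(x[ok])) / stats::sd(x[ok]) * avg_sd[p]
      acc[names(z), p] <- acc[names(z), p] + z
      cnt[names(z), p] <- cnt[names(z), p] + 1
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Median-cut binarization of population scores
#'
#' Each population row is split at its cohort median: samples strictly
#' above the median are `"high"`, samples at or below it are `"low"`.
#' The rule is invariant under monotone transforms of the scores.
#'
#' @param scores A `ScoreMatrix` or a numeric matrix (populations x
#'   samples).
#' @return Character matrix of `"high"`/`"low"` with the same dimnames.
#' @export
median_binarize <- function(scores) {
  v <- if (inherits(scores, "ScoreMatrix")) scores$values else scores
  if (ncol(v) < 2) stop("need at least 2 samples to binarize")
  meds <- apply(v, 1, stats::median)
  out <- ifelse(v > meds, "high", "low")
  dimnames(out) <- dimnames(v)
  out
}

#' Four-class microenvironment assignment
#'
#' Concatenates the binarized states of two populations into the classes
#' high-high, high-low, low-high, low-low (order: `pop_a` then `pop_b`),
#' the stratification used for microenvironment-based tumor
#' classifications.
#'
#' @param bin A [median_binarize()] matrix.
#' @param pop_a,pop_b Row names of the two populations.
#' @return Named character vector, sample id -> class.
#' @export
micro_classes <- function(bin, pop_a, pop_b) {
  missing_pop <- setdiff(c(pop_a, pop_b), rownames(bin))
  if (length(missing_pop)) {
    stop("unknown population(s): ", paste(missing_pop, collapse = ", "))
  }
  stats::setNames(paste(bin[pop_a, ], bin[pop_b, ], sep = "-"),
                  colnames(bin))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-dataset effect estimates (e.g. log hazard ratios per 1-SD
#' score from univariate Cox models fitted separately in each dataset)
#' under a common-effect assumption, justified when the per-dataset scores
#' have been Z-standardized to a common distribution. Weights are inverse
#' variances: `pooled_beta = sum(b_i / se_i^2) / sum(1 / se_i^2)`,
#' `pooled_se = sqrt(1 / sum(1 / se_i^2))`.
#'
#' @param estimates Data frame with columns `beta` and `se` (one row per
#'   study), optionally `population` (must be a single value) and
#'   `dataset_id`.
#' @return A list of class `MetaResult`: `population`, `pooled_beta`,
#'   `pooled_se`, `z`, `p` (two-sided normal), `n_studies`.
#' @export
fixed_effect_meta <- function(estimates) {
  if (!all(c("beta", "se") %in% names(estimates))) {
    stop("'estimates' needs columns 'beta' and 'se'")
  }
  if (!nrow(estimates)) stop("no study estimate given")
  if (any(estimates$se <= 0)) stop("standard errors must be positive")
  pop <- NA_character_
  if ("population" %in% names(estimates)) {
    pop <- unique(estimates$population)
    if (length(pop) != 1) {
      stop("estimates mix populations: ", paste(pop, collapse = ", "))
    }
  }
  w <- 1 / estimates$se^2
  pooled_beta <- sum(w * estimates$beta) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  z <- pooled_beta / pooled_se
  structure(list(population = pop, pooled_beta = pooled_beta,
                 pooled_se = pooled_se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 n_studies = nrow(estimates)),
            class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf(
    "MetaResult%s: beta = %.4f (se %.4f), z = %.3f, p = %.3g, %d studies\n",
    if (is.na(x$population)) "" else paste0(" [", x$population, "]"),
    x$pooled_beta, x$pooled_se, x$z, x$p, x$n_studies))
  invisible(x)
}

#' Run the fixed-effect meta-analysis per population
#'
#' Convenience wrapper applying [fixed_effect_meta()] to each population of
#' a long study-estimate table.
#'
#' @param estimates Data frame with columns `dataset_id`, `population`,
#'   `beta`, `se`.
#' @return Data frame with one row per population: `population`,
#'   `pooled_beta`, `pooled_se`, `z`, `p`, `n_studies`.
#' @export
meta_by_population <- function(estimates) {
  parts <- split(estimates, estimates$population)
  do.call(rbind, lapply(parts, function(d) {
    m <- fixed_effect_meta(d)
    data.frame(population = m$population, pooled_beta = m$pooled_beta,
               pooled_se = m$pooled_se, z = m$z, p = m$p,
               n_studies = m$n_studies, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

#' Per-dataset univariate Cox estimates (optional convenience wrapper)
#'
#' Fits, for each dataset and population, a univariate Cox proportional
#' hazards model of overall survival on the (ideally dataset-standardized)
#' population score, returning the coefficient/SE pairs that
#' [fixed_effect_meta()] consumes. Requires the `survival` package; the
#' meta-analysis core itself never fits survival models.
#'
#' @param scores A `ScoreMatrix` (Z-standardize first with
#'   [z_by_dataset()]).
#' @param surv Data frame with columns `sample_id`, `time`, `event`
#'   (0/1).
#' @param dataset_of_sample Named character vector, sample id -> dataset.
#' @return Data frame with columns `dataset_id`, `population`, `beta`,
#'   `se`.
#' @export
cox_study_estimates <- function(scores, surv, dataset_of_sample) {
  if (!requireNamespace("survival", quietly = TRUE)) {
    stop("the 'survival' package is required for cox_study_estimates()")
  }
  stopifnot(inherits(scores, "ScoreMatrix"))
  sid <- intersect(colnames(scores$values), surv$sample_id)
  if (!length(sid)) stop("no scored sample has survival annotation")
  surv <- surv[match(sid, surv$sample_id), ]
  ds <- dataset_of_sample[sid]
  out <- list()
  for (d in unique(ds)) {
    idx <- which(ds == d)
    y <- survival::Surv(surv$time[idx], surv$event[idx])
    for (p in rownames(scores$values)) {
      x <- scores$values[p, sid[idx]]
      fit <- survival::coxph(y ~ x)
      out[[length(out) + 1L]] <- data.frame(
        dataset_id = d, population = p,
        beta = unname(stats::coef(fit)[1]),
        se = sqrt(unname(stats::vcov(fit)[1, 1])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
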