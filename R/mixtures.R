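#' Mixture design container
#'
#' A `MixtureDesign` holds the weight matrix W (source profiles x mixtures)
#' used to convolve purified-cell expression profiles into virtual bulk
#' mixtures. Weights are mRNA proportions: non-negative, each mixture
#' column summing to one.
#'
#' @param W Numeric matrix, sources x mixtures, with rownames (source
#'   labels) and colnames (mixture ids).
#' @return An object of class `MixtureDesign`.
#' @export
mixture_design <- function(W) {
  if (!is.matrix(W) || is.null(rownames(W)) || is.null(colnames(W))) {
    stop("'W' must be a matrix with source rownames and mixture colnames")
  }
  if (any(W < 0)) stop("mixture weights must be non-negative")
  cs <- colSums(W)
  if (any(abs(cs - 1) > 1e-12)) {
    stop("mixture column(s) do not sum to 1: ",
         paste(colnames(W)[abs(cs - 1) > 1e-12], collapse = ", "))
  }
  structure(list(W = W, source_labels = rownames(W)), class = "MixtureDesign")
}

#' @export
print.MixtureDesign <- function(x, ...) {
  cat(sprintf("MixtureDesign: %d sources x %d mixtures\n",
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Equal-immune-weight dilution design
#'
#' The 6 x 7 design in which five immune populations are introduced at a
#' common weight w spanning 0.002 to 0.18 per mixture, and a tumor cell
#' line takes the complement 1 - 5w (0.99 down to 0.1). Used to contrast
#' abundance scoring (which must track w) with within-leukocyte
#' proportion estimates (which stay flat).
#'
#' @param immune_weights Common per-population immune weight of each
#'   mixture.
#' @return A [mixture_design()] with rows T cells, NK cells, B cells,
#'   Monocytic lineage, Neutrophils, Tumor cell line.
#' @export
table4_design <- function(immune_weights = c(0.002, 0.004, 0.01, 0.02,
                                             0.04, 0.1, 0.18)) {
  pops <- c("T cells", "NK cells", "B cells", "Monocytic lineage",
            "Neutrophils")
  W <- rbind(matrix(rep(immune_weights, each = length(pops)),
                    nrow = length(pops)),
             1 - length(pops) * immune_weights)
  dimnames(W) <- list(c(pops, "Tumor cell line"),
                      paste0("mixture", seq_along(immune_weights)))
  mixture_design(W)
}

#' Transposed latin-square dilution design
#'
#' Reproduces the in vitro mRNA mixture layout: `n_dilutions` twofold
#' serial dilutions S0 (strongest) to S(n-1) of each immune population are
#' arranged in two transposed latin squares (each dilution level occurring
#' once per population and once per mixture within a square), on top of a
#' fixed amount of tumor cell-line background mRNA. Two additional
#' pure-background mixtures lead the layout. The latin squares decorrelate
#' the population proportions across mixtures, which is what makes
#' per-population specificity testable. Column proportions are normalized
#' to sum to one.
#'
#' @param n_dilutions Number of dilution levels (and immune populations).
#' @param dilution_factor Fold change between consecutive dilution levels.
#' @param background_weight Relative weight of the background mRNA aliquot,
#'   on the scale where an undiluted S0 aliquot weighs 1.
#' @return A [mixture_design()] with `2 + 2 * n_dilutions` mixtures; the
#'   dilution-level layout is attached as attribute `"levels"`.
#' @export
latin_square_design <- function(n_dilutions = 5, dilution_factor = 2,
                                background_weight = 1) {
  n <- n_dilutions
  pops <- if (n == 5) {
    c("NK cells", "B cells", "T cells", "Neutrophils", "Monocytic lineage")
  } else {
    paste("Population", seq_len(n))
  }
  sq1 <- outer(seq_len(n) - 1, seq_len(n) - 1,
               function(i, j) (j - i) %% n)
  sq2 <- outer(seq_len(n) - 1, seq_len(n) - 1,
               function(i, j) (-(i + j)) %% n)
  levels <- cbind(matrix(NA_integer_, n, 2), sq1, sq2)
  amounts <- rbind(
    cbind(matrix(0, n, 2),
          dilution_factor^-sq1, dilution_factor^-sq2),
    background_weight)
  amounts[nrow(amounts), ] <- background_weight
  W <- sweep(amounts, 2, colSums(amounts), "/")
  dimnames(W) <- list(c(pops, "Tumor cell line"),
                      paste0("mix", seq_len(2 + 2 * n)))
  d <- mixture_design(W)
  dimnames(levels) <- list(pops, colnames(W))
  attr(d, "levels") <- levels
  d
}

#' Simulate bulk mRNA mixtures from purified profiles
#'
#' Convolves linear-scale source profiles with the design weights and adds
#' i.i.d. standard-normal-scaled noise per matrix cell:
#' `S* = P W + e`, `S' = log2(S* clamped at floor)`. The clamp keeps the
#' log2 transform defined when noise drives low-signal cells non-positive.
#'
#' @param profiles Linear-scale [ExpressionMatrix], one column per design
#'   source (column names must cover the design's source labels).
#' @param design A [mixture_design()].
#' @param noise_sd Standard deviation of the additive noise (0 disables).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream
#'   (e.g. inside a seeded outer protocol).
#' @param floor Lower clamp applied before the log2 transform.
#' @return A list of class `SimulatedMixtures`: `linear` and `log2`
#'   [ExpressionMatrix] objects over the mixtures, `true_proportions` (the
#'   design's W), `seed`.
#' @export
simulate_mixtures <- function(profiles, design, noise_sd = 1, seed = NULL,
                              floor = 2^-10) {
  stopifnot(inherits(profiles, "ExpressionMatrix"),
            inherits(design, "MixtureDesign"))
  if (profiles$scale != "linear") {
    stop("simulate_mixtures expects linear-scale profiles")
  }
  missing_src <- setdiff(design$source_labels, colnames(profiles$values))
  if (length(missing_src)) {
    stop("profiles lack design source(s): ",
         paste(missing_src, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  P <- profiles$values[, design$source_labels, drop = FALSE]
  S <- P %*% design$W
  if (noise_sd > 0) {
    S <- S + matrix(stats::rnorm(length(S), 0, noise_sd), nrow = nrow(S))
  }
  lin <- ExpressionMatrix(pmax(S, 0), namespace = profiles$namespace,
                          scale = "linear")
  lg <- ExpressionMatrix(log2(pmax(S, floor)), namespace = profiles$namespace,
                         scale = "log2")
  structure(list(linear = lin, log2 = lg, true_proportions = design$W,
                 seed = seed),
            class = "SimulatedMixtures")
}

#' Dilution-series scoring protocol on simulated mixtures
#'
#' Repeats `n_runs` times: draw one expression profile per source phenotype
#' from the compendium (uniformly, with replacement across runs), convolve
#' the drawn profiles with the equal-immune-weight design, add noise, log2
#' transform, and score with [mcp_estimate()]. Returns per (population,
#' mixture) mean scores and standard errors across runs — with the default
#' 7-mixture design and 50 runs, 350 estimates per population.
#'
#' @param compendium A log2-scale [ExpressionMatrix] of purified profiles.
#' @param labels Data frame (`sample_id`, `label`) covering every design
#'   source label.
#' @param markers A [marker_set()] used for scoring.
#' @param n_runs Number of simulation runs.
#' @param noise_sd Additive noise standard deviation on the linear scale.
#' @param seed Integer seed (required).
#' @param design A [mixture_design()]; defaults to [table4_design()].
#' @return A list of class `DilutionProtocol`: `summary` (data frame
#'   `population`, `mixture`, `immune_weight`, `mean_score`, `se`),
#'   `scores` (array population x mixture x run), `n_estimates`
#'   (`n_runs * n mixtures`), `design`.
#' @export
run_fig4_protocol <- function(compendium, labels, markers, n_runs = 50,
                              noise_sd = 1, seed, design = table4_design()) {
  stopifnot(inherits(compendium, "ExpressionMatrix"))
  if (missing(seed)) stop("'seed' is required")
  if (compendium$scale != "log2") {
    stop("compendium must be on the log2 scale")
  }
  by_label <- split(labels$sample_id, labels$label)
  missing_ph <- setdiff(design$source_labels, names(by_label))
  if (length(missing_ph)) {
    stop("compendium has no sample for phenotype(s): ",
         paste(missing_ph, collapse = ", "))
  }
  set.seed(seed)
  lin_all <- 2^compendium$values
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    picks <- vapply(design$source_labels, function(l) {
      ids <- by_label[[l]]
      ids[sample.int(length(ids), 1)]
    }, character(1))
    prof <- lin_all[, picks, drop = FALSE]
    colnames(prof) <- design$source_labels
    pm <- ExpressionMatrix(prof, namespace = compendium$namespace,
                           scale = "linear")
    sim <- simulate_mixtures(pm, design, noise_sd = noise_sd, seed = NULL)
    runs[[r]] <- mcp_estimate(sim$log2, markers)$values
  }
  pops <- rownames(runs[[1]])
  mix <- colnames(design$W)
  arr <- array(unlist(runs),
               dim = c(length(pops), length(mix), n_runs),
               dimnames = list(pops, mix, NULL))
  mean_s <- apply(arr, c(1, 2), mean)
  se_s <- apply(arr, c(1, 2), stats::sd) / sqrt(n_runs)
  iw <- apply(design$W[setdiff(rownames(design$W), "Tumor cell line"), ,
                       drop = FALSE], 2, max)
  summary <- data.frame(
    population = rep(pops, times = length(mix)),
    mixture = rep(mix, each = length(pops)),
    immune_weight = rep(iw, each = length(pops)),
    mean_score = as.vector(mean_s),
    se = as.vector(se_s),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, scores = arr,
                 n_estimates = n_runs * length(mix), design = design),
            class = "DilutionProtocol")
}

#' Specification for the synthetic purified-cell compendium
#'
#' Parameters of the generator that emulates a labeled compendium of
#' purified-cell expression profiles with planted transcriptomic markers.
#' Defaults: each population carries 10 markers expressed 6 log2 units
#' above a baseline of 4, per-feature Gaussian noise of 0.5 log2 units, 40
#' samples per label, 500 unspecific background genes, and a tumor
#' cell-line label serving as negative control.
#'
#' @param n_populations Number of marker-bearing populations; with the
#'   default 5 the population names match the immune sources of
#'   [table4_design()], so the compendium feeds [run_fig4_protocol()]
#'   directly.
#' @param markers_per_population Number of planted markers per population.
#' @param n_background_genes Number of unspecific background genes.
#' @param samples_per_label Samples generated per label.
#' @param marker_log2_effect Planted marker elevation over baseline (log2).
#' @param noise_sd Per-feature Gaussian noise SD (log2 units).
#' @param baseline Baseline log2 expression level.
#' @param seed Integer seed (required at generation time).
#' @return A list of class `SynthCompendiumSpec`.
#' @export
synth_spec <- function(n_populations = 5, markers_per_population = 10,
                       n_background_genes = 500, samples_per_label = 40,
                       marker_log2_effect = 6, noise_sd = 0.5, baseline = 4,
                       seed = NULL) {
  stopifnot(n_populations >= 1, markers_per_population >= 1,
            n_background_genes >= 1, samples_per_label >= 1,
            marker_log2_effect >= 0, noise_sd >= 0)
  structure(list(n_populations = n_populations,
                 markers_per_population = markers_per_population,
                 n_background_genes = n_background_genes,
                 samples_per_label = samples_per_label,
                 marker_log2_effect = marker_log2_effect,
                 noise_sd = noise_sd, baseline = baseline, seed = seed),
            class = "SynthCompendiumSpec")
}

.synth_populations <- function(n) {
  if (n == 5) {
    c("T cells", "NK cells", "B cells", "Monocytic lineage", "Neutrophils")
  } else {
    paste("Population", seq_len(n))
  }
}

#' Generate a synthetic purified-cell compendium
#'
#' Builds a log2-scale expression matrix of labeled purified-cell samples
#' in which each population's planted markers are drawn from
#' `N(baseline + effect, sd)` within the population and `N(baseline, sd)`
#' everywhere else (background genes from `N(baseline, sd)` throughout),
#' together with the matching label table, the planted marker set, and a
#' flat pyramid whose tumor cell-line node is flagged as a non-screenable
#' negative control.
#'
#' @param spec A [synth_spec()] object.
#' @param seed Integer seed; overrides `spec$seed` if given.
#' @return A list: `expr` ([ExpressionMatrix], log2, hugo_symbol),
#'   `labels` (data frame `sample_id`, `label`), `markers` (planted
#'   [marker_set()]), `pyramid` ([build_pyramid()]), `spec`.
#' @export
synth_compendium <- function(spec = synth_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "SynthCompendiumSpec"))
  if (is.null(seed)) stop("'seed' is required")
  set.seed(seed)
  pops <- .synth_populations(spec$n_populations)
  labels_all <- c(pops, "Tumor cell line")
  n_samp <- spec$samples_per_label * length(labels_all)
  sample_label <- rep(labels_all, each = spec$samples_per_label)
  sample_id <- sprintf("S%04d", seq_len(n_samp))

  marker_names <- unlist(lapply(seq_along(pops), function(i) {
    sprintf("P%02d.TM%02d", i, seq_len(spec$markers_per_population))
  }))
  bg_names <- sprintf("BG%04d", seq_len(spec$n_background_genes))
  genes <- c(marker_names, bg_names)

  vals <- matrix(stats::rnorm(length(genes) * n_samp, spec$baseline,
                              spec$noise_sd),
                 nrow = length(genes),
                 dimnames = list(genes, sample_id))
  for (i in seq_along(pops)) {
    mk <- sprintf("P%02d.TM%02d", i, seq_len(spec$markers_per_population))
    in_pop <- sample_label == pops[i]
    vals[mk, in_pop] <- vals[mk, in_pop] + spec$marker_log2_effect
  }
  expr <- ExpressionMatrix(vals, namespace = "hugo_symbol", scale = "log2")
  labels <- data.frame(sample_id = sample_id, label = sample_label,
                       stringsAsFactors = FALSE)
  markers <- marker_set(
    stats::setNames(lapply(seq_along(pops), function(i) {
      sprintf("P%02d.TM%02d", i, seq_len(spec$markers_per_population))
    }), pops), namespace = "hugo_symbol")
  edges <- data.frame(child = labels_all, parent = "Microenvironment",
                      stringsAsFactors = FALSE)
  pyramid <- build_pyramid(labels_all, c("Microenvironment", labels_all),
                           edges, non_screenable = "Tumor cell line")
  list(expr = expr, labels = labels, markers = markers, pyramid = pyramid,
       spec = spec)
}

#' Ideal marker-exclusive source profiles
#'
#' Linear-scale profiles of one purified sample per population in which
#' every marker is expressed only in its own population (zero elsewhere)
#' and background genes are expressed equally everywhere. Under the
#' proportionality model these profiles make a marker's mixture signal
#' exactly `weight x source expression`, so population scores on noiseless
#' mixtures equal `log2(weight) + constant` — the reference fixture for
#' score-linearity checks.
#'
#' @param markers A [marker_set()]; one source column is created per
#'   population plus a `"Tumor cell line"` background column.
#' @param n_background Number of shared background genes.
#' @param marker_log2 log2 expression of a marker in its own population.
#' @param background_log2 log2 expression of background genes everywhere.
#' @return A linear-scale [ExpressionMatrix], genes x sources.
#' @export
synth_source_profiles <- function(markers, n_background = 100,
                                  marker_log2 = 12, background_log2 = 4) {
  stopifnot(inherits(markers, "MarkerSet"))
  pops <- names(markers$markers)
  srcs <- c(pops, "Tumor cell line")
  genes <- c(unlist(markers$markers, use.names = FALSE),
             sprintf("BG%04d", seq_len(n_background)))
  vals <- matrix(0, nrow = length(genes), ncol = length(srcs),
                 dimnames = list(genes, srcs))
  for (p in pops) vals[markers$markers[[p]], p] <- 2^marker_log2
  vals[grepl("^BG", genes), ] <- 2^background_log2
  ExpressionMatrix(vals, namespace = markers$namespace, scale = "linear")
}

#' Limit of detection by inverse regression
#'
#' Fits a least-squares line of known natural-log mRNA proportions on the
#' corresponding population scores over calibration mixtures, predicts the
#' log-proportion at the scores of control samples known to lack the
#' population, and reports the exponential of the mean prediction: the
#' mRNA fraction below which the population is indistinguishable from its
#' absence.
#'
#' @param scores Numeric vector of per-mixture population scores.
#' @param true_log_proportions Natural-log mRNA proportions matching
#'   `scores`.
#' @param control_scores Scores of samples lacking the population.
#' @return A list: `lod` (mRNA fraction), `fit` (the `lm` object),
#'   `predicted_log_proportions`.
#' @export
estimate_lod <- function(scores, true_log_proportions, control_scores) {
  if (length(scores) != length(true_log_proportions)) {
    stop("'scores' and 'true_log_proportions' lengths differ")
  }
  if (length(scores) < 3) stop("need at least 3 calibration mixtures")
  if (stats::sd(scores) == 0) stop("calibration scores have zero variance")
  fit <- stats::lm(lp ~ s, data = data.frame(lp = true_log_proportions,
                                             s = scores))
  pred <- stats::predict(fit, newdata = data.frame(s = control_scores))
  list(lod = exp(mean(pred)), fit = fit,
       predicted_log_proportions = unname(pred))
}

#' Bivariate linear model of a composite-population score
#'
#' Tests whether a cytotoxic-lymphocyte style score is driven by its two
#' contributing populations: regresses `2^score` on the NK and T mRNA
#' proportions by ordinary least squares. A non-collinear mixture layout
#' (e.g. transposed latin squares) is required for the coefficients to be
#' separately identifiable.
#'
#' @param score Numeric vector of per-mixture scores (log2 units).
#' @param nk_prop,t_prop mRNA proportions of the two contributing
#'   populations in each mixture.
#' @return A list: `coefficients` (named `b`, `a_NK`, `a_T`; a constant
#'   regressor is dropped with a warning and reported as `NA`),
#'   `p_values`, `r_squared`, `fit`.
#' @export
cytotoxic_model <- function(score, nk_prop, t_prop) {
  if (length(score) < 4) stop("need at least 4 mixtures")
  df <- data.frame(y = 2^score, NK = nk_prop, T_ = t_prop)
  drop_nk <- stats::sd(df$NK) == 0
  drop_t <- stats::sd(df$T_) == 0
  if (drop_nk && drop_t) stop("both regressors are constant")
  if (drop_nk) {
    warning("NK proportions constant; a_NK dropped")
    fit <- stats::lm(y ~ T_, data = df)
  } else if (drop_t) {
    warning("T proportions constant; a_T dropped")
    fit <- stats::lm(y ~ NK, data = df)
  } else {
    if (qr(cbind(1, df$NK, df$T_))$rank < 3) {
      stop("collinear mixture design: NK and T proportions are not separable")
    }
    fit <- stats::lm(y ~ NK + T_, data = df)
  }
  cf <- stats::coef(fit)
  # synthetic noiseless input triggers summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  pv <- sm$coefficients[, "Pr(>|t|)"]
  get <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else NA_real_
  getp <- function(nm) if (nm %in% names(pv)) unname(pv[nm]) else NA_real_
  list(coefficients = c(b = get("(Intercept)"), a_NK = get("NK"),
                        a_T = get("T_")),
       p_values = c(b = getp("(Intercept)"), a_NK = getp("NK"),
                    a_T = getp("T_")),
       r_squared = sm$r.squared, fit = fit)
}
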