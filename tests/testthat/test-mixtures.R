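test_that("the equal-immune-weight design reproduces the dilution grid", {
  d <- table4_design()
  expect_identical(dim(d$W), c(6L, 7L))
  expect_equal(unname(d$W["Tumor cell line", 1]), 0.99)
  expect_equal(unname(d$W["Tumor cell line", ]),
               c(0.99, 0.98, 0.95, 0.9, 0.8, 0.5, 0.1))
  expect_equal(unname(d$W["T cells", 7]), 0.18)
  expect_equal(unname(colSums(d$W)), rep(1, 7))
})

test_that("the latin-square design has valid transposed squares", {
  d <- latin_square_design()
  expect_identical(ncol(d$W), 12L)
  # the two leading mixes are pure background
  expect_equal(unname(d$W["Tumor cell line", 1:2]), c(1, 1))
  expect_true(all(d$W[1:5, 1:2] == 0))
  lv <- attr(d, "levels")
  for (block in list(lv[, 3:7], lv[, 8:12])) {
    for (i in 1:5) expect_setequal(block[i, ], 0:4)
    for (j in 1:5) expect_setequal(block[, j], 0:4)
  }
  # twofold dilution: within a column, level k weighs 2^-k of level 0
  w3 <- d$W[1:5, 3] * 2^lv[, 3]
  expect_true(all(abs(w3 - w3[1]) < 1e-12))
  expect_equal(unname(colSums(d$W)), rep(1, 12))
})

test_that("simulate_mixtures performs the stated linear convolution", {
  # zero noise, identity design -> profiles unchanged
  prof <- tiny_expr(list(g1 = c(10, 20), g2 = c(5, 0)), c("A", "B"),
                    scale = "linear")
  idW <- diag(2)
  dimnames(idW) <- list(c("A", "B"), c("mix1", "mix2"))
  sim <- simulate_mixtures(prof, mixture_design(idW), noise_sd = 0)
  expect_equal(sim$linear$values, prof$values, ignore_attr = "dimnames")
  # the log2 view clamps at the floor so zero cells stay defined
  expect_equal(sim$log2$values, log2(pmax(prof$values, 2^-10)),
               ignore_attr = "dimnames")
  # two equal sources mixed 50/50 equal either source
  prof2 <- tiny_expr(list(g = c(8, 8)), c("A", "B"), scale = "linear")
  hw <- matrix(c(0.5, 0.5), 2, dimnames = list(c("A", "B"), "m"))
  sim2 <- simulate_mixtures(prof2, mixture_design(hw), noise_sd = 0)
  expect_equal(unname(sim2$linear$values[1, 1]), 8)
  # hand-multiplied 3-gene toy against the first dilution column
  d <- table4_design()
  set.seed(4)
  vals <- matrix(runif(18, 1, 100), 3,
                 dimnames = list(paste0("g", 1:3), rownames(d$W)))
  p3 <- ExpressionMatrix(vals, "hugo_symbol", "linear")
  sim3 <- simulate_mixtures(p3, d, noise_sd = 0)
  expect_equal(unname(sim3$linear$values[, 1]),
               unname(0.002 * rowSums(vals[, 1:5]) + 0.99 * vals[, 6]))
  # column sums are conserved by the convolution
  expect_equal(unname(colSums(sim3$linear$values)),
               unname(colSums(vals) %*% d$W)[1, ])
  # mismatched sources error
  bad <- tiny_expr(list(g = c(1, 2)), c("X", "Y"), scale = "linear")
  expect_error(simulate_mixtures(bad, d), "lack design source")
})

test_that("simulation is reproducible under a fixed seed", {
  prof <- synth_source_profiles(marker_set(list(P = c("a", "b"))),
                                n_background = 10)
  d <- mixture_design(matrix(c(0.3, 0.7), 2,
                             dimnames = list(c("P", "Tumor cell line"),
                                             "m1")))
  s1 <- simulate_mixtures(prof, d, noise_sd = 1, seed = 123)
  s2 <- simulate_mixtures(prof, d, noise_sd = 1, seed = 123)
  expect_identical(s1$linear$values, s2$linear$values)
})

test_that("the dilution protocol tallies n_runs x mixtures estimates", {
  comp <- synth_compendium(synth_spec(n_background_genes = 50,
                                      samples_per_label = 6), seed = 31)
  pr <- run_fig4_protocol(comp$expr, comp$labels, comp$markers, n_runs = 4,
                          seed = 7)
  expect_identical(pr$n_estimates, 28)
  expect_identical(dim(pr$scores), c(5L, 7L, 4L))
  expect_identical(nrow(pr$summary), 35L)
  # fixed seed -> identical repeat
  pr2 <- run_fig4_protocol(comp$expr, comp$labels, comp$markers, n_runs = 4,
                           seed = 7)
  expect_identical(pr$scores, pr2$scores)
  expect_error(run_fig4_protocol(comp$expr, comp$labels, comp$markers,
                                 n_runs = 2),
               "seed")
  # a missing phenotype is a hard error
  sub <- comp$labels[comp$labels$label != "NK cells", ]
  expect_error(run_fig4_protocol(comp$expr, sub, comp$markers, n_runs = 1,
                                 seed = 1),
               "NK cells")
})

test_that("zero-noise protocol scores increase strictly with the weight", {
  comp <- synth_compendium(synth_spec(n_background_genes = 50,
                                      samples_per_label = 4), seed = 13)
  pr <- run_fig4_protocol(comp$expr, comp$labels, comp$markers, n_runs = 1,
                          noise_sd = 0, seed = 2)
  for (p in rownames(pr$scores)) {
    expect_true(all(diff(pr$scores[p, , 1]) > 0))
  }
})

test_that("the synthetic compendium closes the screen-and-score loop", {
  comp <- synth_compendium(synth_spec(n_background_genes = 100), seed = 17)
  res <- screen_all(comp$expr, comp$labels, comp$pyramid)
  for (p in names(comp$markers$markers)) {
    expect_setequal(res$markers[[p]], comp$markers$markers[[p]])
  }
  sc <- mcp_estimate(comp$expr, comp$markers)
  for (p in names(comp$markers$markers)) {
    expect_equal(evaluate_markers(sc, comp$labels, comp$pyramid, p), 1)
  }
  # no effect -> nothing selected
  comp0 <- synth_compendium(synth_spec(marker_log2_effect = 0,
                                       n_background_genes = 100), seed = 17)
  res0 <- screen_all(comp0$expr, comp0$labels, comp0$pyramid)
  expect_identical(sum(lengths(res0$markers)), 0L)
  # one sample per label: every category skipped by the positivity floor
  comp1 <- synth_compendium(synth_spec(samples_per_label = 1,
                                       n_background_genes = 20), seed = 17)
  res1 <- screen_all(comp1$expr, comp1$labels, comp1$pyramid)
  expect_length(res1$markers, 0)
  expect_identical(nrow(res1$skipped), 5L)
})

test_that("limit of detection inverts an exact calibration line", {
  scores <- c(1, 2, 3, 5, 8)
  lod <- estimate_lod(scores, scores - 10, rep(4, 6))
  expect_equal(lod$lod, exp(-6), tolerance = 1e-12)
  # control score at a training point predicts that point's proportion
  lod2 <- estimate_lod(scores, scores - 10, scores[2])
  expect_equal(lod2$lod, exp(scores[2] - 10), tolerance = 1e-12)
  # scale equivariance: c * proportions -> c * LOD
  lod3 <- estimate_lod(scores, scores - 10 + log(3), rep(4, 6))
  expect_equal(lod3$lod, 3 * lod$lod, tolerance = 1e-12)
  expect_error(estimate_lod(rep(2, 5), rep(1, 5), 1), "zero variance")
  expect_error(estimate_lod(1:2, 1:2, 1), "at least 3")
})

test_that("limit of detection recovers a noisy generative line", {
  set.seed(55)
  score <- seq(2, 9, length.out = 10)
  truth <- estimate_lod(score, 0.9 * score - 11, 3.5)$lod
  lods <- replicate(30, {
    estimate_lod(score, 0.9 * score - 11 + rnorm(10, 0, 0.05), 3.5)$lod
  })
  expect_lt(abs(mean(lods) - truth) / truth, 0.1)
})

test_that("the bivariate mixture model recovers exact coefficients", {
  d <- latin_square_design()
  nk <- d$W["NK cells", ]; tc <- d$W["T cells", ]
  y <- 3 * nk + 1 * tc + 0.5
  fit <- cytotoxic_model(log2(y), nk, tc)
  expect_equal(unname(fit$coefficients),
               c(0.5, 3, 1), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant NK column is dropped with a warning
  expect_warning(fit0 <- cytotoxic_model(log2(1 + tc), rep(0, 12), tc),
                 "a_NK dropped")
  expect_true(is.na(fit0$coefficients["a_NK"]))
  # collinear proportions cannot be separated
  expect_error(cytotoxic_model(log2(1 + nk), nk, 2 * nk), "collinear")
})

test_that("noisy bivariate fits cover the true coefficients", {
  d <- latin_square_design()
  nk <- d$W["NK cells", ]; tc <- d$W["T cells", ]
  set.seed(77)
  hits <- replicate(200, {
    y <- 3 * nk + 1 * tc + 0.5 + rnorm(12, 0, 0.01)
    f <- cytotoxic_model(log2(pmax(y, 1e-9)), nk, tc)
    ci <- confint(f$fit)
    ci["NK", 1] <= 3 && 3 <= ci["NK", 2]
  })
  expect_gte(mean(hits), 0.9)
})
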