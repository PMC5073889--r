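make_scores <- function(v) {
  structure(list(values = v,
                 coverage = stats::setNames(rep(1, nrow(v)), rownames(v)),
                 markers_used = NULL, namespace = "hugo_symbol"),
            class = "ScoreMatrix")
}

test_that("within-dataset Z-transform standardizes each score row", {
  v <- matrix(c(1, 2, 3), 1, dimnames = list("P", paste0("s", 1:3)))
  ds <- c(s1 = "d1", s2 = "d1", s3 = "d1")
  z <- z_by_dataset(make_scores(v), ds)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  # two identical datasets transform to identical blocks
  v2 <- cbind(v, v + 10)
  colnames(v2) <- paste0("s", 1:6)
  ds2 <- setNames(rep(c("d1", "d2"), each = 3), colnames(v2))
  z2 <- z_by_dataset(make_scores(v2), ds2)
  expect_equal(unname(z2$values[, 1:3]), unname(z2$values[, 4:6]))
  # property: per-dataset mean ~0 and SD ~1
  set.seed(3)
  v3 <- matrix(rnorm(60, 5, 2), 3, 20,
               dimnames = list(paste0("P", 1:3), paste0("s", 1:20)))
  ds3 <- setNames(rep(c("a", "b"), each = 10), colnames(v3))
  z3 <- z_by_dataset(make_scores(v3), ds3)$values
  for (d in c("a", "b")) {
    blk <- z3[, ds3[colnames(z3)] == d]
    expect_true(all(abs(rowMeans(blk)) < 1e-10))
    expect_true(all(abs(apply(blk, 1, sd) - 1) < 1e-10))
  }
  # zero-variance row is named in the error
  v4 <- matrix(c(1, 1, 1, 2, 3, 4), 2, byrow = TRUE,
               dimnames = list(c("Flat", "Ok"), paste0("s", 1:3)))
  expect_error(z_by_dataset(make_scores(v4), ds), "Flat")
})

test_that("pan-cancer summary rescales by the cross-platform average SD", {
  # two platforms, same cancers, hand-derived expectation
  a <- matrix(c(1, 3), 2, dimnames = list(c("c1", "c2"), "P"))
  b <- matrix(c(10, 16), 2, dimnames = list(c("c1", "c2"), "P"))
  out <- pan_summary(list(A = a, B = b))
  avg_sd <- (sd(c(1, 3)) + sd(c(10, 16))) / 2
  expect_equal(unname(out[, "P"]),
               c((-1 / sd(c(1, 3))) * avg_sd, (1 / sd(c(1, 3))) * avg_sd))
  # identical matrices with equal SDs: output = column-centered input
  m <- matrix(c(1, 2, 4), 3, dimnames = list(paste0("c", 1:3), "P"))
  out2 <- pan_summary(list(m, m, m))
  expect_equal(unname(out2[, "P"]), c(1, 2, 4) - mean(c(1, 2, 4)))
  # a cancer missing from one platform keeps the other platform's value
  b2 <- matrix(c(10, 16, 13), 3, dimnames = list(c("c1", "c2", "c9"), "P"))
  out3 <- pan_summary(list(A = a, B = b2))
  expect_true("c9" %in% rownames(out3))
  expect_false(is.na(out3["c9", "P"]))
  # column on a single platform warns
  a4 <- matrix(c(1, 3), 2, dimnames = list(c("c1", "c2"), "Q"))
  expect_warning(pan_summary(list(a, a4)), "single platform")
})

test_that("median cut splits strictly-above from at-or-below", {
  v <- matrix(c(1, 2, 3, 4), 1, dimnames = list("P", paste0("s", 1:4)))
  expect_equal(unname(median_binarize(v)[1, ]),
               c("low", "low", "high", "high"))
  # the median sample itself is low for odd n; all-equal rows are all low
  v3 <- matrix(c(1, 2, 3), 1, dimnames = list("P", paste0("s", 1:3)))
  expect_equal(unname(median_binarize(v3)[1, ]), c("low", "low", "high"))
  ve <- matrix(rep(7, 4), 1, dimnames = list("P", paste0("s", 1:4)))
  expect_true(all(median_binarize(ve) == "low"))
  # invariance under monotone transforms
  set.seed(12)
  r <- matrix(rnorm(30), 1, dimnames = list("P", paste0("s", 1:30)))
  expect_identical(median_binarize(r), median_binarize(exp(r)))
})

test_that("micro classes are the concatenated binarizations", {
  bin <- matrix(c("high", "high", "low", "low",
                  "high", "low", "high", "low"), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), paste0("s", 1:4)))
  cls <- micro_classes(bin, "A", "B")
  expect_equal(unname(cls),
               c("high-high", "high-low", "low-high", "low-low"))
  expect_error(micro_classes(bin, "A", "Z"), "unknown population")
  # class counts equal the 2x2 contingency of the binarizations
  set.seed(101)
  v <- matrix(rnorm(200), 2, 100, dimnames = list(c("A", "B"),
                                                  paste0("s", 1:100)))
  b <- median_binarize(v)
  cls2 <- micro_classes(b, "A", "B")
  tab <- table(b["A", ], b["B", ])
  expect_equal(unname(sum(cls2 == "high-high")), tab["high", "high"],
               ignore_attr = TRUE)
  expect_equal(unname(sum(cls2 == "low-high")), tab["low", "high"],
               ignore_attr = TRUE)
})

test_that("independent binarizations give near-uniform class frequencies", {
  set.seed(202)
  v <- matrix(rnorm(20000), 2, 10000,
              dimnames = list(c("A", "B"), paste0("s", 1:10000)))
  cls <- micro_classes(median_binarize(v), "A", "B")
  counts <- table(factor(cls, c("high-high", "high-low", "low-high",
                                "low-low")))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("fixed-effect pooling matches the closed form", {
  est <- data.frame(dataset_id = c("d1", "d2"), population = "T cells",
                    beta = c(0.5, 1.0), se = c(0.1, 0.1))
  m <- fixed_effect_meta(est)
  expect_equal(m$pooled_beta, 0.75)
  expect_equal(m$pooled_se, sqrt(1 / 200))
  expect_equal(m$z, m$pooled_beta / m$pooled_se)
  expect_equal(m$p, 2 * pnorm(-abs(m$z)))
  expect_identical(m$n_studies, 2L)
  # single study: identity
  m1 <- fixed_effect_meta(data.frame(beta = 0.3, se = 0.2))
  expect_equal(m1$pooled_beta, 0.3)
  expect_equal(m1$pooled_se, 0.2)
  # an uninformative study has vanishing influence
  m2 <- fixed_effect_meta(data.frame(beta = c(0.3, 50), se = c(0.2, 1e8)))
  expect_equal(m2$pooled_beta, 0.3, tolerance = 1e-6)
  expect_error(fixed_effect_meta(data.frame(beta = 1, se = 0)), "positive")
  expect_error(
    fixed_effect_meta(data.frame(beta = 1:2, se = 1,
                                 population = c("A", "B"))),
    "mix populations")
})

test_that("pooled estimates are convex and reduce variance", {
  set.seed(303)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    est <- data.frame(beta = rnorm(k), se = runif(k, 0.01, 2))
    m <- fixed_effect_meta(est)
    expect_gte(m$pooled_beta, min(est$beta) - 1e-12)
    expect_lte(m$pooled_beta, max(est$beta) + 1e-12)
    expect_lte(m$pooled_se, min(est$se) + 1e-12)
  }
})

test_that("meta_by_population pools each population separately", {
  est <- data.frame(dataset_id = rep(c("d1", "d2"), 2),
                    population = rep(c("A", "B"), each = 2),
                    beta = c(0.5, 1.0, -0.2, -0.4),
                    se = c(0.1, 0.1, 0.2, 0.2))
  out <- meta_by_population(est)
  expect_identical(nrow(out), 2L)
  expect_equal(out$pooled_beta[out$population == "A"], 0.75)
  expect_equal(out$pooled_beta[out$population == "B"], -0.3)
})

test_that("the optional Cox wrapper emits poolable coefficient pairs", {
  skip_if_not_installed("survival")
  set.seed(404)
  n <- 120
  v <- matrix(rnorm(n, 0, 1), 1, dimnames = list("P", paste0("s", 1:n)))
  ds <- setNames(rep(c("d1", "d2"), each = n / 2), colnames(v))
  # hazard increases with the score
  time <- rexp(n, rate = exp(0.8 * v[1, ]))
  surv <- data.frame(sample_id = colnames(v), time = time, event = 1)
  est <- cox_study_estimates(make_scores(v), surv, ds)
  expect_identical(nrow(est), 2L)
  expect_true(all(est$se > 0))
  m <- fixed_effect_meta(est[c("beta", "se")])
  expect_gt(m$pooled_beta, 0)
  expect_lt(m$p, 0.01)
})
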