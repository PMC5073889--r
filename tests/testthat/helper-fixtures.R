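# Shared fixtures and independent oracles.

# Brute-force Mann-Whitney AUC over all (positive, negative) pairs:
# full credit when pos > neg, half credit on ties.
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + (p > n) + 0.5 * (p == n)
  }
  s / (length(pos) * length(neg))
}

# Tiny expression matrix from a named list of feature -> sample values.
tiny_expr <- function(rows, sample_ids, namespace = "hugo_symbol",
                      scale = "log2") {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), sample_ids)
  ExpressionMatrix(m, namespace = namespace, scale = scale)
}

# Minimal two-level pyramid: root + flat categories, every label its own
# category, with optional explicit relations.
flat_pyramid <- function(labels, non_screenable = character(),
                         relations = NULL) {
  build_pyramid(labels, c("root", labels),
                data.frame(child = labels, parent = "root"),
                relations = relations, non_screenable = non_screenable)
}

# Hand-made partition without going through a pyramid.
raw_partition <- function(pos, neg, mixed = character()) {
  structure(list(category = "cat", positive_samples = pos,
                 negative_samples = neg, mixed_samples = mixed),
            class = "SamplePartition")
}
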