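# Shared fixtures, built once per test run. Small profiles keep unit tests
# fast; the full default generator is exercised in the acceptance tests.

small_profiles <- function() {
  if (is.null(.fixture_env$small_profiles))
    .fixture_env$small_profiles <-
      default_profiles(n_genes = 300, n_markers = 5)
  .fixture_env$small_profiles
}

small_reference <- function() {
  if (is.null(.fixture_env$small_reference))
    .fixture_env$small_reference <-
      generate_reference(small_profiles(), 220, seed = 5)
  .fixture_env$small_reference
}

.fixture_env <- new.env(parent = emptyenv())

# Brute-force KNN by full pairwise Euclidean distances.
brute_knn <- function(query, ref, k) {
  t(apply(query, 1, function(q) {
    d <- sqrt(colSums((t(ref) - q)^2))
    order(d)[seq_len(k)]
  }))
}

# A fabricated DE result table with a given significance/direction mask.
fake_de <- function(genes, sig_up, sig_down) {
  data.frame(gene = genes,
             log2fc = ifelse(genes %in% sig_down, -2,
                             ifelse(genes %in% sig_up, 2, 0)),
             significant = genes %in% c(sig_up, sig_down),
             stringsAsFactors = FALSE)
}
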