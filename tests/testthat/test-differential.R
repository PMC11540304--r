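# Pseudobulk DE, gene-set logic, CLR and the ADT Mann-Whitney test.

test_that("pseudobulk replicates partition cells and conserve counts", {
  ref <- small_reference()
  cells <- colnames(ref$rna)[1:9]
  reps <- pseudobulk_replicates(ref$rna, cells, n_reps = 3, seed = 1)
  expect_equal(ncol(reps), 3)
  expect_equal(unname(rowSums(reps)),
               unname(Matrix::rowSums(ref$rna[, cells])))
  expect_identical(reps, pseudobulk_replicates(ref$rna, cells, 3, seed = 1))
  expect_error(pseudobulk_replicates(ref$rna, cells[1:2], 3, seed = 1),
               "n_reps")
})

test_that("de_test excludes mito/ribo and low-count genes before testing", {
  set.seed(2)
  genes <- c("MT-G1", "RPL1", "RPS9", "LOWCOUNT", sprintf("G%03d", 1:60))
  a <- matrix(rnbinom(length(genes) * 3, mu = 60, size = 5),
              ncol = 3, dimnames = list(genes, NULL))
  b <- matrix(rnbinom(length(genes) * 3, mu = 60, size = 5),
              ncol = 3, dimnames = list(genes, NULL))
  a["LOWCOUNT", ] <- c(1, 0, 1); b["LOWCOUNT", ] <- c(0, 1, 0)
  res <- de_test(a, b)
  expect_false(any(c("MT-G1", "RPL1", "RPS9", "LOWCOUNT") %in% res$gene))
  expect_true(all(res$padj >= res$pvalue - 1e-12))
})

test_that("de_test log2FC flips sign under group swap", {
  set.seed(3)
  genes <- sprintf("G%03d", 1:80)
  a <- matrix(rnbinom(80 * 3, mu = 80, size = 5), ncol = 3,
              dimnames = list(genes, NULL))
  b <- matrix(rnbinom(80 * 3, mu = 80, size = 5), ncol = 3,
              dimnames = list(genes, NULL))
  b[1:5, ] <- b[1:5, ] * 6
  r1 <- de_test(a, b)
  r2 <- de_test(b, a)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-4)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-4)
})

test_that("spiked genes are detected with the stated thresholds", {
  set.seed(4)
  genes <- sprintf("G%03d", 1:300)
  spiked <- genes[1:20]
  a <- matrix(rnbinom(300 * 3, mu = 100, size = 10), ncol = 3,
              dimnames = list(genes, NULL))
  b <- matrix(rnbinom(300 * 3, mu = 100, size = 10), ncol = 3,
              dimnames = list(genes, NULL))
  a[spiked, ] <- matrix(rnbinom(20 * 3, mu = 400, size = 10), ncol = 3)
  res <- de_test(a, b)
  hit <- res$gene[res$significant & res$log2fc > 0]
  expect_gte(mean(spiked %in% hit), 0.8)
  expect_lte(mean(setdiff(genes, spiked) %in% res$gene[res$significant]),
             0.01)
})

test_that("cluster-unique and pan gene sets equal brute-force set logic", {
  set.seed(5)
  genes <- sprintf("G%03d", 1:100)
  results <- lapply(setNames(1:11, paste0("cl", 1:11)), function(i) {
    up <- sample(genes, 20)
    dn <- sample(setdiff(genes, up), 10)
    fake_de(genes, up, dn)
  })
  uniq <- cluster_specific_genes(results)
  pan <- pan_signature(results)
  sig_any <- lapply(results, function(r) r$gene[r$significant])
  for (cl in names(results)) {
    others <- unique(unlist(sig_any[setdiff(names(results), cl)]))
    r <- results[[cl]]
    expect_setequal(uniq[[cl]]$up,
                    setdiff(r$gene[r$significant & r$log2fc > 0], others))
    expect_setequal(uniq[[cl]]$down,
                    setdiff(r$gene[r$significant & r$log2fc < 0], others))
  }
  expect_setequal(pan$up, Reduce(intersect, lapply(results, function(r)
    r$gene[r$significant & r$log2fc > 0])))
  expect_error(pan_signature(results[1:10], required = names(results)),
               "cl11")
})

test_that("a gene significant in exactly one cluster is unique to it", {
  genes <- c("g1", "g2", "g3")
  res <- list(A = fake_de(genes, "g1", character(0)),
              B = fake_de(genes, "g2", character(0)),
              C = fake_de(genes, c("g2", "g3"), character(0)))
  uniq <- cluster_specific_genes(res)
  expect_identical(uniq$A$up, "g1")
  expect_identical(uniq$B$up, character(0))  # shared with C
  expect_identical(uniq$C$up, "g3")
})

test_that("CLR values center to zero and match hand arithmetic", {
  adt <- matrix(c(1, 3, 7), 3, 1,
                dimnames = list(c("a", "b", "c"), "cell1"))
  clr <- clr_normalize(adt)
  hand <- log(c(2, 4, 8)) - mean(log(c(2, 4, 8)))
  expect_equal(unname(clr[, 1]), hand)

  ref <- small_reference()
  clr2 <- clr_normalize(ref$adt)
  expect_equal(unname(colSums(clr2)), rep(0, ncol(clr2)), tolerance = 1e-9)

  uniform <- matrix(5, 4, 2, dimnames = list(letters[1:4], c("x", "y")))
  expect_true(all(clr_normalize(uniform) == 0))
})

test_that("Mann-Whitney U and exact p equal full enumeration for (4,4)", {
  enumerate_mw <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    u_obs <- sum(r[1:4]) - 4 * 5 / 2
    mu <- 4 * 4 / 2
    combs <- combn(8, 4)
    u_all <- apply(combs, 2, function(idx) sum(r[idx]) - 10)
    list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
  }
  set.seed(6)
  for (i in 1:20) {
    x <- rpois(4, 8); y <- rpois(4, 12)
    # a constant second antibody keeps the CLR of the first monotone in it
    adt <- matrix(c(rbind(c(x, y), 10)), 2, 8,
                  dimnames = list(c("ab", "ctrl"), sprintf("c%d", 1:8)))
    res <- adt_differential(adt, sprintf("c%d", 1:4), sprintf("c%d", 5:8),
                            p_cut = 0.05)
    clr <- clr_normalize(adt)
    oracle <- enumerate_mw(clr["ab", 1:4], clr["ab", 5:8])
    expect_equal(res$u[res$adt == "ab"], oracle$u)
    expect_equal(res$pvalue[res$adt == "ab"], oracle$p)
  }
})

test_that("identical ADT groups are never significant and Bonferroni holds", {
  ref <- small_reference()
  cells <- colnames(ref$adt)[1:40]
  res <- adt_differential(ref$adt, cells, cells)
  expect_equal(res$log2fc, rep(0, nrow(res)))
  expect_false(any(res$significant))
  expect_equal(res$padj, pmin(1, nrow(res) * res$pvalue))
  r1 <- adt_differential(ref$adt[1, , drop = FALSE],
                         colnames(ref$adt)[1:30], colnames(ref$adt)[31:60])
  expect_equal(r1$padj, r1$pvalue)
})
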