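# The generators must be deterministic, honor their generative parameters
# (checked against closed-form moments), and keep truth records complete.

test_that("generators are bit-identical under a fixed seed", {
  prof <- small_profiles()
  a <- generate_reference(prof[1:2], 200, seed = 1)
  b <- generate_reference(prof[1:2], 200, seed = 1)
  expect_identical(a$rna, b$rna)
  expect_identical(a$adt, b$adt)
  expect_identical(a$truth, b$truth)

  sig <- bcrabl_signature(prof, n_up = 10, n_down = 5)
  des <- patient_design("P1", c(Primitive = 0.5, GMP = 0.5), 0.3,
                        n_cells = 150, seed = 9)
  p1 <- generate_patient(des, prof, sig)
  p2 <- generate_patient(des, prof, sig)
  expect_identical(p1$rna, p2$rna)

  h1 <- generate_hto(a$truth, 3, 0.1, seed = 2)
  h2 <- generate_hto(a$truth, 3, 0.1, seed = 2)
  expect_identical(h1$hto, h2$hto)

  fr <- matrix(c(0.6, 0.4), 1, 2,
               dimnames = list("s1", c("Primitive", "GMP")))
  expect_identical(generate_bulk(prof, fr, 0.1, seed = 4)$bulk,
                   generate_bulk(prof, fr, 0.1, seed = 4)$bulk)
})

test_that("empirical marker means match the generative parameters", {
  prof <- small_profiles()[c("Primitive", "GMP")]
  out <- generate_reference(prof, 1000, seed = 2, libsize_sd = 0)
  gene <- prof$Primitive$marker_genes[1]
  in_prim <- out$truth$cluster == "Primitive"
  x <- as.numeric(out$rna[gene, in_prim])
  design_mean <- prof$Primitive$rna_means[[gene]]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - design_mean), 3 * se)
  # marker boosted 8-fold relative to the other cluster
  expect_equal(design_mean / prof$GMP$rna_means[[gene]], 8)
})

test_that("zero dispersion gives the Poisson limit", {
  prof <- small_profiles()[1]
  out <- generate_reference(prof, 600, seed = 3, phi = 0, libsize_sd = 0)
  x <- as.matrix(out$rna)
  m <- rowMeans(x)
  ratio <- matrixStats::rowVars(x)[m > 2] / m[m > 2]
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("profiles with mismatched feature universes are rejected", {
  prof <- small_profiles()
  bad <- prof
  names(bad[[2]]$rna_means)[1] <- "ROGUE"
  expect_error(generate_reference(bad, 100, seed = 1),
               bad[[2]]$name)
})

test_that("patient generator splits primitive cells per the design", {
  prof <- small_profiles()
  sig <- bcrabl_signature(prof, n_up = 10, n_down = 5)

  des0 <- patient_design("P0", c(Primitive = 1), bcr_abl1_fraction = 0,
                         n_cells = 100, seed = 1)
  expect_false(any(generate_patient(des0, prof, sig)$truth$status == "pos"))

  des <- patient_design("P1", c(Primitive = 1), bcr_abl1_fraction = 0.5,
                        n_cells = 400, seed = 11)
  pat <- generate_patient(des, prof, sig)
  n_pos <- sum(pat$truth$status == "pos")
  ci <- qbinom(c(0.005, 0.995), 400, 0.5)
  expect_gte(n_pos, ci[1])
  expect_lte(n_pos, ci[2])

  expect_error(patient_design("P", c(Primitive = 1), 1.5), "bcr_abl1_fraction")
})

test_that("signature effect doubles up-gene means in leukemic cells", {
  prof <- small_profiles()
  sig <- bcrabl_signature(prof, n_up = 10, n_down = 5)
  des <- patient_design("P1", c(Primitive = 1), 0.5, signature_effect = 1,
                        n_cells = 800, seed = 21, pan_effect = 0, pan_sd = 0)
  pat <- generate_patient(des, prof, sig, libsize_sd = 0)
  pos <- pat$truth$status == "pos"
  ratio <- Matrix::rowMeans(pat$rna[sig$up_genes, pos]) /
    Matrix::rowMeans(pat$rna[sig$up_genes, !pos])
  expect_equal(mean(ratio), 2, tolerance = 0.05)
})

test_that("hashtag generator controls doublet rate and signal", {
  prof <- small_profiles()
  truth <- generate_reference(prof, 1000, seed = 6)$truth

  h0 <- generate_hto(truth, 3, doublet_rate = 0, seed = 1)
  expect_false(any(h0$truth$doublet))

  h <- generate_hto(truth, 3, doublet_rate = 0.1, seed = 1)
  n_dbl <- sum(h$truth$doublet)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_dbl, ci[1])
  expect_lte(n_dbl, ci[2])

  # for singlets the assigned hashtag carries the max count in >= 99%
  singlets <- which(!h$truth$doublet)
  top <- rownames(h$hto)[apply(as.matrix(h$hto[, singlets]), 2, which.max)]
  expect_gte(mean(top == h$truth$hashtag[singlets]), 0.99)

  expect_error(generate_hto(truth, 0, 0.1, 1), "n_hashtags")
  expect_error(generate_hto(truth, 3, 1.2, 1), "doublet_rate")
})

test_that("bulk mixtures honor identity and symmetry at zero noise", {
  prof <- small_profiles()
  f1 <- matrix(c(1, 0), 1, 2, dimnames = list("s", c("Primitive", "MEP")))
  b1 <- generate_bulk(prof, f1, noise_sd = 0, seed = 1)
  expect_equal(as.numeric(b1$bulk[, 1]),
               unname(prof$Primitive$rna_means))

  f2 <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s", c("Primitive", "MEP")))
  b2 <- generate_bulk(prof, f2, noise_sd = 0, seed = 1)
  expect_equal(as.numeric(b2$bulk[, 1]),
               unname((prof$Primitive$rna_means + prof$MEP$rna_means) / 2))

  f_bad <- matrix(c(1.5, -0.5), 1, 2,
                  dimnames = list("s", c("Primitive", "MEP")))
  expect_error(generate_bulk(prof, f_bad, 0, 1), "non-negative")
})

test_that("cluster compositions converge to the design and truth is complete", {
  prof <- small_profiles()
  sig <- bcrabl_signature(prof, n_up = 10, n_down = 5)
  comp <- c(Primitive = 0.3, GMP = 0.5, MEP = 0.2)
  des <- patient_design("P1", comp, 0.2, n_cells = 1500, seed = 13)
  pat <- generate_patient(des, prof, sig)
  emp <- table(pat$truth$cluster)[names(comp)] / 1500
  dev <- abs(emp - comp)
  expect_true(all(dev < 3 * sqrt(comp * (1 - comp) / 1500)))
  expect_identical(pat$truth$cell_id, colnames(pat$rna))
  expect_false(anyDuplicated(pat$truth$cell_id) > 0)
  expect_true(all(pat$rna@x >= 0), all(pat$rna@x == round(pat$rna@x)))
})
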