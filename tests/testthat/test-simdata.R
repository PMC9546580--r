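test_that("genetic map places markers on an arithmetic grid", {
  m1 <- simulate_genetic_map(c("1" = 100), 10)
  expect_equal(nrow(m1), 11)
  expect_equal(m1$pos, seq(0, 100, 10))
  m2 <- simulate_genetic_map(stats::setNames(rep(120, 10), 1:10), 5)
  expect_equal(nrow(m2), 10 * (120 / 5 + 1))
  expect_false(anyDuplicated(m2$marker) > 0)
  expect_error(simulate_genetic_map(c("1" = 100), 0), "positive")
  expect_error(simulate_genetic_map(c("1" = 5), 10), "at least twice")
})

test_that("RIL genotypes follow the Haldane switch model", {
  ## zero distance between adjacent markers -> identical states, always
  map0 <- data.frame(marker = c("m1", "m2"), chr = "1", pos = c(10, 10))
  class(map0) <- c("gmap", "data.frame")
  g0 <- simulate_ril_genotypes(map0, 500, seed = 1)
  expect_identical(g0$geno[, 1], g0$geno[, 2])

  map <- simulate_genetic_map(c("1" = 40), 20)
  cr <- simulate_ril_genotypes(map, 10000, seed = 2)
  ## symmetric initialization: per-marker AA frequency 1/2
  freq <- colMeans(cr$geno == 1L)
  expect_true(all(abs(freq - 0.5) < 0.02))
  ## observed switch fraction at d = 20 cM matches the closed form
  sw <- mean(cr$geno[, 1] != cr$geno[, 2])
  expect_lt(abs(sw - haldane_r(20)), 0.01)

  expect_error(simulate_ril_genotypes(map, 0), ">= 1")
  badmap <- map; badmap$pos <- rev(badmap$pos)
  expect_error(simulate_ril_genotypes(badmap, 5), "non-decreasing")
})

test_that("simulated runs are reproducible from the seed", {
  map <- simulate_genetic_map(c("1" = 60), 10)
  a <- simulate_ril_genotypes(map, 50, seed = 7, error_rate = 0.01,
                              missing_rate = 0.05)
  b <- simulate_ril_genotypes(map, 50, seed = 7, error_rate = 0.01,
                              missing_rate = 0.05)
  expect_identical(a$geno, b$geno)
  scen <- sim_scenario(seed = 8)
  expect_identical(simulate_phenotypes(a, scen)$angles,
                   simulate_phenotypes(b, scen)$angles)
})

test_that("phenotype generator plants additive parameter effects", {
  map <- simulate_genetic_map(c("1" = 60), 10)
  cross <- simulate_ril_genotypes(map, 200, seed = 3)
  zero_sd <- c(lambda = 0, mu = 0, A = 0, overshoot = 0)

  ## degenerate noise: every series identical
  s0 <- sim_scenario(line_sd = zero_sd, obs_sd = 0, seed = 4)
  ph0 <- simulate_phenotypes(cross, s0)
  expect_true(all(abs(sweep(ph0$angles, 2, ph0$angles[1, ])) < 1e-12))

  ## +10 on A: between-genotype difference of the planted parameter
  s1 <- sim_scenario(qtl_effects = data.frame(chr = "1", pos = 30,
                                              param = "A", effect = 10),
                     line_sd = zero_sd, obs_sd = 0, seed = 4)
  ph1 <- simulate_phenotypes(cross, s1)
  g <- cross$true_geno[, ph1$truth$qtl$marker]
  dA <- mean(ph1$truth$params$A[g == 2L]) - mean(ph1$truth$params$A[g == 1L])
  expect_equal(dA, 10)
  ## and the late-time angles differ by almost exactly that much
  dy <- mean(ph1$angles[g == 2L, 61]) - mean(ph1$angles[g == 1L, 61])
  expect_lt(abs(dy - 10), 0.5)

  ## observation noise has the configured per-time-point SD
  s2 <- sim_scenario(line_sd = zero_sd, obs_sd = 3, seed = 5)
  big <- simulate_ril_genotypes(map, 500, seed = 6)
  ph2 <- simulate_phenotypes(big, s2)
  tr <- ph2$truth$params
  curve <- logistic_curve(ph2$times[30], tr$A[1], tr$mu[1], tr$lambda[1])
  expect_lt(abs(stats::sd(ph2$angles[, 30] - curve) - 3), 0.3)

  expect_error(sim_scenario(qtl_effects = data.frame(
    chr = "1", pos = 30, param = "banana", effect = 1)), "must target")
  s3 <- sim_scenario(qtl_effects = data.frame(chr = "1", pos = 300,
                                              param = "A", effect = 1))
  expect_error(simulate_phenotypes(cross, s3), "off chromosome")
})

test_that("proteome generator plants verifiable one-to-one orthology", {
  ## divergence 0: planted pairs align at 100% identity
  sp0 <- simulate_proteomes(n_genes = 8, n_intervals = 1, divergence = 0,
                            paralog_spec = list(n = 0), seed = 10)
  al <- align_proteins(sp0$proteomes$a[["ga0001"]],
                       sp0$proteomes$b[["gb0001"]])
  expect_equal(al$pid, 100)

  ## planted truth equals brute-force all-vs-all reciprocal best
  sp <- simulate_proteomes(n_genes = 14, n_intervals = 2, divergence = 0.1,
                           paralog_spec = list(n = 4, divergence = 0.4),
                           seed = 11, len_range = c(60, 100))
  S <- outer(names(sp$proteomes$a), names(sp$proteomes$b),
             Vectorize(function(i, j)
               align_proteins(sp$proteomes$a[[i]],
                              sp$proteomes$b[[j]])$score))
  dimnames(S) <- list(names(sp$proteomes$a), names(sp$proteomes$b))
  ## every planted pair is a mutual best hit in the brute-force matrix,
  ## so the decoy paralogs never displace a planted partner
  tr <- sp$truth
  for (k in seq_len(nrow(tr))) {
    expect_equal(names(which.max(S[tr$gene_a[k], ])), tr$gene_b[k])
    expect_equal(names(which.max(S[, tr$gene_b[k]])), tr$gene_a[k])
  }

  ## designed failure: the decoy outscores the true partner one way
  spf <- simulate_proteomes(n_genes = 20, n_intervals = 2,
                            divergence = 0.15,
                            paralog_spec = list(n = 2, divergence = 0.4,
                                                n_fail = 1),
                            seed = 12, len_range = c(60, 100))
  fail <- spf$truth[spf$truth$designed_fail, ]
  expect_equal(nrow(fail), 1)
  expect_false(fail$expected_bbh)
  dec <- grep("^ga_dec", names(spf$proteomes$a), value = TRUE)
  s_dec <- align_proteins(spf$proteomes$a[[dec]],
                          spf$proteomes$b[[fail$gene_b]])$score
  s_true <- align_proteins(spf$proteomes$a[[fail$gene_a]],
                           spf$proteomes$b[[fail$gene_b]])$score
  expect_gt(s_dec, s_true)

  expect_error(simulate_proteomes(n_genes = 5, divergence = 0.3,
                                  paralog_spec = list(n = 2,
                                                      divergence = 0.2)),
               "exceed")
})

test_that("proteome truth round-trips through its JSON serialization", {
  sp <- simulate_proteomes(n_genes = 10, n_intervals = 1, divergence = 0.1,
                           paralog_spec = list(n = 0), seed = 13,
                           len_range = c(50, 80), out_dir = withr::local_tempdir())
  back <- jsonlite::fromJSON(sp$files$truth)
  expect_equal(back, sp$truth)
})

test_that("root image stacks carry drawn-tangent ground truth", {
  s <- simulate_root_image_series(c(45, 45), start_angle = 45)
  expect_equal(s$truth$angle, c(45, 45))
  expect_equal(length(s$frames), 2)
  expect_error(simulate_root_image_series(45, width_px = 1), "width_px")
  ## blank image: downstream segmentation reports no root
  expect_null(segment_root(matrix(0, 60, 60)))
})
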