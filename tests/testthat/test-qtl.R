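test_that("genotype probabilities match the exact HMM posterior", {
  ## 3-marker chromosome, middle position untyped
  map <- data.frame(marker = c("m1", "m2", "m3"), chr = "1",
                    pos = c(0, 10, 20))
  class(map) <- c("gmap", "data.frame")
  for (obs in list(c(1L, NA, 1L), c(1L, NA, 2L), c(2L, 1L, NA))) {
    cross <- structure(list(
      map = map, geno = matrix(obs, 1, 3,
                               dimnames = list("L1", map$marker))),
      class = "ril_cross")
    gp <- calc_genoprob(cross, step_cM = 10, error_prob = 0.01)
    got <- gp[["1"]]$prob[1, , ]
    want <- oracle_hmm_posterior(obs, c(10, 10), 0.01)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
  ## error-free emission puts unit mass on the observed call
  cross <- structure(list(
    map = map, geno = matrix(c(1L, 2L, 1L), 1, 3,
                             dimnames = list("L1", map$marker))),
    class = "ril_cross")
  gp0 <- calc_genoprob(cross, step_cM = 5, error_prob = 0)
  expect_equal(unname(gp0[["1"]]$prob[1, 1, "AA"]), 1)
  expect_equal(unname(gp0[["1"]]$prob[1, 3, "BB"]), 1)
  ## fully missing individual: uniform prior everywhere
  cross$geno[] <- NA_integer_
  gpm <- calc_genoprob(cross, step_cM = 5)
  expect_true(all(abs(gpm[["1"]]$prob - 0.5) < 1e-12))
  ## probability pairs always sum to one
  tc <- make_test_cross()
  sums <- lapply(tc$gp, function(cc) cc$prob[, , 1] + cc$prob[, , 2])
  expect_true(all(abs(unlist(sums) - 1) < 1e-12))
})

test_that("the Haley-Knott scan equals per-position regression", {
  ## hand-computed 4-individual fixture
  map <- simulate_genetic_map(c("1" = 100), 50)
  cross <- structure(list(
    map = map,
    geno = matrix(c(1L, 1L, 2L, 2L), 4, 3,
                  dimnames = list(paste0("i", 1:4), map$marker))),
    class = "ril_cross")
  gp <- calc_genoprob(cross, step_cM = 50, error_prob = 0)
  sc <- scanone_hk(gp, c(1, 1.1, 2, 2.1))
  expect_equal(max(sc$lod), 2 * log10(1.01 / 0.01), tolerance = 1e-8)

  ## constant phenotype scans flat at zero
  expect_true(all(scanone_hk(gp, rep(3, 4))$lod == 0))

  ## full profile equals the lm oracle, and is affine invariant
  tc <- make_test_cross(n = 50, seed = 31)
  set.seed(32)
  y <- rnorm(50) + tc$gp[["1"]]$prob[, 5, 2]
  y[c(3, 7)] <- NA
  sc2 <- scanone_hk(tc$gp, y)
  X <- dosage_matrix(tc$gp)$X
  expect_equal(sc2$lod, oracle_scan_lod(X, y), tolerance = 1e-8)
  sc3 <- scanone_hk(tc$gp, 100 - 7 * y)
  expect_equal(sc3$lod, sc2$lod, tolerance = 1e-8)
})

test_that("permutation thresholds are deterministic and calibrated at the edges", {
  tc <- make_test_cross(n = 40, seed = 33)
  set.seed(34)
  y <- rnorm(40)
  t1 <- permutation_threshold(tc$gp, y, n_perm = 150, seed = 9)
  t2 <- permutation_threshold(tc$gp, y, n_perm = 150, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  ## alpha = 1 returns the smallest null maximum
  tmin <- permutation_threshold(tc$gp, y, n_perm = 150, alpha = 1, seed = 9)
  expect_equal(as.numeric(tmin), min(attr(tmin, "maxima")))
  expect_error(permutation_threshold(tc$gp, y, n_perm = 50), ">= 100")
})

test_that("stepwise selection recovers planted QTL and rejects nulls", {
  map <- simulate_genetic_map(stats::setNames(rep(100, 3), 1:3), 10)
  cross <- simulate_ril_genotypes(map, 200, seed = 35)
  zero_sd <- c(lambda = 0, mu = 0, A = 0, overshoot = 0)
  scen <- sim_scenario(qtl_effects = data.frame(
    chr = c("1", "3"), pos = c(50, 20), param = c("A", "A"),
    effect = c(20, 15)), line_sd = zero_sd, obs_sd = 0, seed = 36)
  ph <- simulate_phenotypes(cross, scen)
  gp <- calc_genoprob(cross, step_cM = 2, error_prob = 0)
  mod <- stepwise_qtl(gp, ph$truth$params$A, penalty = 3)
  ## both QTL at the true marker positions, in map order
  expect_equal(mod$qtl$chr, c("1", "3"))
  expect_equal(mod$qtl$pos, c(50, 20))
  ## dosage-scale effects are half the between-homozygote difference
  expect_equal(mod$qtl$effect, c(10, 7.5), tolerance = 1e-6)
  ## support intervals contain their peaks
  expect_true(all(mod$intervals$lo <= mod$qtl$pos &
                    mod$intervals$hi >= mod$qtl$pos))

  ## honest penalty keeps null phenotypes empty almost always
  set.seed(37)
  empty <- vapply(1:8, function(i) {
    y <- rnorm(200)
    thr <- permutation_threshold(gp, y, n_perm = 150, seed = 37 + i)
    nrow(stepwise_qtl(gp, y, penalty = as.numeric(thr))$qtl) == 0
  }, logical(1))
  expect_gte(sum(empty), 7)
  expect_error(stepwise_qtl(gp, ph$truth$params$A, penalty = 0), "> 0")
})

test_that("support intervals implement the LOD-drop rule", {
  prof <- data.frame(chr = "1", pos = seq(0, 60, 10),
                     lod = c(0, 1, 3, 5, 3, 1, 0))
  iv <- support_interval(prof, 30, drop = 1.5)
  expect_equal(c(iv$lo, iv$hi), c(20, 40))
  expect_false(iv$flagged)
  ## monotone profile peaking at the chromosome end: one-sided
  mono <- data.frame(chr = "1", pos = seq(0, 60, 10),
                     lod = c(0, 1, 2, 3, 4, 5, 6))
  ivm <- support_interval(mono, 60, drop = 1.5)
  expect_equal(ivm$hi, 60)
  expect_lt(ivm$lo, 60)
  ## degenerate drop
  iv0 <- support_interval(prof, 30, drop = 0)
  expect_equal(c(iv0$lo, iv0$hi), c(30, 30))
  ## flat profile flags the whole chromosome
  flat <- data.frame(chr = "1", pos = seq(0, 60, 10), lod = rep(2, 7))
  ivf <- support_interval(flat, 30)
  expect_true(ivf$flagged)
  expect_equal(c(ivf$lo, ivf$hi), c(0, 60))
})

test_that("tQTL tracks follow the run/link/duration definitions", {
  qtl_at <- function(chr, pos) list(qtl = data.frame(
    chr = chr, pos = pos, lod = 5, stringsAsFactors = FALSE))
  none <- list(qtl = data.frame(chr = character(), pos = numeric(),
                                lod = numeric()))
  times <- seq(3, 30, by = 3)
  ## 5 consecutive significant frames -> one 15-min track
  models <- c(lapply(1:5, function(i) qtl_at("9", 40)),
              lapply(1:5, function(i) none))
  tr <- link_tqtl_over_time(models, times = times, frame_min = 3)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$duration, 15)
  expect_equal(tr$onset, 3)
  ## a one-frame hole splits the run
  models2 <- c(lapply(1:2, function(i) qtl_at("9", 40)), list(none),
               lapply(1:2, function(i) qtl_at("9", 40)),
               lapply(1:5, function(i) none))
  tr2 <- link_tqtl_over_time(models2, times = times, frame_min = 3)
  expect_equal(nrow(tr2), 2)
  expect_equal(sort(tr2$duration), c(6, 6))
  ## a 12-cM jump breaks the chain at link_dist 10
  models3 <- c(list(qtl_at("9", 40), qtl_at("9", 52)),
               lapply(1:8, function(i) none))
  tr3 <- link_tqtl_over_time(models3, times = times, frame_min = 3,
                             link_dist_cM = 10)
  expect_equal(nrow(tr3), 2)

  ## matching: co-located pQTL on the same chromosome within 10 cM
  pq <- list(A = list(qtl = data.frame(chr = "9", pos = 42, lod = 8)))
  mt <- match_tqtl_pqtl(tr, pq)
  expect_equal(nrow(mt$matched), 1)
  expect_equal(mt$summary$mean_duration[mt$summary$class == "matched"], 15)
  pq2 <- list(A = list(qtl = data.frame(chr = "3", pos = 42, lod = 8)))
  mt2 <- match_tqtl_pqtl(tr, pq2)
  expect_equal(nrow(mt2$matched), 0)
  expect_equal(nrow(mt2$unmatched), 1)
})
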