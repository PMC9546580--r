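test_that("cM to bp interpolation is linear between anchors", {
  an <- data.frame(chrom = "c1", cm = c(0, 100), bp = c(1, 1e8))
  r <- cm_to_bp(c(25, 75), an)
  expect_equal(r$bp_lo, 25e6, tolerance = 1e-3)
  expect_equal(r$bp_hi, 75e6, tolerance = 1e-3)
  expect_false(r$clamped)
  ## endpoint exactly at an anchor returns that anchor's bp
  expect_equal(cm_to_bp(c(0, 100), an)$bp_lo, 1)
  ## piecewise anchors: interpolate within the correct segment
  an2 <- data.frame(chrom = "c1", cm = c(0, 50, 100), bp = c(0, 1e7, 1e8))
  expect_equal(cm_to_bp(c(10, 75), an2)$bp_hi, 5.5e7)
  ## outside the span: clamped and flagged
  rc <- cm_to_bp(c(-5, 110), an)
  expect_true(rc$clamped)
  expect_equal(c(rc$bp_lo, rc$bp_hi), c(1, 1e8))
  bad <- data.frame(chrom = "c1", cm = c(0, 50, 100), bp = c(0, 2e7, 1e7))
  expect_error(cm_to_bp(c(1, 2), bad), "monotone")
})

test_that("interval gene extraction uses the 1-bp overlap rule", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1",
                    start = c(100, 210, 300), end = c(200, 240, 400))
  expect_equal(genes_in_interval(ann, "c1", 150, 250), c("g1", "g2"))
  expect_equal(genes_in_interval(ann, "c1", 201, 209), character(0))
  expect_equal(genes_in_interval(ann, "c1", 1, 1e6), c("g1", "g2", "g3"))
  expect_warning(g <- genes_in_interval(ann, "cX", 1, 10), "cX")
  expect_equal(g, character(0))
})

test_that("local alignment matches the affine-gap dynamic program", {
  ## identical sequences: 100% identity, score = sum of diagonal entries
  sm <- get_blosum62()
  s <- "MKTAYIAKQR"
  al <- align_proteins(s, s)
  expect_equal(al$pid, 100)
  expect_equal(al$score, sum(diag(sm[strsplit(s, "")[[1]],
                                     strsplit(s, "")[[1]]])))
  ## no positive substitution: best local score from bare residue pairs
  ac <- align_proteins("AAAA", "CCCC")
  expect_equal(ac$score, 0)
  expect_equal(ac$identities, 0)
  ## symmetry of the scoring
  set.seed(50)
  for (i in 1:3) {
    a <- rand_protein(25); b <- rand_protein(30)
    expect_equal(align_proteins(a, b)$score, align_proteins(b, a)$score)
  }
  ## equality with the exhaustive DP oracle on short random pairs
  set.seed(51)
  for (i in 1:12) {
    a <- rand_protein(sample(8:30, 1)); b <- rand_protein(sample(8:30, 1))
    expect_equal(align_proteins(a, b)$score, oracle_sw_score(a, b))
  }
  expect_error(align_proteins("", "AAA"), "empty")
})

test_that("best hits maximize score with deterministic tie-breaking", {
  set.seed(52)
  prots <- stats::setNames(vapply(c(60, 70, 80), rand_protein,
                                  character(1)), c("p1", "p2", "p3"))
  q <- prots[["p2"]]
  bh <- best_hit(q, prots)
  expect_equal(bh$subject, "p2")
  ## exhaustive maximum
  scores <- vapply(prots, function(p) align_proteins(q, p)$score,
                   numeric(1))
  expect_equal(bh$score, max(scores))
  ## exact ties resolved to the lexicographically smallest id
  dup <- c(zz = unname(prots["p1"]), aa = unname(prots["p1"]))
  expect_equal(best_hit(prots[["p1"]], dup)$subject, "aa")
  ## nothing above the minimum score
  expect_null(best_hit("AAAA", c(x = "CCCC"), min_score = 50))
})

test_that("reciprocal best hits recover planted orthology exactly", {
  ## identical toy proteomes: identity pairing at 100%
  set.seed(53)
  pa <- stats::setNames(vapply(rep(60, 4), rand_protein, character(1)),
                        paste0("a", 1:4))
  pb <- stats::setNames(pa, paste0("b", 1:4))
  iva <- stats::setNames(rep("QA", 4), names(pa))
  ivb <- stats::setNames(rep("QB", 4), names(pb))
  pairs <- find_bbh(iva, ivb, pa, pb)
  expect_equal(nrow(pairs), 4)
  expect_equal(pairs$gene_b, sub("^a", "b", pairs$gene_a))
  expect_true(all(pairs$pid_ab == 100))

  ## planted simulation: exact recovery, symmetric in species order
  sp <- simulate_proteomes(n_genes = 30, n_intervals = 2, divergence = 0.1,
                           paralog_spec = list(n = 6, divergence = 0.4,
                                               n_fail = 1),
                           seed = 54, len_range = c(60, 120))
  ga <- stats::setNames(rep("ivA", sum(sp$truth$in_a)),
                        sp$truth$gene_a[sp$truth$in_a])
  gb <- stats::setNames(rep("ivB", sum(sp$truth$in_b)),
                        sp$truth$gene_b[sp$truth$in_b])
  fwd <- find_bbh(ga, gb, sp$proteomes$a, sp$proteomes$b)
  expect_setequal(fwd$gene_a, sp$truth$gene_a[sp$truth$expected_bbh])
  ## the designed decoy breaks reciprocity for its pair
  expect_false(any(fwd$gene_a %in%
                     sp$truth$gene_a[sp$truth$designed_fail]))
  ## starting from species B yields the same set
  rev <- find_bbh(gb, ga, sp$proteomes$b, sp$proteomes$a)
  expect_setequal(paste(rev$gene_b, rev$gene_a),
                  paste(fwd$gene_a, fwd$gene_b))
  ## partial matching: no gene twice
  expect_false(anyDuplicated(fwd$gene_a) > 0)
  expect_false(anyDuplicated(fwd$gene_b) > 0)
})

test_that("candidate tables are sorted, named and guarded", {
  p0 <- find_bbh(character(0), character(0), c(a = "MKT"), c(b = "MKT"))
  t0 <- report_candidates(p0)
  expect_equal(nrow(t0), 0)
  expect_true(all(c("qtl_a", "gene_a", "identity_pct") %in% names(t0)))
  dup <- data.frame(gene_a = c("x", "x"), gene_b = c("y", "z"),
                    qtl_a = "q", qtl_b = "q", pid_ab = 50, pid_ba = 50,
                    score_ab = 100, score_ba = 100)
  expect_error(report_candidates(dup), "one-to-one")
})

test_that("the full interval-orthology filter reproduces planted pairs", {
  sp <- simulate_proteomes(n_genes = 24, n_intervals = 2, divergence = 0.1,
                           paralog_spec = list(n = 4, divergence = 0.4),
                           seed = 55, len_range = c(60, 110))
  orth <- qtl_orthologs(sp$annotations$a, sp$proteomes$a, sp$intervals$a,
                        sp$anchors$a, sp$annotations$b, sp$proteomes$b,
                        sp$intervals$b, sp$anchors$b)
  expect_setequal(orth$pairs$gene_a,
                  sp$truth$gene_a[sp$truth$expected_bbh])
  expect_equal(nrow(orth$table), nrow(orth$pairs))
})
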