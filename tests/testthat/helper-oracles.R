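## Independent brute-force oracles used across the test files.

## per-position regression LOD, one lm per position
oracle_scan_lod <- function(X, y) {
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::var(x) < 1e-12) return(0)
    rss1 <- sum(stats::resid(stats::lm(y ~ x))^2)
    (n / 2) * log10(rss0 / rss1)
  }, numeric(1))
}

## exhaustive 2-state HMM posterior by path enumeration (small K only)
oracle_hmm_posterior <- function(obs, dists, error_prob) {
  K <- length(obs)
  r <- graviqtl::haldane_r(dists)
  emit <- function(state, o) {
    if (is.na(o)) 1 else if (o == state) 1 - error_prob else error_prob
  }
  states <- as.matrix(expand.grid(rep(list(1:2), K)))
  w <- apply(states, 1, function(s) {
    p <- 0.5 * emit(s[1], obs[1])
    for (k in 2:K) {
      tr <- if (s[k] == s[k - 1]) 1 - r[k - 1] else r[k - 1]
      p <- p * tr * emit(s[k], obs[k])
    }
    p
  })
  post <- vapply(seq_len(K), function(k)
    sum(w[states[, k] == 1]) / sum(w), numeric(1))
  cbind(AA = post, BB = 1 - post)
}

## Smith-Waterman local alignment score, affine gaps costing
## open + len * extend (blastp-style), BLOSUM62 by default
oracle_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  sm <- get_blosum62()
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sm[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

## quick simulated cross + genoprob shared by qtl tests
make_test_cross <- function(n = 60, chrs = c("1" = 80, "2" = 80),
                            spacing = 10, seed = 42, step = 5) {
  map <- simulate_genetic_map(chrs, spacing)
  cross <- simulate_ril_genotypes(map, n, seed = seed)
  list(map = map, cross = cross,
       gp = calc_genoprob(cross, step_cM = step))
}

rand_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}
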