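## Synthetic proteome pairs with planted one-to-one orthologs, paralog
## decoys and QTL-interval annotations, for exercising the reciprocal
## best-hit orthology filter with known truth.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

## substitute each site independently with probability p (to a different
## residue, so p is the realized per-site divergence in expectation)
mutate_protein <- function(seq, p) {
  if (p <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(s)) < p
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(a)
      sample(setdiff(AA_ALPHABET, a), 1L), character(1))
  }
  paste(s, collapse = "")
}

place_genes <- function(ids, aa_len, order, n_chrom, gap = 5000L) {
  n <- length(ids)
  sizes <- diff(round(seq(0, n, length.out = n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), sizes)
  ann <- data.frame(gene_id = ids[order], chrom = chrom,
                    start = NA_real_, end = NA_real_, strand = "+",
                    aa_len = aa_len[order], stringsAsFactors = FALSE)
  for (ch in unique(ann$chrom)) {
    i <- which(ann$chrom == ch)
    glen <- ann$aa_len[i] * 3 + 3
    ends <- cumsum(glen + gap)
    ann$start[i] <- ends - glen + 1
    ann$end[i] <- ends
  }
  ann$protein_id <- paste0(ann$gene_id, ".p1")
  ann
}

#' Simulate a pair of proteomes with planted orthology and QTL intervals
#'
#' Each species receives `n_genes` genes placed on synthetic chromosomes.
#' Species B genes are per-site mutated copies of their species A
#' orthologs (per-site substitution probability `divergence`), so every
#' gene has exactly one planted one-to-one ortholog.  Within-species
#' paralog decoys are added at the higher `paralog_spec$divergence`.  A
#' block of genes is kept adjacent in both species and covered by the
#' first QTL interval of each, guaranteeing in-interval ortholog pairs;
#' further intervals are random gene windows.  Optionally,
#' `paralog_spec$n_fail` in-interval pairs get a species-A decoy derived
#' from the species-B ortholog at half the ortholog divergence, a
#' designed reciprocity failure.
#'
#' @param n_genes Orthologous genes per species.
#' @param n_intervals QTL intervals per species.
#' @param divergence Ortholog per-site substitution probability, `[0, 1)`.
#' @param paralog_spec List: `n` decoys per species, `divergence`
#'   (must exceed the ortholog divergence), `n_fail` designed failures.
#' @param seed Optional integer seed.
#' @param len_range Protein length range (aa).
#' @param n_chrom Chromosomes per species.
#' @param shared_frac Fraction of genes in the guaranteed shared block.
#' @param out_dir If non-NULL, write FASTA/GFF3/TSV/JSON files there.
#' @return List of class `sim_proteomes`: `proteomes` (named character
#'   vectors per species), `annotations`, `intervals` (label, chrom,
#'   cm_lo, cm_hi), `anchors` (chrom, cm, bp; 1 cM per Mb), `truth`
#'   (`data.frame` of planted pairs with `expected_bbh`), and `files`.
#' @export
simulate_proteomes <- function(n_genes = 60, n_intervals = 3,
                               divergence = 0.1,
                               paralog_spec = list(n = 10, divergence = 0.35,
                                                   n_fail = 0),
                               seed = NULL, len_range = c(80, 200),
                               n_chrom = 2, shared_frac = 0.1,
                               out_dir = NULL) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  np <- paralog_spec$n %||% 0
  pd <- paralog_spec$divergence %||% 0.35
  n_fail <- paralog_spec$n_fail %||% 0
  if (np > 0 && pd <= divergence)
    stop("paralog divergence must exceed ortholog divergence")
  if (!is.null(seed)) set.seed(seed)

  aa_len <- sample(seq(len_range[1], len_range[2]), n_genes, replace = TRUE)
  seq_a <- vapply(aa_len, random_protein, character(1))
  seq_b <- vapply(seq_a, mutate_protein, character(1), p = divergence)
  ids_a <- sprintf("ga%04d", seq_len(n_genes))
  ids_b <- sprintf("gb%04d", seq_len(n_genes))
  names(seq_a) <- ids_a
  names(seq_b) <- ids_b

  m <- max(2L, round(shared_frac * n_genes))
  shared <- sort(sample(n_genes, m))

  ## adjacency-preserving permutation: shared block contiguous per species
  make_order <- function() {
    rest <- sample(setdiff(seq_len(n_genes), shared))
    cut <- sample(0:length(rest), 1L)
    c(rest[seq_len(cut)], sample(shared), rest[setdiff(seq_along(rest),
                                                       seq_len(cut))])
  }
  ord_a <- make_order()
  ord_b <- make_order()
  ann_a <- place_genes(ids_a, aa_len, ord_a, n_chrom)
  ann_b <- place_genes(ids_b, aa_len, ord_b, n_chrom)

  block_interval <- function(ann, ids_shared, pad = 1000) {
    rows <- ann[ann$gene_id %in% ids_shared, ]
    ch <- unique(rows$chrom)
    if (length(ch) > 1L) { # block split over a chromosome break: use larger part
      ch <- names(which.max(table(rows$chrom)))
      rows <- rows[rows$chrom == ch, ]
    }
    c(chrom = ch, lo = max(1, min(rows$start) - pad), hi = max(rows$end) + pad)
  }
  random_interval <- function(ann, w) {
    ch <- sample(unique(ann$chrom), 1L)
    rows <- ann[ann$chrom == ch, ]
    w <- min(w, nrow(rows))
    i0 <- sample(nrow(rows) - w + 1L, 1L)
    c(chrom = ch, lo = rows$start[i0], hi = rows$end[i0 + w - 1L])
  }
  build_intervals <- function(ann) {
    iv <- list(block_interval(ann, ann$gene_id[ann$gene_id %in%
                 c(ids_a[shared], ids_b[shared])]))
    w <- max(3L, round(0.08 * n_genes))
    while (length(iv) < n_intervals) iv <- c(iv, list(random_interval(ann, w)))
    data.frame(chrom = vapply(iv, `[[`, "", "chrom"),
               bp_lo = as.numeric(vapply(iv, `[[`, "", "lo")),
               bp_hi = as.numeric(vapply(iv, `[[`, "", "hi")),
               stringsAsFactors = FALSE)
  }
  iv_a <- build_intervals(ann_a)
  iv_b <- build_intervals(ann_b)

  ## paralog decoys: within-species near-duplicates
  add_paralogs <- function(seqs, ann, prefix) {
    if (np == 0) return(list(seqs = seqs, ann = ann))
    src <- sample(names(seqs), np)
    par_seq <- vapply(seqs[src], mutate_protein, character(1), p = pd)
    par_ids <- sprintf("%s_par%03d", prefix, seq_len(np))
    names(par_seq) <- par_ids
    ann2 <- append_genes(ann, par_ids, nchar(par_seq))
    list(seqs = c(seqs, par_seq), ann = rbind(ann, ann2))
  }
  pa <- add_paralogs(seq_a, ann_a, "ga")
  pb <- add_paralogs(seq_b, ann_b, "gb")
  seq_a <- pa$seqs; ann_a <- pa$ann
  seq_b <- pb$seqs; ann_b <- pb$ann

  ## designed reciprocity failures: A-side decoys nearer the B ortholog
  fail_genes <- integer(0)
  if (n_fail > 0) {
    in_iv <- function(ann, iv, id) {
      r <- ann[ann$gene_id == id, ]
      any(iv$chrom == r$chrom & r$start <= iv$bp_hi & r$end >= iv$bp_lo)
    }
    cand <- shared[vapply(shared, function(i)
      in_iv(ann_a, iv_a, ids_a[i]) && in_iv(ann_b, iv_b, ids_b[i]),
      logical(1))]
    fail_genes <- utils::head(cand, n_fail)
    if (length(fail_genes) > 0) {
      dec <- vapply(seq_b[ids_b[fail_genes]], mutate_protein, character(1),
                    p = divergence / 2)
      dec_ids <- sprintf("ga_dec%03d", seq_along(fail_genes))
      names(dec) <- dec_ids
      ann_a <- rbind(ann_a, append_genes(ann_a, dec_ids, nchar(dec)))
      seq_a <- c(seq_a, dec)
    }
  }

  anchors <- function(ann) {
    do.call(rbind, lapply(unique(ann$chrom), function(ch) {
      hi <- max(ann$end[ann$chrom == ch]) + 5000
      bp <- c(0, round(hi / 2), hi)
      data.frame(chrom = ch, cm = bp / 1e6, bp = bp)
    }))
  }
  an_a <- anchors(ann_a)
  an_b <- anchors(ann_b)
  label_iv <- function(iv) {
    iv$label <- stats::ave(iv$chrom, iv$chrom, FUN = function(x)
      sprintf("%s-%d", x, seq_along(x)))
    data.frame(label = iv$label, chrom = iv$chrom,
               cm_lo = iv$bp_lo / 1e6, cm_hi = iv$bp_hi / 1e6,
               stringsAsFactors = FALSE)
  }
  iv_a_cm <- label_iv(iv_a)
  iv_b_cm <- label_iv(iv_b)

  gene_in_any <- function(ann, iv, id) {
    r <- ann[ann$gene_id == id, ]
    any(iv$chrom == r$chrom & r$start <= iv$bp_hi & r$end >= iv$bp_lo)
  }
  truth <- data.frame(
    gene_a = ids_a, gene_b = ids_b,
    in_a = vapply(ids_a, gene_in_any, logical(1), ann = ann_a, iv = iv_a),
    in_b = vapply(ids_b, gene_in_any, logical(1), ann = ann_b, iv = iv_b),
    designed_fail = seq_len(n_genes) %in% fail_genes,
    stringsAsFactors = FALSE, row.names = NULL)
  truth$expected_bbh <- truth$in_a & truth$in_b & !truth$designed_fail

  out <- structure(list(
    proteomes = list(a = seq_a, b = seq_b),
    annotations = list(a = ann_a, b = ann_b),
    intervals = list(a = iv_a_cm, b = iv_b_cm),
    anchors = list(a = an_a, b = an_b),
    truth = truth, files = NULL), class = "sim_proteomes")
  if (!is.null(out_dir)) out$files <- write_proteome_set(out, out_dir)
  out
}

## append extra genes at the end of a random chromosome
append_genes <- function(ann, ids, aa_len, gap = 5000L) {
  ch <- sample(unique(ann$chrom), length(ids), replace = TRUE)
  res <- data.frame(gene_id = ids, chrom = ch, start = NA_real_,
                    end = NA_real_, strand = "+", aa_len = aa_len,
                    protein_id = paste0(ids, ".p1"),
                    stringsAsFactors = FALSE)
  for (c0 in unique(ch)) {
    i <- which(ch == c0)
    pos <- max(ann$end[ann$chrom == c0]) + gap
    for (k in i) {
      glen <- aa_len[k] * 3 + 3
      res$start[k] <- pos + 1
      res$end[k] <- pos + glen
      pos <- pos + glen + gap
    }
  }
  res
}
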