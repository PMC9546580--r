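## Candidate-gene filtering by orthology: map QTL intervals from cM to
## bp via marker anchors, pull genes overlapping the intervals from an
## annotation, and identify one-to-one orthologs across two species by
## reciprocal best-hit local protein alignment (BLOSUM62, affine gaps
## 11/1, blastp-default costs), reporting percent identity over
## alignment columns (gap columns included).

#' Interpolate a genetic interval to physical coordinates
#'
#' Linear interpolation between flanking marker anchors; endpoints
#' outside the anchored span are clamped to the terminal anchors and
#' flagged.
#'
#' @param interval `c(cm_lo, cm_hi)` in cM.
#' @param anchors `data.frame` with `chrom`, `cm`, `bp` for one
#'   chromosome (>= 2 rows; `bp` strictly monotone in `cm`).
#' @return List: `bp_lo`, `bp_hi`, `clamped`.
#' @export
cm_to_bp <- function(interval, anchors) {
  stopifnot(length(interval) == 2, all(c("cm", "bp") %in% names(anchors)))
  a <- anchors[order(anchors$cm), ]
  if (nrow(a) < 2) stop("need at least 2 anchors on the chromosome")
  if (any(diff(a$bp) <= 0) || any(diff(a$cm) <= 0))
    stop("anchors must be strictly monotone (bp increasing with cM)")
  clamped <- interval[1] < min(a$cm) || interval[2] > max(a$cm)
  bp <- stats::approx(a$cm, a$bp, xout = pmin(pmax(interval, min(a$cm)),
                                              max(a$cm)))$y
  list(bp_lo = bp[1], bp_hi = bp[2], clamped = clamped)
}

#' Genes overlapping a physical interval
#'
#' Strand-agnostic 1-bp overlap rule on 1-based inclusive coordinates.
#'
#' @param annotation `data.frame` with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param chrom Chromosome name.
#' @param bp_lo,bp_hi Interval bounds (bp, inclusive).
#' @return Character vector of gene ids (empty, with a warning, for an
#'   unknown chromosome).
#' @export
genes_in_interval <- function(annotation, chrom, bp_lo, bp_hi) {
  if (!chrom %in% annotation$chrom) {
    warning("chromosome ", chrom, " not in annotation")
    return(character(0))
  }
  keep <- annotation$chrom == chrom & annotation$start <= bp_hi &
    annotation$end >= bp_lo
  annotation$gene_id[keep]
}

#' Local protein alignment with blastp-default costs
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (open 11, extend 1 per residue).  Percent identity counts identities
#' over all alignment columns, including gap columns.
#'
#' @param a,b Protein sequences (character or `AAString`), non-empty,
#'   over the 20-letter alphabet plus X.
#' @param matrix Substitution matrix name.
#' @param gap_open,gap_extend Affine gap costs.
#' @return List of class `alignment_result`: `score`, `identities`,
#'   `columns`, `pid`.
#' @export
align_proteins <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  idn <- Biostrings::nmatch(pa)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  structure(list(score = Biostrings::score(pa), identities = idn,
                 columns = cols,
                 pid = if (cols > 0) 100 * idn / cols else 0),
            class = "alignment_result")
}

#' Best hit of a query protein in a target proteome
#'
#' Ranks targets by raw Smith-Waterman score; ties are broken by higher
#' percent identity, then by lexicographically smallest subject id.
#' Hits below `min_score` are discarded.
#'
#' @param query Protein sequence (character).
#' @param proteome Named character vector (or `AAStringSet`) of target
#'   proteins.
#' @param min_score Minimum raw score for a reportable hit.
#' @inheritParams align_proteins
#' @return List: `subject`, `score`, `pid`; or `NULL` when nothing
#'   reaches `min_score`.
#' @export
best_hit <- function(query, proteome, min_score = 50, matrix = "BLOSUM62",
                     gap_open = 11, gap_extend = 1) {
  if (length(proteome) == 0) stop("target proteome is empty")
  subj <- if (inherits(proteome, "AAStringSet")) proteome else
    Biostrings::AAStringSet(proteome)
  scores <- Biostrings::pairwiseAlignment(
    subj, Biostrings::AAString(as.character(query)), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  top <- max(scores)
  if (top < min_score) return(NULL)
  tied <- which(scores >= top - 1e-9)
  if (length(tied) > 1) {
    pids <- vapply(tied, function(i)
      align_proteins(as.character(subj[[i]]), as.character(query),
                     matrix, gap_open, gap_extend)$pid, numeric(1))
    tied <- tied[pids >= max(pids) - 1e-9]
    tied <- tied[order(names(subj)[tied])][1]
  }
  i <- tied[1]
  al <- align_proteins(as.character(query), as.character(subj[[i]]),
                       matrix, gap_open, gap_extend)
  list(subject = names(subj)[i], score = al$score, pid = al$pid)
}

#' Reciprocal best hits between interval gene sets
#'
#' For every species-A interval gene, the best hit in the full species-B
#' proteome is found; the pair is kept when that hit lies in a
#' species-B interval and its own best hit in the full species-A
#' proteome is the original gene.  The construction is symmetric: the
#' same set results from starting on either side, and no gene appears
#' in two pairs.
#'
#' @param genes_a,genes_b Named character vectors mapping in-interval
#'   gene ids to their interval labels, per species.
#' @param proteome_a,proteome_b Full proteomes: named character vectors
#'   of protein sequences, names = gene ids.
#' @param min_score Passed to [best_hit()].
#' @return `data.frame` of class `bbh_pairs`: `gene_a`, `gene_b`,
#'   `qtl_a`, `qtl_b`, `score_ab`, `score_ba`, `pid_ab`, `pid_ba`.
#' @export
find_bbh <- function(genes_a, genes_b, proteome_a, proteome_b,
                     min_score = 50) {
  pa <- Biostrings::AAStringSet(proteome_a)
  pb <- Biostrings::AAStringSet(proteome_b)
  miss <- setdiff(names(genes_a), names(pa))
  if (length(miss) > 0) {
    warning("gene(s) without protein skipped: ", paste(miss, collapse = ", "))
    genes_a <- genes_a[setdiff(names(genes_a), miss)]
  }
  rows <- list()
  for (g in names(genes_a)) {
    h <- best_hit(proteome_a[[g]], pb, min_score = min_score)
    if (is.null(h) || !h$subject %in% names(genes_b)) next
    back <- best_hit(proteome_b[[h$subject]], pa, min_score = min_score)
    if (is.null(back) || back$subject != g) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = g, gene_b = h$subject,
      qtl_a = unname(genes_a[g]), qtl_b = unname(genes_b[h$subject]),
      score_ab = h$score, score_ba = back$score,
      pid_ab = h$pid, pid_ba = back$pid, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) data.frame(
    gene_a = character(), gene_b = character(), qtl_a = character(),
    qtl_b = character(), score_ab = numeric(), score_ba = numeric(),
    pid_ab = numeric(), pid_ba = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  class(out) <- c("bbh_pairs", "data.frame")
  out
}

#' Candidate table from BBH pairs
#'
#' One row per reciprocal-best-hit pair: QTL labels, gene ids, percent
#' identity (A-to-B alignment) and an optional gene name, sorted by the
#' species-A QTL label.  Refuses pair sets where a gene appears twice
#' (the one-to-one matching invariant).
#'
#' @param pairs A `bbh_pairs` data frame.
#' @param gene_names Optional named character vector, gene id -> name.
#' @return `data.frame`: `qtl_a`, `gene_a`, `qtl_b`, `gene_b`,
#'   `identity_pct`, `name`.
#' @export
report_candidates <- function(pairs, gene_names = NULL) {
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stop("a gene appears in more than one pair; not a one-to-one matching")
  out <- data.frame(qtl_a = pairs$qtl_a, gene_a = pairs$gene_a,
                    qtl_b = pairs$qtl_b, gene_b = pairs$gene_b,
                    identity_pct = pairs$pid_ab,
                    name = if (is.null(gene_names))
                      rep(NA_character_, nrow(pairs)) else
                      unname(gene_names[pairs$gene_a]),
                    stringsAsFactors = FALSE)
  out[order(out$qtl_a, out$gene_a), , drop = FALSE]
}

#' Run the full interval-orthology filter for two species
#'
#' Converts each species' QTL intervals from cM to bp with its marker
#' anchors, collects the genes overlapping them, and intersects the two
#' candidate sets by reciprocal best hit against the full proteomes.
#'
#' @param annotation_a,annotation_b Gene annotations (`data.frame` with
#'   `gene_id`, `chrom`, `start`, `end`).
#' @param proteome_a,proteome_b Named character vectors, gene id ->
#'   protein sequence.
#' @param intervals_a,intervals_b `data.frame`s with `label`, `chrom`,
#'   `cm_lo`, `cm_hi`.
#' @param anchors_a,anchors_b `data.frame`s with `chrom`, `cm`, `bp`.
#' @param min_score Passed to [best_hit()].
#' @return List of class `orthology_result`: `candidates_a`,
#'   `candidates_b` (gene id -> interval label), `pairs` (`bbh_pairs`),
#'   `table` (the candidate report).
#' @export
qtl_orthologs <- function(annotation_a, proteome_a, intervals_a, anchors_a,
                          annotation_b, proteome_b, intervals_b, anchors_b,
                          min_score = 50) {
  interval_genes <- function(ann, iv, anch) {
    out <- character(0)
    for (i in seq_len(nrow(iv))) {
      a <- anch[anch$chrom == iv$chrom[i], , drop = FALSE]
      bp <- cm_to_bp(c(iv$cm_lo[i], iv$cm_hi[i]), a)
      gs <- genes_in_interval(ann, iv$chrom[i], bp$bp_lo, bp$bp_hi)
      add <- setdiff(gs, names(out))
      lab <- stats::setNames(rep(iv$label[i], length(add)), add)
      out <- c(out, lab)
    }
    out
  }
  ga <- interval_genes(annotation_a, intervals_a, anchors_a)
  gb <- interval_genes(annotation_b, intervals_b, anchors_b)
  pairs <- find_bbh(ga, gb, proteome_a, proteome_b, min_score = min_score)
  structure(list(candidates_a = ga, candidates_b = gb, pairs = pairs,
                 table = report_candidates(pairs)),
            class = "orthology_result")
}
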