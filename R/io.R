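## Readers and writers for the pipeline's file formats.
##
## Genotype CSV dialect: row 1 = individual-id header plus marker names,
## row 2 = chromosome per marker (first field empty), row 3 = cM
## position (first field empty), then one row per individual with codes
## A / B / - ; unknown codes are treated as missing and counted.

#' Write a cross (map + genotypes) to CSV
#'
#' @param cross A `ril_cross`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cross <- function(cross, path) {
  map <- cross$map
  g <- cross$geno
  codes <- matrix("-", nrow(g), ncol(g))
  codes[!is.na(g) & g == 1L] <- "A"
  codes[!is.na(g) & g == 2L] <- "B"
  lines <- c(
    paste(c("id", map$marker), collapse = ","),
    paste(c("", map$chr), collapse = ","),
    paste(c("", format(map$pos, trim = TRUE, scientific = FALSE)),
          collapse = ","),
    vapply(seq_len(nrow(g)), function(i)
      paste(c(rownames(g)[i], codes[i, ]), collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cross (map + genotypes) from CSV
#'
#' Validates marker-name uniqueness and within-chromosome position
#' monotonicity (rejecting shuffled columns), and counts unknown
#' genotype codes as missing.
#'
#' @param path Genotype CSV in the three-header-row dialect.
#' @return A `ril_cross`.
#' @export
read_cross <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("genotype file needs 3 header rows + data")
  split1 <- strsplit(lines, ",", fixed = TRUE)
  markers <- split1[[1]][-1]
  chrs <- split1[[2]][-1]
  pos <- as.numeric(split1[[3]][-1])
  if (anyDuplicated(markers))
    stop("duplicated marker names in header (line 1)")
  map <- data.frame(marker = markers, chr = chrs, pos = pos,
                    stringsAsFactors = FALSE)
  bad <- unlist(tapply(seq_along(pos), factor(chrs, levels = unique(chrs)),
                       function(i) any(diff(pos[i]) < 0)))
  if (any(bad))
    stop("non-monotone cM positions (line 3) for chromosome(s): ",
         paste(unique(chrs)[bad], collapse = ", "))
  class(map) <- c("gmap", "data.frame")
  body <- split1[-(1:3)]
  ids <- vapply(body, `[[`, "", 1L)
  codes <- t(vapply(body, function(x) x[-1], character(length(markers))))
  g <- matrix(NA_integer_, nrow(codes), ncol(codes),
              dimnames = list(ids, markers))
  g[codes == "A"] <- 1L
  g[codes == "B"] <- 2L
  unknown <- sum(!(codes %in% c("A", "B", "-")))
  if (unknown > 0)
    warning(unknown, " unknown genotype code(s) treated as missing")
  structure(list(map = map, geno = g), class = "ril_cross")
}

#' Write / read a wide per-line angle matrix
#'
#' Columns: `id`, `line`, then `t_<minutes>`, one row per seedling or
#' line.
#'
#' @param angles Matrix (rows = seedlings/lines) with rownames as ids.
#' @param times Time grid, minutes.
#' @param path CSV file.
#' @param lines Optional line id per row (defaults to rownames).
#' @return `path` invisibly; `read_angles()` returns a list with
#'   `angles`, `times`, `lines`.
#' @export
write_angles <- function(angles, times, path, lines = NULL) {
  ids <- rownames(angles) %||% sprintf("s%04d", seq_len(nrow(angles)))
  df <- data.frame(id = ids, line = lines %||% ids, angles,
                   check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("t_", times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angles
#' @export
read_angles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcols <- grep("^t_", names(df))
  angles <- as.matrix(df[, tcols])
  rownames(angles) <- df$id
  list(angles = angles,
       times = as.numeric(sub("^t_", "", names(df)[tcols])),
       lines = df$line)
}

#' Write / read a fitted-parameter table
#'
#' @param params Parameter table from [fit_parameter_table()].
#' @param path CSV file.
#' @return `path` invisibly; the reader returns the `data.frame`.
#' @export
write_parameters <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) utils::read.csv(path)

#' Write / read simulation ground truth as JSON
#'
#' @param truth Any serializable truth structure.
#' @param path JSON file.
#' @return `path` invisibly; the reader returns the structure.
#' @export
write_truth <- function(truth, path) {
  truth$scenario <- NULL  # closures/seeds echoed in the run log instead
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::fromJSON(path)

#' Write a QTL model (or list of models) as JSON
#'
#' @param model A `qtl_model`, `pqtl_result`, or list of models.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_qtl_model <- function(model, path) {
  strip <- function(m) list(qtl = m$qtl, lod = m$lod, plod = m$plod,
                            penalty = m$penalty, intervals = m$intervals,
                            n = m$n)
  obj <- if (inherits(model, "qtl_model")) strip(model)
  else if (inherits(model, "pqtl_result")) lapply(model$models, strip)
  else lapply(model, strip)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Write interval / anchor / candidate tables as TSV
#'
#' @param df A `data.frame`.
#' @param path TSV file.
#' @return `path` invisibly; `read_tsv_table()` returns the
#'   `data.frame`.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Write the files of a simulated proteome pair
#'
#' FASTA proteomes (sequence names = gene ids), GFF3 annotations with
#' gene and mRNA features, interval and anchor TSVs, and the truth JSON.
#'
#' @param sim A `sim_proteomes` object.
#' @param dir Output directory.
#' @return Named list of file paths.
#' @export
write_proteome_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (sp in c("a", "b")) {
    fa <- file.path(dir, sprintf("proteome_%s.fasta", sp))
    seqs <- sim$proteomes[[sp]]
    ann <- sim$annotations[[sp]]
    ## FASTA records are keyed by protein id, as in real proteome files
    names(seqs) <- ann$protein_id[match(names(seqs), ann$gene_id)]
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fa)
    gff <- file.path(dir, sprintf("annotation_%s.gff3", sp))
    write_gene_gff3(sim$annotations[[sp]], gff)
    iv <- file.path(dir, sprintf("intervals_%s.tsv", sp))
    write_tsv_table(sim$intervals[[sp]], iv)
    an <- file.path(dir, sprintf("anchors_%s.tsv", sp))
    write_tsv_table(sim$anchors[[sp]], an)
    paths[[paste0("proteome_", sp)]] <- fa
    paths[[paste0("annotation_", sp)]] <- gff
    paths[[paste0("intervals_", sp)]] <- iv
    paths[[paste0("anchors_", sp)]] <- an
  }
  tj <- file.path(dir, "orthology_truth.json")
  jsonlite::write_json(sim$truth, tj, auto_unbox = TRUE, digits = NA)
  paths$truth <- tj
  paths
}

## GFF3 with a gene and one mRNA feature per gene
write_gene_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = rep(ann$chrom, 2),
    ranges = IRanges::IRanges(start = rep(ann$start, 2),
                              end = rep(ann$end, 2)),
    strand = rep(ann$strand, 2))
  n <- nrow(ann)
  gr$type <- rep(c("gene", "mRNA"), each = n)
  gr$ID <- c(ann$gene_id, ann$protein_id)
  gr$Parent <- c(rep(NA_character_, n), ann$gene_id)
  gr$source <- "graviqtl"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation (GFF3) with representative proteins
#'
#' Imports gene and mRNA features; each gene's representative protein
#' is the longest of its mRNA isoforms found in the proteome FASTA.
#'
#' @param gff GFF3 file with `gene` and `mRNA` features.
#' @param fasta Protein FASTA whose names match mRNA IDs.
#' @return List: `annotation` (`data.frame` with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `protein_id`) and `proteome` (named
#'   character vector keyed by gene id).
#' @export
read_annotation <- function(gff, fasta) {
  gr <- rtracklayer::import(gff, format = "gff3")
  prot <- Biostrings::readAAStringSet(fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  genes <- gr[gr$type == "gene"]
  mrna <- gr[gr$type == "mRNA"]
  parent <- as.character(unlist(mrna$Parent))
  ann <- do.call(rbind, lapply(seq_along(genes), function(i) {
    gid <- genes$ID[i]
    iso <- mrna[parent == gid]
    iso_ids <- intersect(iso$ID, names(prot))
    if (length(iso_ids) == 0) return(NULL)
    rep_id <- iso_ids[which.max(Biostrings::width(prot[iso_ids]))]
    data.frame(gene_id = gid,
               chrom = as.character(GenomicRanges::seqnames(genes)[i]),
               start = GenomicRanges::start(genes)[i],
               end = GenomicRanges::end(genes)[i],
               strand = as.character(GenomicRanges::strand(genes)[i]),
               protein_id = rep_id, stringsAsFactors = FALSE)
  }))
  proteome <- stats::setNames(as.character(prot[ann$protein_id]),
                              ann$gene_id)
  list(annotation = ann, proteome = proteome)
}

#' Render a tQTL LOD heatmap as PNG
#'
#' Blue intensity proportional to LOD for significant cells, white for
#' insignificant (zero) cells; x = time (min), y = cumulative cM with
#' dashed lines at chromosome boundaries.
#'
#' @param heatmap Positions x times matrix (0 = insignificant).
#' @param info Position table (`chr`, `pos`), rows aligned to the
#'   heatmap.
#' @param times Mapped time points, minutes.
#' @param path Output PNG.
#' @param annotate Draw axes and chromosome separators (set `FALSE` for
#'   a bare, pixel-addressable image).
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(heatmap, info, times, path, annotate = TRUE,
                           width = 700, height = 500) {
  if (length(heatmap) == 0 || nrow(heatmap) == 0)
    stop("empty heatmap matrix")
  ## cumulative cM coordinate with a gap between chromosomes
  chrs <- unique(info$chr)
  offset <- 0
  cum <- numeric(nrow(info))
  breaks <- numeric(0)
  for (ch in chrs) {
    i <- which(info$chr == ch)
    cum[i] <- info$pos[i] - min(info$pos[i]) + offset
    offset <- max(cum[i]) + 2
    breaks <- c(breaks, offset)
  }
  breaks <- utils::head(breaks, -1)
  top <- max(heatmap, 1e-9)
  pal <- grDevices::colorRampPalette(c("white", "#9ecae1", "#08306b"))(256)
  col_idx <- function(v) ifelse(v <= 0, 1L, 1L + ceiling(254 * v / top))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (annotate) {
    graphics::par(mar = c(4, 4, 2, 1))
  } else {
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  }
  graphics::image(x = times, y = cum, z = t(matrix(col_idx(heatmap),
                                                   nrow(heatmap))),
                  col = pal, zlim = c(1, 256), useRaster = FALSE,
                  xlab = if (annotate) "time (min)" else "",
                  ylab = if (annotate) "cumulative cM" else "",
                  axes = annotate)
  if (annotate) {
    graphics::abline(h = breaks, lty = 2)
    graphics::box()
  }
  invisible(path)
}
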