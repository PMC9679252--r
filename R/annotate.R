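#' Read gene annotation intervals
#'
#' Parses GFF3 or BED via `rtracklayer` and returns gene intervals on the
#' internal 1-based inclusive convention (GFF3 is already 1-based
#' inclusive; BED's 0-based half-open intervals are converted). For GFF3,
#' features are restricted to `feature_types` and named from the `Name`,
#' `ID` or `gene_id` attribute, in that order of preference.
#'
#' @param path annotation file.
#' @param format `"auto"` (from the file extension), `"gff3"` or `"bed"`.
#' @param feature_types GFF3 feature types to keep (default `gene`,
#'   `mRNA`).
#' @return data.frame with `name`, `lg`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed"),
                            feature_types = c("gene", "mRNA")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- if (format == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    rtracklayer::import(path, format = "GFF3")
  }
  if (format == "gff3") {
    if (!is.null(gr$type)) gr <- gr[as.character(gr$type) %in% feature_types]
    nm <- rep(NA_character_, length(gr))
    for (field in c("Name", "ID", "gene_id")) {
      v <- S4Vectors::mcols(gr)[[field]]
      if (!is.null(v)) {
        v <- as.character(v)
        nm[is.na(nm) & !is.na(v)] <- v[is.na(nm) & !is.na(v)]
      }
    }
    nm[is.na(nm)] <- sprintf("feature_%d", which(is.na(nm)))
  } else {
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("feature_%d", seq_along(gr))
  }
  if (!length(gr)) stop("no gene features found in ", path)
  data.frame(
    name = nm,
    lg = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Genes overlapping islands, with SNP counts and mean F_ST
#'
#' A gene is reported when its body overlaps an island interval by at
#' least 1 bp. For each reported gene, all SNPs inside the gene body are
#' counted (membership is by gene body, not clipped to the island) and
#' their mean per-SNP F_ST recorded; genes containing no SNPs are
#' omitted.
#'
#' @param islands a [find_islands()] result (`lg`, `start`, `end`,
#'   `island_id`).
#' @param genes gene intervals from [read_annotation()].
#' @param snps data.frame with `lg`, `pos` and `fst` (per-SNP F_ST for
#'   the comparison, e.g. from [per_snp_stats()]).
#' @return data.frame with one row per qualifying gene: `name`, `lg`,
#'   `start`, `end`, `islands` (comma-separated overlapped island ids),
#'   `n_snps`, `mean_fst`.
#' @export
genes_in_islands <- function(islands, genes, snps) {
  empty <- data.frame(
    name = character(0), lg = character(0), start = integer(0),
    end = integer(0), islands = character(0), n_snps = integer(0),
    mean_fst = numeric(0), stringsAsFactors = FALSE
  )
  if (!nrow(islands) || !nrow(genes)) return(empty)
  gene_gr <- GenomicRanges::GRanges(
    genes$lg, IRanges::IRanges(genes$start, genes$end))
  isl_gr <- GenomicRanges::GRanges(
    islands$lg, IRanges::IRanges(islands$start, islands$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, isl_gr)
  if (!length(hits)) return(empty)
  snp_gr <- GenomicRanges::GRanges(
    snps$lg, IRanges::IRanges(snps$pos, snps$pos))

  gene_idx <- sort(unique(S4Vectors::queryHits(hits)))
  out <- lapply(gene_idx, function(g) {
    isl_ids <- islands$island_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == g]]
    in_gene <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(snp_gr, gene_gr[g]))
    if (!length(in_gene)) return(NULL)
    data.frame(
      name = genes$name[g], lg = genes$lg[g],
      start = genes$start[g], end = genes$end[g],
      islands = paste(sort(isl_ids), collapse = ","),
      n_snps = length(in_gene),
      mean_fst = mean(snps$fst[in_gene], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$lg, out$start, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
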