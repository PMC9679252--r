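#' Read a pooled allele-count table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv`}{the package's native format: header `lg  pos  ref  alt`
#'     followed by one integer reference-count column per pool, with `.`
#'     for missing calls. Counts are on the pool ploidy scale, so the
#'     `1/C` quantization of pooled calls survives a round trip (unlike
#'     sync, which stores read counts). An optional companion depth file
#'     (same shape) can be given via `depth_path`.}
#'   \item{`sync`}{PoPoolation2 sync: `chr  pos  ref` then one
#'     `A:T:C:G:N:del` colon-separated read-count cell per pool. The two
#'     most frequent alleles over all pools are kept (the major one as
#'     reference if the stated reference base is not among them), each
#'     pool's depth-based frequency is rounded to the nearest `1/C`, and
#'     cells with zero coverage of the two alleles become missing. Read
#'     depths are taken from the two retained alleles.}
#' }
#'
#' @param path input file.
#' @param format `"tsv"` or `"sync"`.
#' @param ploidy pool ploidy `C` (default 20).
#' @param superpools optional named character vector mapping pool id to
#'   superpool label; defaults to each pool being its own superpool.
#' @param depth_path optional depth TSV for `format = "tsv"`.
#' @return a [pool_matrix()].
#' @export
read_pool_table <- function(path, format = c("tsv", "sync"), ploidy = 20L,
                            superpools = NULL, depth_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    read_pool_tsv(path, ploidy, superpools, depth_path)
  } else {
    read_pool_sync(path, ploidy, superpools)
  }
}

read_pool_tsv <- function(path, ploidy, superpools, depth_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = ".", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(lg = "character", pos = "integer",
                                          ref = "character", alt = "character"))
  fixed <- c("lg", "pos", "ref", "alt")
  if (!all(fixed %in% names(tab))) {
    stop("native TSV must start with columns: ", paste(fixed, collapse = ", "))
  }
  pool_ids <- setdiff(names(tab), fixed)
  if (!length(pool_ids)) stop("no pool columns in ", path)
  counts <- as.matrix(tab[, pool_ids, drop = FALSE])
  if (any(counts != round(counts), na.rm = TRUE)) {
    bad <- which(apply(counts != round(counts), 1, any, na.rm = TRUE))[1]
    stop("non-integer allele count at line ", bad + 1L, " of ", path)
  }
  mode(counts) <- "integer"
  depths <- NULL
  if (!is.null(depth_path)) {
    dtab <- utils::read.table(depth_path, header = TRUE, sep = "\t",
                              na.strings = ".", check.names = FALSE,
                              comment.char = "#", stringsAsFactors = FALSE)
    depths <- as.matrix(dtab[, pool_ids, drop = FALSE])
    mode(depths) <- "integer"
    depths[is.na(depths)] <- 0L
  }
  pool_matrix(tab[, fixed], counts, pool_meta(pool_ids, ploidy, superpools),
              depths)
}

read_pool_sync <- function(path, ploidy, superpools) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("empty sync file: ", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(rows)
  if (any(ncol != ncol[1]) || ncol[1] < 4) {
    stop("malformed sync row at line ",
         which(ncol != ncol[1] | ncol < 4)[1], " of ", path)
  }
  n_pool <- ncol[1] - 3L
  pool_ids <- sprintf("pool%d", seq_len(n_pool))
  bases <- c("A", "T", "C", "G")
  n <- length(rows)
  counts <- matrix(NA_integer_, n, n_pool)
  depths <- matrix(0L, n, n_pool)
  ref <- alt <- character(n)
  lg <- vapply(rows, `[`, "", 1L)
  pos <- as.integer(vapply(rows, `[`, "", 2L))
  for (i in seq_len(n)) {
    cells <- rows[[i]][-(1:3)]
    mat <- vapply(strsplit(cells, ":", fixed = TRUE), function(x) {
      v <- suppressWarnings(as.integer(x))
      if (length(v) != 6 || anyNA(v)) {
        stop("malformed sync cell at line ", i, " of ", path)
      }
      v
    }, integer(6))  # 6 x n_pool: A,T,C,G,N,del
    tot <- rowSums(mat[1:4, , drop = FALSE])
    top2 <- order(tot, decreasing = TRUE)[1:2]
    stated_ref <- toupper(rows[[i]][3])
    if (stated_ref %in% bases[top2]) {
      ref_i <- match(stated_ref, bases)
      alt_i <- setdiff(top2, ref_i)[1]
    } else {
      ref_i <- top2[1]
      alt_i <- top2[2]
    }
    ref[i] <- bases[ref_i]
    alt[i] <- bases[alt_i]
    d <- mat[ref_i, ] + mat[alt_i, ]
    depths[i, ] <- as.integer(d)
    has <- d > 0
    counts[i, has] <- as.integer(round(mat[ref_i, has] / d[has] * ploidy))
  }
  pool_matrix(
    data.frame(lg = lg, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    counts, pool_meta(pool_ids, ploidy, superpools), depths
  )
}

pool_meta <- function(pool_ids, ploidy, superpools) {
  sp <- if (is.null(superpools)) {
    stats::setNames(pool_ids, pool_ids)
  } else {
    superpools
  }
  if (!all(pool_ids %in% names(sp))) {
    stop("superpool mapping missing for: ",
         paste(setdiff(pool_ids, names(sp)), collapse = ", "))
  }
  data.frame(pool_id = pool_ids, ploidy = as.integer(ploidy),
             superpool = unname(sp[pool_ids]), stringsAsFactors = FALSE)
}

#' Write a pool_matrix as native TSV
#'
#' Inverse of [read_pool_table()] with `format = "tsv"`: missing counts
#' are written as `.`. Depths, if present, go to `depth_path` in the same
#' layout.
#'
#' @param m a [pool_matrix()].
#' @param path output TSV path.
#' @param depth_path optional output path for the depth matrix.
#' @return `path`, invisibly.
#' @export
write_pool_table <- function(m, path, depth_path = NULL) {
  tab <- cbind(m$snps[, c("lg", "pos", "ref", "alt")],
               as.data.frame(m$counts))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  if (!is.null(depth_path)) {
    if (is.null(m$depths)) stop("no depths to write")
    dtab <- cbind(m$snps[, c("lg", "pos", "ref", "alt")],
                  as.data.frame(m$depths))
    utils::write.table(dtab, depth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  invisible(path)
}

#' Read-depth filter
#'
#' Removes every SNP at which any pool's read depth is below `min_depth`
#' or above `max_frac` of that pool's total reads (depth summed over all
#' SNPs present before filtering). The per-pool caps therefore adapt to
#' each pool's overall coverage.
#'
#' @param m a [pool_matrix()] with depths.
#' @param min_depth minimum per-pool depth (default 20).
#' @param max_frac maximum depth as a fraction of the pool's total reads
#'   (default 0.02).
#' @return the filtered [pool_matrix()]; the number of SNPs removed and
#'   the per-pool caps are attached as attributes `"removed"` and
#'   `"depth_caps"`.
#' @export
filter_depth <- function(m, min_depth = 20, max_frac = 0.02) {
  if (is.null(m$depths)) stop("depth filter requires read depths")
  caps <- colSums(m$depths, na.rm = TRUE) * max_frac
  too_low <- m$depths < min_depth
  too_high <- sweep(m$depths, 2, caps, ">")
  drop <- apply(too_low | too_high, 1, any, na.rm = TRUE) |
    apply(is.na(m$depths), 1, any)
  out <- subset_snps(m, !drop)
  attr(out, "removed") <- sum(drop)
  attr(out, "depth_caps") <- caps
  out
}

#' Completeness / biallelic / variant filter
#'
#' Removes SNPs with a missing call in any pool and SNPs that are
#' invariant across all pools (reference count 0 in every pool, or equal
#' to the ploidy in every pool). Sites flagged multi-allelic upstream
#' should not reach this container (the readers collapse to two
#' alleles), so biallelicity is structural here.
#'
#' @param m a [pool_matrix()].
#' @return the filtered [pool_matrix()] with attribute `"removed"`.
#' @export
filter_complete_biallelic_variant <- function(m) {
  missing_any <- apply(is.na(m$counts), 1, any)
  C <- m$pools$ploidy
  all_zero <- apply(m$counts == 0, 1, all)
  all_fixed <- apply(sweep(m$counts, 2, C, "=="), 1, all)
  drop <- missing_any | (!missing_any & (all_zero | all_fixed))
  out <- subset_snps(m, !drop)
  attr(out, "removed") <- sum(drop)
  out
}

#' Standard two-step SNP filtering
#'
#' Applies [filter_depth()] then [filter_complete_biallelic_variant()].
#'
#' @inheritParams filter_depth
#' @return the filtered [pool_matrix()].
#' @export
filter_standard <- function(m, min_depth = 20, max_frac = 0.02) {
  filter_complete_biallelic_variant(filter_depth(m, min_depth, max_frac))
}

#' Write windows or islands as a BED track
#'
#' Intervals are written 0-based half-open per BED convention (internal
#' coordinates are 1-based inclusive).
#'
#' @param x data.frame with `lg`, `start`, `end` and optionally a name
#'   column (`island_id` is used when present).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("island_id" %in% names(x)) x$island_id else
    sprintf("%s_%d", x$lg, seq_len(nrow(x)))
  bed <- data.frame(chrom = x$lg, start = as.integer(x$start) - 1L,
                    end = as.integer(x$end), name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
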