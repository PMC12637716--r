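#' Read a BED file into a region_set
#'
#' Reads 3+ column tab-separated BED. Comment (`#`), `track` and `browser`
#' lines are skipped. Extra columns beyond the first three are preserved as
#' opaque annotation columns (`V4`, `V5`, ... unless the file is headered,
#' which BED is not). The result is normalized to genomic sort order.
#'
#' @param path path to a BED file (plain or gzip-compressed).
#' @param name optional region-set identifier (defaults to the file name).
#' @return A `region_set`.
#' @export
read_bed <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("read_bed: file not found: ", path, call. = FALSE)
  lines <- readLines(gzfile(path))
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(region_set(name = name))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("read_bed: line %d has %d field(s); need >= 3 tab-separated fields",
                 lineno[which(nf < 3L)[1L]], min(nf)), call. = FALSE)
  }
  ncol_keep <- min(nf)
  m <- t(vapply(fields, function(f) f[seq_len(ncol_keep)], character(ncol_keep)))
  if (ncol_keep == 1L) m <- matrix(m, ncol = 1L)  # defensive; cannot occur with nf >= 3
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad)) {
    stop(sprintf("read_bed: parse error at line %d: '%s' (non-integer coordinates or end <= start)",
                 lineno[bad[1L]], lines[bad[1L]]), call. = FALSE)
  }
  df <- data.frame(chrom = m[, 1L], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (ncol_keep > 3L) {
    extra <- as.data.frame(m[, 4:ncol_keep, drop = FALSE], stringsAsFactors = FALSE)
    names(extra) <- paste0("V", 4:ncol_keep)
    df <- cbind(df, extra)
  }
  as_region_set(df, name = name)
}

#' Write a region_set as BED
#'
#' Emits tab-separated BED in genomic sort order. Extra annotation columns
#' are written after the three coordinate columns when `keep_extra = TRUE`.
#' `read_bed(write_bed(x))` recovers the normalized region set.
#'
#' @param regions a `region_set`.
#' @param path output path.
#' @param keep_extra write annotation columns too (default TRUE).
#' @export
write_bed <- function(regions, path, keep_extra = TRUE) {
  regions <- as_region_set(regions)
  df <- as.data.frame(regions)
  if (!keep_extra) df <- df[, c("chrom", "start", "end"), drop = FALSE]
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_bed: cannot write '", path, "': ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Read a 10x-style fragments file
#'
#' Parses the 5-column tab-separated fragments dialect
#' (chrom, start, end, barcode, count), optionally gzip-compressed; `#`
#' comment lines are skipped. The 4-column dialect without a count column is
#' accepted with count = 1. Fragments are grouped by cell barcode.
#'
#' @param path path to fragments.tsv or fragments.tsv.gz.
#' @param allowed_barcodes optional character vector; other barcodes dropped.
#' @return A `cell_fragment_store`: list with `fragments` (one data.frame per
#'   barcode, columns chrom/start/end/barcode/count) and `summary` (per-barcode
#'   fragment counts).
#' @export
read_fragments <- function(path, allowed_barcodes = NULL) {
  if (!file.exists(path)) stop("read_fragments: file not found: ", path, call. = FALSE)
  lines <- readLines(gzfile(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("read_fragments: no fragments in ", path)
    return(new_fragment_store(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(4L, 5L))) {
    stop(sprintf("read_fragments: line %d has %d column(s); expected 5 (or 4 without count)",
                 which(!(nf %in% c(4L, 5L)))[1L], nf[!(nf %in% c(4L, 5L))][1L]),
         call. = FALSE)
  }
  get_f <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1L))
  df <- data.frame(chrom = get_f(1L),
                   start = suppressWarnings(as.integer(get_f(2L))),
                   end = suppressWarnings(as.integer(get_f(3L))),
                   barcode = get_f(4L),
                   count = suppressWarnings(as.integer(get_f(5L, "1"))),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start |
                 is.na(df$count) | df$count < 1L)
  if (length(bad)) {
    stop(sprintf("read_fragments: parse error at data line %d: '%s'",
                 bad[1L], lines[bad[1L]]), call. = FALSE)
  }
  if (!is.null(allowed_barcodes)) {
    df <- df[df$barcode %in% allowed_barcodes, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    warning("read_fragments: empty store after barcode filtering")
    return(new_fragment_store(list()))
  }
  # order-independent grouping: sort fragments within each barcode
  df <- df[order(df$barcode, df$chrom, df$start, df$end, method = "radix"), ,
           drop = FALSE]
  frs <- split(df, df$barcode)
  frs <- lapply(frs, function(d) { rownames(d) <- NULL; d })
  new_fragment_store(frs)
}

new_fragment_store <- function(frs) {
  out <- list(fragments = frs,
              summary = data.frame(barcode = names(frs),
                                   n_fragments = vapply(frs, nrow, integer(1L)),
                                   row.names = NULL,
                                   stringsAsFactors = FALSE))
  class(out) <- "cell_fragment_store"
  out
}

#' @export
print.cell_fragment_store <- function(x, ...) {
  cat(sprintf("cell_fragment_store with %d barcode(s), %d fragment(s)\n",
              nrow(x$summary), sum(x$summary$n_fragments)))
  invisible(x)
}

#' Read a peak-by-cell count matrix with sidecar files
#'
#' Loads a MatrixMarket coordinate file plus a peaks BED and a barcodes text
#' file, and resolves the orientation so that rows are cells and columns are
#' peaks.
#'
#' @param mtx_path MatrixMarket .mtx file.
#' @param peaks_bed_path BED file of peak coordinates (one per matrix peak).
#' @param barcodes_path text file with one cell barcode per line.
#' @return list with `matrix` (sparse dgCMatrix, cells x peaks), `peaks`
#'   (`region_set`, in file order as loaded then normalized order is stored in
#'   `peaks`; the column order of `matrix` matches the *file* order of peaks),
#'   and `barcodes`.
#' @export
read_count_matrix <- function(mtx_path, peaks_bed_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  m <- methods::as(m, "CsparseMatrix")
  peaks_raw <- read_bed_file_order(peaks_bed_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  np <- nrow(peaks_raw); nb <- length(barcodes)
  if (nrow(m) == nb && ncol(m) == np) {
    # already cells x peaks
  } else if (nrow(m) == np && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(paste0("read_count_matrix: matrix is %d x %d but sidecars give ",
                        "%d peak(s) and %d barcode(s)"),
                 nrow(m), ncol(m), np, nb), call. = FALSE)
  }
  rownames(m) <- barcodes
  list(matrix = m, peaks = peaks_raw, barcodes = barcodes)
}

# BED reader that preserves file order (needed to match matrix columns);
# coordinates validated but not re-sorted.
read_bed_file_order <- function(path) {
  rs <- read_bed(path)  # validates
  lines <- readLines(gzfile(path))
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = as.integer(vapply(fields, `[`, "", 2L)),
                   end = as.integer(vapply(fields, `[`, "", 3L)),
                   stringsAsFactors = FALSE)
  class(df) <- c("region_set_file_order", "data.frame")
  df
}

#' Extract transcription start sites from a GTF file
#'
#' Uses `transcript` features. The TSS of a `+` transcript is the feature
#' start converted to 0-based; for a `-` transcript it is the (1-based,
#' inclusive) feature end converted to 0-based. Records with unknown strand
#' are skipped with a warning; duplicates at identical (chrom, position,
#' strand) are collapsed.
#'
#' @param gtf_path path to a GTF file.
#' @return data.frame with columns `chrom`, `position` (0-based), `strand`,
#'   `gene_id`, sorted by (chrom, position).
#' @export
extract_tss <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  if (length(gr) == 0L) stop("extract_tss: no transcript features in ", gtf_path,
                             call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  unknown <- strand == "*"
  if (any(unknown)) {
    warning(sprintf("extract_tss: skipping %d record(s) with missing strand",
                    sum(unknown)))
    gr <- gr[!unknown]; strand <- strand[!unknown]
  }
  # rtracklayer gives 1-based inclusive [start, end]
  pos <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  gene_id <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
    as.character(seq_along(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   position = as.integer(pos),
                   strand = strand,
                   gene_id = gene_id,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$position, df$strand, df$gene_id,
                 method = "radix"), , drop = FALSE]
  df <- df[!duplicated(df[, c("chrom", "position", "strand")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

tss_records <- function(chrom, position, strand, gene_id) {
  stopifnot(all(strand %in% c("+", "-")))
  df <- data.frame(chrom = as.character(chrom), position = as.integer(position),
                   strand = strand, gene_id = as.character(gene_id),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$position, df$strand, df$gene_id,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a bedGraph signal track
#'
#' 4-column bedGraph (chrom, start, end, value). Intervals are sorted;
#' overlapping intervals are accepted (resolved during aggregation).
#'
#' @param path bedGraph file (plain or gzipped).
#' @return A `signal_track`: region_set with a numeric `value` column.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) stop("read_signal_track: file not found: ", path,
                               call. = FALSE)
  lines <- readLines(gzfile(path))
  lines <- lines[nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L) {
    st <- region_set(value = numeric())
    class(st) <- c("signal_track", class(st))
    return(st)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop(sprintf("read_signal_track: line %d has fewer than 4 columns",
                 which(lengths(fields) < 4L)[1L]), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  if (any(!is.finite(val))) {
    stop(sprintf("read_signal_track: non-numeric or non-finite value at line %d",
                 which(!is.finite(val))[1L]), call. = FALSE)
  }
  st <- region_set(chrom = vapply(fields, `[`, "", 1L),
                   start = as.integer(vapply(fields, `[`, "", 2L)),
                   end = as.integer(vapply(fields, `[`, "", 3L)),
                   value = val)
  class(st) <- c("signal_track", class(st))
  st
}

#' Write a signal track as bedGraph
#' @param track a `signal_track` (region_set with a `value` column).
#' @param path output path.
#' @export
write_signal_track <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "end", "value")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
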