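#' Token sequences
#'
#' A `token_sequence` holds one cell's unordered set of vocabulary ids after
#' interval-overlap tokenization: integer ids in `[0, V)`, duplicates
#' collapsed, listed in ascending id order.
#'
#' @param cell_id cell identifier string.
#' @param tokens integer vector of vocabulary ids (0-based).
#' @param source_region_count number of raw input regions that produced them.
#' @param n_unmatched number of input regions overlapping no vocabulary region.
#' @return A `token_sequence`.
#' @export
token_sequence <- function(cell_id, tokens, source_region_count = length(tokens),
                           n_unmatched = NA_integer_) {
  tokens <- sort(unique(as.integer(tokens)))
  structure(list(cell_id = as.character(cell_id),
                 tokens = tokens,
                 source_region_count = as.integer(source_region_count),
                 n_unmatched = as.integer(n_unmatched)),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("token_sequence '%s': %d token(s) from %d region(s)\n",
              x$cell_id, length(x$tokens), x$source_region_count))
  invisible(x)
}

#' Context-window policy
#'
#' Limits a cell to at most `max_tokens` tokens, either by keeping the first
#' `C` in ascending id order (`truncate`) or by seeded sampling without
#' replacement (`sample`). Random sampling is the default, as it preserves
#' accessibility heterogeneity rather than biasing toward low-id regions.
#'
#' @param max_tokens context window size C (>= 1).
#' @param mode `"sample"` (default) or `"truncate"`.
#' @param seed integer seed driving the sample mode.
#' @return A `context_policy`.
#' @export
context_policy <- function(max_tokens = 256L, mode = c("sample", "truncate"),
                           seed = 0L) {
  mode <- match.arg(mode)
  max_tokens <- as.integer(max_tokens)
  stopifnot(max_tokens >= 1L)
  structure(list(max_tokens = max_tokens, mode = mode, seed = as.integer(seed)),
            class = "context_policy")
}

#' Apply a context-window policy to a token sequence
#'
#' If the cell has `<= C` tokens it is returned unchanged. `truncate` keeps
#' the first C tokens in ascending id order; `sample` draws C without
#' replacement. The draw is deterministic given (tokens, policy): the RNG
#' stream is derived from the policy seed and a hash of the token content,
#' and the caller's RNG state is untouched.
#'
#' @param ts a `token_sequence`.
#' @param policy a `context_policy`.
#' @return A `token_sequence` with at most C tokens, sorted by id.
#' @export
apply_context_policy <- function(ts, policy) {
  stopifnot(inherits(ts, "token_sequence"), inherits(policy, "context_policy"))
  n <- length(ts$tokens)
  if (n <= policy$max_tokens) return(ts)
  kept <- if (policy$mode == "truncate") {
    ts$tokens[seq_len(policy$max_tokens)]
  } else {
    h <- (as.double(policy$seed) + 1000003 * n + sum(as.double(ts$tokens))) %%
      2147483647
    with_local_seed(h, sort(sample(ts$tokens, policy$max_tokens)))
  }
  token_sequence(ts$cell_id, kept, ts$source_region_count, ts$n_unmatched)
}

# Core sweep: map sorted query intervals to vocabulary ids by strict overlap
# (>= 1 shared base; book-ended intervals do not match). Returns 0-based ids.
overlap_ids_sweep <- function(regions, vocab) {
  ids <- integer(0)
  n_unmatched <- 0L
  vdf <- as.data.frame(vocab)
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    v <- vdf[vdf$chrom == ch, , drop = FALSE]
    if (nrow(v) == 0L) { n_unmatched <- n_unmatched + nrow(r); next }
    # vocabulary regions are sorted, non-overlapping: ends are increasing too
    lo <- findInterval(r$start, v$end) + 1L      # first vocab with end > r.start
    hi <- findInterval(r$end - 1L, v$start)      # last vocab with start < r.end
    hit <- hi >= lo
    n_unmatched <- n_unmatched + sum(!hit)
    if (any(hit)) {
      lo <- lo[hit]; hi <- hi[hit]
      idx <- sequence(hi - lo + 1L, from = lo)
      ids <- c(ids, v$id[unique(idx)])
    }
  }
  list(ids = sort(unique(ids)), n_unmatched = n_unmatched)
}

#' Tokenize a region set against a vocabulary
#'
#' A vocabulary token is emitted iff some input region strictly overlaps it
#' (shared bases > 0); one input region spanning k vocabulary regions
#' contributes all k tokens; duplicates are collapsed. Implemented as a
#' sorted sweep per chromosome; input regions overlapping nothing are
#' counted in the `n_unmatched` field.
#'
#' @param regions a `region_set` (one cell's accessible regions).
#' @param vocab a `vocabulary`.
#' @param cell_id identifier for the resulting sequence.
#' @return A `token_sequence`.
#' @export
tokenize_regions <- function(regions, vocab, cell_id = attr(regions, "name") %||% "cell") {
  rs <- as_region_set(regions)
  stopifnot(inherits(vocab, "vocabulary"))
  res <- overlap_ids_sweep(rs, vocab)
  token_sequence(cell_id, res$ids, source_region_count = nrow(rs),
                 n_unmatched = res$n_unmatched)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize every barcode of a fragment store
#'
#' Fragment intervals are treated as accessible regions; read counts do not
#' weight tokens (tokenization is presence-based). The context policy, if
#' given, is applied per cell.
#'
#' @param store a `cell_fragment_store`.
#' @param vocab a `vocabulary`.
#' @param policy optional `context_policy`.
#' @return list of `token_sequence`, one per barcode (empty sequences kept).
#' @export
tokenize_fragment_store <- function(store, vocab, policy = NULL) {
  stopifnot(inherits(store, "cell_fragment_store"))
  out <- lapply(names(store$fragments), function(bc) {
    fr <- store$fragments[[bc]]
    rs <- region_set(fr$chrom, fr$start, fr$end)
    ts <- tokenize_regions(rs, vocab, cell_id = bc)
    if (!is.null(policy)) ts <- apply_context_policy(ts, policy) else ts
  })
  names(out) <- names(store$fragments)
  out
}

#' Tokenize a cells-by-peaks count matrix
#'
#' For each cell, the peaks with nonzero counts are tokenized as a region
#' set (count values are binarized: presence only). The peak-to-token
#' mapping is computed once and reused across cells.
#'
#' @param matrix sparse or dense cells x peaks count matrix.
#' @param peaks peak coordinates in matrix column order (data.frame with
#'   chrom/start/end, e.g. the `peaks` element of [read_count_matrix()]).
#' @param barcodes cell identifiers, length nrow(matrix).
#' @param vocab a `vocabulary`.
#' @param policy optional `context_policy`.
#' @return list of `token_sequence`, one per cell.
#' @export
tokenize_count_matrix <- function(matrix, peaks, barcodes, vocab, policy = NULL) {
  if (nrow(matrix) != length(barcodes)) {
    stop(sprintf("tokenize_count_matrix: %d matrix row(s) but %d barcode(s)",
                 nrow(matrix), length(barcodes)), call. = FALSE)
  }
  if (ncol(matrix) != nrow(peaks)) {
    stop(sprintf("tokenize_count_matrix: %d matrix column(s) but %d peak(s)",
                 ncol(matrix), nrow(peaks)), call. = FALSE)
  }
  # map each peak (file order) to its overlapping vocabulary ids
  peak_tokens <- vector("list", nrow(peaks))
  ord_rs <- as_region_set(data.frame(chrom = peaks$chrom, start = peaks$start,
                                     end = peaks$end,
                                     peak_idx = seq_len(nrow(peaks))))
  vdf <- as.data.frame(vocab)
  for (ch in unique(ord_rs$chrom)) {
    r <- ord_rs[ord_rs$chrom == ch, , drop = FALSE]
    v <- vdf[vdf$chrom == ch, , drop = FALSE]
    if (nrow(v) == 0L) next
    lo <- findInterval(r$start, v$end) + 1L
    hi <- findInterval(r$end - 1L, v$start)
    for (i in which(hi >= lo)) {
      peak_tokens[[r$peak_idx[i]]] <- v$id[lo[i]:hi[i]]
    }
  }
  m <- methods::as(methods::as(matrix, "CsparseMatrix"), "generalMatrix")
  out <- vector("list", length(barcodes))
  for (i in seq_along(barcodes)) {
    nz <- which(m[i, ] != 0)
    ts <- token_sequence(barcodes[i], unlist(peak_tokens[nz]),
                         source_region_count = length(nz))
    out[[i]] <- if (!is.null(policy)) apply_context_policy(ts, policy) else ts
  }
  names(out) <- barcodes
  out
}
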