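#' Merge overlapping and book-ended regions
#'
#' Collapses overlapping or book-ended (end == start) same-chromosome
#' intervals into maximal intervals (bedtools-merge semantics). Output is
#' sorted and non-overlapping.
#'
#' @param regions a `region_set` (or coercible data.frame).
#' @return A `region_set` of maximal merged intervals (coordinate columns only).
#' @export
merge_regions <- function(regions) {
  rs <- as_region_set(regions)
  if (nrow(rs) == 0L) return(region_set())
  out <- lapply(split(rs[, c("start", "end")], rs$chrom), function(d) {
    s <- d$start; e <- d$end  # already sorted by start within chrom
    run_end <- cummax_end <- cummax(e)
    new_run <- c(TRUE, s[-1L] > run_end[-length(e)])  # strict: book-ended merges
    grp <- cumsum(new_run)
    data.frame(start = tapply(s, grp, min), end = tapply(e, grp, max))
  })
  chroms <- rep(names(out), vapply(out, nrow, integer(1L)))
  merged <- do.call(rbind, out)
  region_set(chrom = chroms, start = merged$start, end = merged$end)
}

#' Build a consensus vocabulary from multiple peak sets
#'
#' Sweeps sorted start/end events and keeps maximal intervals of genomic
#' bases covered by at least `min_support` of the input peak sets, then
#' assigns dense integer ids in genomic order. Bases covered more than once
#' by the *same* set count once (each set is merged first).
#'
#' @param peak_sets list of `region_set`s.
#' @param min_support integer in `[1, length(peak_sets)]`.
#' @return A `vocabulary`.
#' @export
build_consensus <- function(peak_sets, min_support = 1L) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1L)
  min_support <- as.integer(min_support)
  if (is.na(min_support) || min_support < 1L || min_support > length(peak_sets)) {
    stop(sprintf("build_consensus: min_support must be in [1, %d], got %s",
                 length(peak_sets), min_support), call. = FALSE)
  }
  merged_sets <- lapply(peak_sets, merge_regions)
  ev <- do.call(rbind, lapply(merged_sets, function(rs)
    as.data.frame(rs)[, c("chrom", "start", "end")]))
  if (is.null(ev) || nrow(ev) == 0L) return(validate_vocabulary(region_set()))
  out <- lapply(split(ev, ev$chrom), function(d) {
    pos <- c(d$start, d$end)
    delta <- c(rep(1L, nrow(d)), rep(-1L, nrow(d)))
    o <- order(pos, -delta)  # starts before ends at the same base: book-ended
    pos <- pos[o]; cov <- cumsum(delta[o])  # coverage on [pos[i], pos[i+1])
    hit <- cov >= min_support
    if (!any(hit)) return(NULL)
    # segment boundaries where the >= min_support state flips
    state <- c(FALSE, hit)
    flips <- which(state[-1L] != state[-length(state)])
    starts <- pos[flips[state[flips + 1L]]]
    ends <- pos[flips[!state[flips + 1L]]]
    keep <- ends > starts
    data.frame(start = starts[keep], end = ends[keep])
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) return(validate_vocabulary(region_set()))
  chroms <- rep(names(out), vapply(out, nrow, integer(1L)))
  seg <- do.call(rbind, out)
  validate_vocabulary(region_set(chrom = chroms, start = seg$start, end = seg$end))
}

#' Validate a region set as a model vocabulary
#'
#' Asserts the regions are (after sorting) pairwise non-overlapping and
#' assigns dense integer ids `0 .. V-1` in genomic order.
#'
#' @param regions a `region_set`.
#' @return A `vocabulary`: region_set with an `id` column and attribute `V`.
#' @export
validate_vocabulary <- function(regions) {
  rs <- as_region_set(regions)
  if (nrow(rs) > 1L) {
    same_chrom <- rs$chrom[-1L] == rs$chrom[-nrow(rs)]
    overlap <- same_chrom & (rs$start[-1L] < rs$end[-nrow(rs)])
    if (any(overlap)) {
      i <- which(overlap)[1L]
      stop(sprintf("validate_vocabulary: regions %s:%d-%d and %s:%d-%d overlap",
                   rs$chrom[i], rs$start[i], rs$end[i],
                   rs$chrom[i + 1L], rs$start[i + 1L], rs$end[i + 1L]),
           call. = FALSE)
    }
  }
  rs$id <- seq_len(nrow(rs)) - 1L
  class(rs) <- c("vocabulary", class(rs))
  attr(rs, "V") <- nrow(rs)
  rs
}

#' Vocabulary size
#' @param vocab a `vocabulary`.
#' @return integer V.
#' @export
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  attr(vocab, "V")
}

#' Read / write a vocabulary as BED (id = line index)
#'
#' Serialization round-trips exactly: region `i` of the BED file has id
#' `i - 1`.
#' @param path BED path.
#' @return `read_vocabulary`: a `vocabulary`.
#' @export
read_vocabulary <- function(path) {
  validate_vocabulary(read_bed(path)[, c("chrom", "start", "end")])
}

#' @rdname read_vocabulary
#' @param vocab a `vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  write_bed(as_region_set(as.data.frame(vocab)[, c("chrom", "start", "end")]), path)
}
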