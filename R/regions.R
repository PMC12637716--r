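#' Genomic region sets
#'
#' A `region_set` is a data.frame with columns `chrom` (character),
#' `start` and `end` (integer, 0-based half-open, BED convention) plus any
#' number of extra annotation columns, kept in genomic sort order
#' (chromosome lexicographic, then start, then end). All coordinates in the
#' package are 0-based half-open; 1-based formats (GTF) are converted at the
#' boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start >= 0`, `end > start`.
#' @param ... extra annotation columns (recycled by `data.frame`).
#' @param name optional identifier stored as the `"name"` attribute.
#' @return A sorted, validated `region_set`.
#' @examples
#' region_set(c("chr1", "chr1"), c(100L, 50L), c(200L, 80L))
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer(),
                       ..., name = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   ...,
                   stringsAsFactors = FALSE)
  as_region_set(df, name = name)
}

#' Coerce a data.frame to a region_set
#'
#' Validates coordinates, sorts into genomic order, and attaches the class.
#'
#' @param df data.frame with at least `chrom`, `start`, `end` columns.
#' @param name optional identifier.
#' @return A `region_set`.
#' @export
as_region_set <- function(df, name = NULL) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_regions(df)
  ord <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  attr(df, "name") <- name
  df
}

validate_regions <- function(df, where = "regions") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0L | df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("%s: invalid coordinates at row(s) %s (need start >= 0 and end > start)",
                 where, paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @export
print.region_set <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("region_set%s with %d region(s) on %d chromosome(s)\n",
              if (is.null(nm)) "" else paste0(" '", nm, "'"),
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# number of bases covered, counting multiply-covered bases once
region_span <- function(rs) {
  if (nrow(rs) == 0L) return(0)
  m <- merge_regions(rs)
  sum(as.numeric(m$end - m$start))
}

#' Run a snippet with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded internals do not
#' perturb the global stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
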