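# Independent brute-force oracles used to check the package's
# implementations. These deliberately avoid the code paths they verify.

# quadratic all-pairs interval intersection (strict overlap)
oracle_tokenize <- function(regions, vocab) {
  vdf <- as.data.frame(vocab)
  rdf <- as.data.frame(regions)
  hits <- integer(0)
  for (i in seq_len(nrow(rdf))) {
    for (j in seq_len(nrow(vdf))) {
      if (rdf$chrom[i] == vdf$chrom[j] &&
          min(rdf$end[i], vdf$end[j]) > max(rdf$start[i], vdf$start[j])) {
        hits <- c(hits, vdf$id[j])
      }
    }
  }
  sort(unique(hits))
}

# per-base boolean coverage thresholding on a small genome
oracle_consensus <- function(peak_sets, min_support, genome_length,
                             chrom = "chr1") {
  cov <- integer(genome_length)
  for (rs in peak_sets) {
    seen <- logical(genome_length)
    d <- as.data.frame(rs)
    for (i in seq_len(nrow(d))) {
      if (d$chrom[i] != chrom) next
      idx <- (d$start[i] + 1L):min(d$end[i], genome_length)
      seen[idx] <- TRUE
    }
    cov <- cov + seen
  }
  hit <- cov >= min_support
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# pair-counting Rand-type index pieces computed directly over all pairs
pair_agreement <- function(lt, lp) {
  n <- length(lt)
  same_both <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (lt[i] == lt[j] && lp[i] == lp[j]) same_both <- same_both + 1
    }
  }
  same_both
}

# ARI by its definition, with the chance term obtained by enumerating every
# permutation of the predicted labels (the permutation model)
oracle_ari <- function(lt, lp, perms) {
  n <- length(lt)
  idx <- sum(vapply(seq_len(nrow(perms)), function(k)
    pair_agreement(lt, lp[perms[k, ]]), numeric(1)))
  expected <- idx / nrow(perms)
  index <- pair_agreement(lt, lp)
  same_t <- pair_agreement(lt, lt)
  same_p <- pair_agreement(lp, lp)
  max_index <- (same_t + same_p) / 2
  if (max_index == expected) return(1.0)
  (index - expected) / (max_index - expected)
}

oracle_mi <- function(lt, lp) {
  n <- length(lt)
  mi <- 0
  for (u in unique(lt)) {
    for (v in unique(lp)) {
      p_uv <- sum(lt == u & lp == v) / n
      if (p_uv > 0) {
        mi <- mi + p_uv * log(p_uv / (sum(lt == u) / n * sum(lp == v) / n))
      }
    }
  }
  mi
}

oracle_entropy <- function(l) {
  p <- as.numeric(table(l)) / length(l)
  -sum(p[p > 0] * log(p[p > 0]))
}

oracle_ami <- function(lt, lp, perms) {
  h_t <- oracle_entropy(lt); h_p <- oracle_entropy(lp)
  if (h_t == 0 && h_p == 0) return(1.0)
  emi <- mean(vapply(seq_len(nrow(perms)), function(k)
    oracle_mi(lt, lp[perms[k, ]]), numeric(1)))
  mi <- oracle_mi(lt, lp)
  denom <- max(h_t, h_p) - emi
  if (denom == 0) return(if (mi == emi) 1.0 else 0.0)
  (mi - emi) / denom
}

oracle_homogeneity <- function(lt, lp) {
  h_c <- oracle_entropy(lt)
  if (h_c == 0) return(1.0)
  n <- length(lt)
  h_ck <- 0
  for (v in unique(lp)) {
    sel <- lp == v
    h_ck <- h_ck + sum(sel) / n * oracle_entropy(lt[sel])
  }
  1 - h_ck / h_c
}

# ranks by counting, Pearson from first principles
oracle_spearman <- function(x, y) {
  rk <- function(v) vapply(v, function(a)
    1 + sum(v < a) + (sum(v == a) - 1) / 2, numeric(1))
  rx <- rk(x); ry <- rk(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# all set partitions of 1..n as label vectors
all_partitions <- function(n) {
  if (n == 1L) return(list(c(1L)))
  prev <- all_partitions(n - 1L)
  out <- list()
  for (p in prev) {
    k <- max(p)
    for (b in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  prev <- all_perms(n - 1L)
  out <- matrix(0L, nrow(prev) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(prev))) {
      r <- r + 1L
      row <- prev[i, ]
      out[r, ] <- append(row, n, after = pos - 1L)
    }
  }
  out
}

random_region_set <- function(n, genome_length = 1e5, max_len = 500,
                              chroms = c("chr1", "chr2")) {
  start <- sample.int(genome_length - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  region_set(sample(chroms, n, replace = TRUE), start, start + len)
}
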