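#' Seeded k-means clustering with k-means++ initialization
#'
#' Lloyd's algorithm (via `stats::kmeans`) started from seeded k-means++
#' centers, with `n_init` restarts keeping the lowest total
#' within-cluster sum of squares. The number of clusters is typically set to
#' the number of distinct cell types.
#'
#' @param embeddings points x dim matrix.
#' @param k number of clusters (`1 <= k <= n`).
#' @param seed RNG seed.
#' @param n_init number of k-means++ restarts.
#' @return integer labels in `[0, k)`.
#' @export
kmeans_cluster <- function(embeddings, k, seed = 0L, n_init = 10L) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (k < 1L || k > n) stop(sprintf("kmeans_cluster: k=%d out of range [1, %d]",
                                    k, n), call. = FALSE)
  if (k == 1L) return(rep(0L, n))
  with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      centers <- kmeanspp_centers(X, k)
      fit <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    as.integer(best$cluster) - 1L
  })
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  # nudge exact duplicates so stats::kmeans accepts the centers
  if (anyDuplicated(centers)) {
    dup <- duplicated(centers)
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(X), sd = 1e-9), sum(dup))
  }
  centers
}

contingency <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  table(true = as.character(labels_true), pred = as.character(labels_pred))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, computed from the
#' contingency table `n_ij` with row sums `a_i`, column sums `b_j`:
#' `ARI = (sum choose(n_ij,2) - E) / (max - E)` with
#' `E = sum choose(a_i,2) * sum choose(b_j,2) / choose(n,2)` and
#' `max = (sum choose(a_i,2) + sum choose(b_j,2)) / 2`. Invariant to label
#' renaming; 1 on identical partitions.
#'
#' @param labels_true,labels_pred equal-length label vectors (n >= 2).
#' @return scalar in [-1, 1].
#' @export
ari <- function(labels_true, labels_pred) {
  n <- length(labels_true)
  stopifnot(n >= 2L)
  tab <- contingency(labels_true, labels_pred)
  sum_nij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1.0)  # both partitions trivial
  (sum_nij - expected) / (max_index - expected)
}

entropy_counts <- function(cnt) {
  n <- sum(cnt)
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  unname(mi)
}

# expected mutual information under the permutation (hypergeometric) model
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1L, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lchoose(b[j], nij) + lchoose(n - b[j], a[i] - nij) - lchoose(n, a[i])
        emi <- emi + exp(lp) * nij / n * log(n * nij / (a[i] * b[j]))
      }
    }
  }
  unname(emi)
}

#' Adjusted mutual information
#'
#' Mutual information between two labelings, adjusted for chance under the
#' permutation model and normalized by the maximum of the two label
#' entropies: `AMI = (MI - E[MI]) / (max(H_true, H_pred) - E[MI])`. Both
#' partitions trivial (zero entropy) gives 1.
#'
#' @inheritParams ari
#' @return scalar (1 on identical partitions).
#' @export
ami <- function(labels_true, labels_pred) {
  tab <- contingency(labels_true, labels_pred)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  h_a <- entropy_counts(a); h_b <- entropy_counts(b)
  if (h_a == 0 && h_b == 0) return(1.0)
  mi <- mutual_information(tab)
  emi <- expected_mutual_information(a, b, n)
  denom <- max(h_a, h_b) - emi
  if (denom == 0) return(if (mi == emi) 1.0 else 0.0)
  (mi - emi) / denom
}

#' Homogeneity score
#'
#' Entropy-based external cluster metric: `1 - H(C|K) / H(C)` where C is the
#' ground-truth labeling and K the predicted clustering. 1 when every
#' predicted cluster contains members of a single true class; defined as 1
#' when `H(C) = 0`.
#'
#' @inheritParams ari
#' @return scalar in [0, 1].
#' @export
homogeneity <- function(labels_true, labels_pred) {
  tab <- contingency(labels_true, labels_pred)
  n <- sum(tab)
  h_c <- entropy_counts(rowSums(tab))
  if (h_c == 0) return(1.0)
  # H(C|K) = sum_k p(k) H(C | K = k)
  h_ck <- 0
  for (j in seq_len(ncol(tab))) {
    nk <- sum(tab[, j])
    if (nk > 0) h_ck <- h_ck + nk / n * entropy_counts(tab[, j])
  }
  1 - h_ck / h_c
}

#' Evaluate a clustering against ground truth
#'
#' @inheritParams ari
#' @return list with `ari`, `ami`, `homogeneity`, and the contingency table.
#' @export
clustering_eval <- function(labels_true, labels_pred) {
  list(ari = ari(labels_true, labels_pred),
       ami = ami(labels_true, labels_pred),
       homogeneity = homogeneity(labels_true, labels_pred),
       contingency = contingency(labels_true, labels_pred))
}

#' Spearman rank correlation
#'
#' Both vectors are ranked (average ranks for ties). Without ties the
#' rank-difference formula `rho = 1 - 6 sum(d_i^2) / (n (n^2 - 1))` is
#' applied; with ties, the product-moment correlation of the ranks.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return scalar in [-1, 1]; errors on constant input (undefined).
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("spearman_rho: correlation undefined for constant input", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
  } else {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  }
}

# ---- vocabulary annotation ----------------------------------------------

#' Annotate vocabulary regions with distance to the nearest TSS
#'
#' Distance is 0 when a TSS position lies within the half-open region,
#' otherwise the gap `max(start - pos, pos - end)`. Equidistant TSSs are
#' broken by the first in sorted order. Chromosomes without any TSS get an
#' infinite distance with a warning.
#'
#' @param vocab a `vocabulary`.
#' @param tss TSS records (data.frame with `chrom`, `position`, `gene_id`),
#'   e.g. from [extract_tss()].
#' @return data.frame with `id`, `tss_distance`, `nearest_gene` (vocabulary
#'   order).
#' @export
annotate_tss_distance <- function(vocab, tss) {
  stopifnot(inherits(vocab, "vocabulary"))
  if (is.null(tss) || nrow(tss) == 0L) {
    stop("annotate_tss_distance: empty TSS list", call. = FALSE)
  }
  vdf <- as.data.frame(vocab)
  out_d <- rep(Inf, nrow(vdf))
  out_g <- rep(NA_character_, nrow(vdf))
  tss <- tss[order(tss$chrom, tss$position, method = "radix"), , drop = FALSE]
  missing_chroms <- setdiff(unique(vdf$chrom), unique(tss$chrom))
  if (length(missing_chroms)) {
    warning(sprintf("annotate_tss_distance: no TSS on chromosome(s) %s; distance set to Inf",
                    paste(missing_chroms, collapse = ", ")))
  }
  for (ch in intersect(unique(vdf$chrom), unique(tss$chrom))) {
    vi <- which(vdf$chrom == ch)
    tch <- tss[tss$chrom == ch, , drop = FALSE]
    pos <- tch$position
    for (i in vi) {
      d <- pmax(vdf$start[i] - pos, pos - vdf$end[i], 0)
      best <- which.min(d)  # ties: first in sorted order
      out_d[i] <- d[best]
      out_g[i] <- tch$gene_id[best]
    }
  }
  data.frame(id = vdf$id, tss_distance = out_d, nearest_gene = out_g,
             stringsAsFactors = FALSE)
}

#' Annotate vocabulary regions with cCRE classes
#'
#' Each vocabulary region is labeled by the candidate cis-regulatory element
#' class it overlaps most (by shared bases); ties are broken by a fixed
#' priority (PLS > pELS > dELS > CTCF > DNase-H3K4me3 > others
#' alphabetically). Regions overlapping nothing get `"unclassified"`;
#' unknown class strings are kept verbatim as their own class.
#'
#' @param vocab a `vocabulary`.
#' @param ccre a `region_set` whose 4th column (or a column named `class`)
#'   carries the class label.
#' @return data.frame with `id` and `ccre_class` (vocabulary order).
#' @export
annotate_ccre <- function(vocab, ccre) {
  stopifnot(inherits(vocab, "vocabulary"))
  cls_col <- if ("class" %in% names(ccre)) "class" else
    if ("V4" %in% names(ccre)) "V4" else
      stop("annotate_ccre: cCRE set needs a class column", call. = FALSE)
  vdf <- as.data.frame(vocab)
  cdf <- as.data.frame(ccre)
  priority <- c("PLS", "pELS", "dELS", "CTCF", "DNase-H3K4me3")
  rank_of <- function(cl) {
    r <- match(cl, priority)
    ifelse(is.na(r), length(priority) + 1L, r)
  }
  out <- rep("unclassified", nrow(vdf))
  for (ch in intersect(unique(vdf$chrom), unique(cdf$chrom))) {
    vi <- which(vdf$chrom == ch)
    cc <- cdf[cdf$chrom == ch, , drop = FALSE]
    for (i in vi) {
      ov <- pmin(vdf$end[i], cc$end) - pmax(vdf$start[i], cc$start)
      hit <- which(ov > 0)
      if (!length(hit)) next
      agg <- tapply(ov[hit], cc[[cls_col]][hit], sum)
      cand <- names(agg)[agg == max(agg)]
      out[i] <- cand[order(rank_of(cand), cand)][1L]
    }
  }
  data.frame(id = vdf$id, ccre_class = out, stringsAsFactors = FALSE)
}

#' Combine TSS-distance and cCRE annotations
#'
#' @param vocab a `vocabulary`.
#' @param tss TSS records.
#' @param ccre labeled cCRE `region_set`.
#' @return A `region_annotation` data.frame: `id`, `tss_distance`,
#'   `nearest_gene`, `ccre_class`.
#' @export
annotate_vocabulary <- function(vocab, tss, ccre) {
  a <- annotate_tss_distance(vocab, tss)
  b <- annotate_ccre(vocab, ccre)
  out <- merge(a, b, by = "id", sort = TRUE)
  class(out) <- c("region_annotation", "data.frame")
  out
}

# ---- TSS distribution score and icTSS ------------------------------------

centroid_distances <- function(region_embeddings, annotation,
                               centroid_class = "pELS") {
  stopifnot(nrow(region_embeddings) == nrow(annotation))
  sel <- annotation$ccre_class == centroid_class
  if (!any(sel)) {
    stop(sprintf("no region labeled %s; centroid undefined", centroid_class),
         call. = FALSE)
  }
  centroid <- colMeans(region_embeddings[sel, , drop = FALSE])
  d <- sqrt(rowSums(sweep(region_embeddings, 2L, centroid)^2))
  list(centroid = centroid, d = d)
}

#' TSS distribution score
#'
#' Measures whether the embedding space is organized by promoter proximity:
#' the centroid of the proximal-enhancer-like (pELS) regions is located, each
#' region's Euclidean distance to that centroid is computed, and that
#' distance is correlated with the region's annotated TSS distance
#' (Spearman by default; Pearson available).
#'
#' @param region_embeddings regions x dim matrix, rows aligned with
#'   `annotation`.
#' @param annotation a `region_annotation` (needs `tss_distance` and
#'   `ccre_class`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `tss_score_result`: list with `score`, `method`,
#'   `centroid`, `centroid_distance` (per region).
#' @export
tss_distribution_score <- function(region_embeddings, annotation,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(nrow(region_embeddings) >= 3L)
  cd <- centroid_distances(region_embeddings, annotation)
  finite <- is.finite(annotation$tss_distance)
  x <- annotation$tss_distance[finite]; y <- cd$d[finite]
  score <- if (method == "spearman") spearman_rho(x, y) else
    stats::cor(x, y)
  structure(list(score = score, method = method, centroid = cd$centroid,
                 centroid_distance = cd$d),
            class = "tss_score_result")
}

#' Detect inferred cryptic TSSs (icTSSs)
#'
#' Selects regions annotated as highly distal from any TSS (above the
#' `1 - tss_quantile` empirical quantile of TSS distance) whose embeddings
#' nevertheless sit close to the pELS centroid (below the
#' `centroid_quantile` quantile of centroid distance) — candidate
#' unannotated promoters.
#'
#' @inheritParams tss_distribution_score
#' @param tss_quantile,centroid_quantile quantiles in (0, 1); defaults 0.25.
#' @return An `ictss_result`: list with `ids` (selected vocabulary ids),
#'   `thresholds`, and the per-region `centroid_distance`.
#' @export
detect_ictss <- function(region_embeddings, annotation, tss_quantile = 0.25,
                         centroid_quantile = 0.25) {
  stopifnot(tss_quantile > 0, tss_quantile < 1,
            centroid_quantile > 0, centroid_quantile < 1)
  cd <- centroid_distances(region_embeddings, annotation)
  td <- annotation$tss_distance
  finite_td <- td[is.finite(td)]
  thr_tss <- stats::quantile(finite_td, 1 - tss_quantile, names = FALSE)
  thr_cent <- stats::quantile(cd$d, centroid_quantile, names = FALSE)
  sel <- (td > thr_tss | is.infinite(td)) & cd$d < thr_cent
  structure(list(ids = annotation$id[sel],
                 thresholds = c(tss_distance = thr_tss,
                                centroid_distance = thr_cent),
                 tss_quantile = tss_quantile,
                 centroid_quantile = centroid_quantile,
                 centroid_distance = cd$d),
            class = "ictss_result")
}

# ---- empirical enrichment ------------------------------------------------

# length-weighted mean signal over each vocabulary region (0 where uncovered)
region_mean_signal <- function(vocab, signal) {
  vdf <- as.data.frame(vocab)
  sdf <- as.data.frame(signal)
  out <- numeric(nrow(vdf))
  for (ch in intersect(unique(vdf$chrom), unique(sdf$chrom))) {
    vi <- which(vdf$chrom == ch)
    sc <- sdf[sdf$chrom == ch, , drop = FALSE]
    for (i in vi) {
      ov <- pmin(vdf$end[i], sc$end) - pmax(vdf$start[i], sc$start)
      hit <- ov > 0
      if (any(hit)) {
        out[i] <- sum(ov[hit] * sc$value[hit]) / (vdf$end[i] - vdf$start[i])
      }
    }
  }
  out
}

#' Empirical enrichment test against a vocabulary-sampled null
#'
#' The observed statistic is the mean, over the target regions, of each
#' region's length-weighted mean signal (uncovered bases count as 0). The
#' null is built by drawing `n_reps` region sets of the same size uniformly
#' without replacement from the vocabulary and recomputing the statistic.
#' Fold enrichment is observed / mean(null); the empirical p-value uses the
#' plus-one convention `p = (1 + #\{null >= observed\}) / (1 + n_reps)` by
#' default (so the smallest attainable p is `1 / (n_reps + 1)`), or the
#' uncorrected `#\{null >= observed\} / n_reps` when `plus_one = FALSE`.
#'
#' @param target_ids 0-based vocabulary ids of the target set (non-empty).
#' @param vocab a `vocabulary`.
#' @param signal a `signal_track`.
#' @param n_reps number of null draws (>= 1); 500 is the conventional default.
#' @param seed RNG seed: null draw r is the r-th `sample.int(V, m)` after
#'   seeding, making the null reproducible.
#' @param plus_one use the plus-one small-sample correction (default TRUE).
#' @return An `enrichment_result`: list with `observed`, `null` (length
#'   n_reps), `fold`, `p_value`.
#' @export
enrichment_test <- function(target_ids, vocab, signal, n_reps = 500L,
                            seed = 0L, plus_one = TRUE) {
  stopifnot(length(target_ids) >= 1L, n_reps >= 1L)
  V <- vocab_size(vocab)
  m <- length(target_ids)
  if (m > V) stop(sprintf("enrichment_test: %d target(s) but vocabulary has %d",
                          m, V), call. = FALSE)
  if (any(target_ids < 0L | target_ids >= V)) {
    stop("enrichment_test: target id out of range [0, V)", call. = FALSE)
  }
  rms <- region_mean_signal(vocab, signal)
  observed <- mean(rms[target_ids + 1L])
  null <- with_local_seed(seed, {
    vapply(seq_len(n_reps), function(r) mean(rms[sample.int(V, m)]), numeric(1))
  })
  p <- if (plus_one) (1 + sum(null >= observed)) / (1 + n_reps) else
    sum(null >= observed) / n_reps
  structure(list(observed = observed, null = null,
                 fold = observed / mean(null), p_value = p,
                 n_reps = as.integer(n_reps), plus_one = plus_one),
            class = "enrichment_result")
}

#' Cross-modal nearest-neighbor label transfer
#'
#' For each query embedding, finds the k nearest reference embeddings by
#' Euclidean distance and returns the majority reference label. Distance
#' ties and majority ties are broken deterministically: neighbors are
#' ordered by (distance, reference index), and among tied majority labels
#' the one reached first in that ordering wins.
#'
#' @param query_embeddings queries x dim matrix.
#' @param reference_embeddings references x dim matrix (same dim).
#' @param reference_labels label per reference row.
#' @param k neighbors to consult (`1 <= k <=` reference count).
#' @return character vector of predicted labels, one per query.
#' @export
cross_modal_neighbors <- function(query_embeddings, reference_embeddings,
                                  reference_labels, k = 5L) {
  Q <- as.matrix(query_embeddings); R <- as.matrix(reference_embeddings)
  stopifnot(ncol(Q) == ncol(R), nrow(R) == length(reference_labels))
  if (k <= 0L || k > nrow(R)) {
    stop(sprintf("cross_modal_neighbors: k=%d out of range [1, %d]", k, nrow(R)),
         call. = FALSE)
  }
  reference_labels <- as.character(reference_labels)
  vapply(seq_len(nrow(Q)), function(i) {
    d <- sqrt(rowSums(sweep(R, 2L, Q[i, ])^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    labs <- reference_labels[ord]
    cnt <- table(labs)
    winners <- names(cnt)[cnt == max(cnt)]
    labs[labs %in% winners][1L]
  }, character(1))
}
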