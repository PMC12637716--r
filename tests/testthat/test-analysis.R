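test_that("clustering metrics equal brute-force definitional oracles on enumerated partitions", {
  # all pairs of set partitions of n = 4, chance terms by enumerating every
  # permutation of the predicted labels
  parts4 <- all_partitions(4L)
  perms4 <- all_perms(4L)
  for (lt in parts4) {
    for (lp in parts4) {
      expect_equal(ari(lt, lp), oracle_ari(lt, lp, perms4), tolerance = 1e-12)
      expect_equal(ami(lt, lp), oracle_ami(lt, lp, perms4), tolerance = 1e-12)
      expect_equal(homogeneity(lt, lp), oracle_homogeneity(lt, lp),
                   tolerance = 1e-12)
    }
  }
  # spot-checked random label pairs at n = 6
  set.seed(61)
  perms6 <- all_perms(6L)
  for (trial in 1:10) {
    lt <- sample(1:3, 6L, replace = TRUE)
    lp <- sample(1:3, 6L, replace = TRUE)
    expect_equal(ari(lt, lp), oracle_ari(lt, lp, perms6), tolerance = 1e-12)
    expect_equal(ami(lt, lp), oracle_ami(lt, lp, perms6), tolerance = 1e-12)
    expect_equal(homogeneity(lt, lp), oracle_homogeneity(lt, lp),
                 tolerance = 1e-12)
  }
})

test_that("clustering metrics have their identity, renaming, and degenerate values", {
  l <- c(1, 1, 2, 2, 3)
  expect_equal(ari(l, l), 1.0)
  expect_equal(ami(l, l), 1.0)
  expect_equal(homogeneity(l, l), 1.0)
  renamed <- c("1" = "b", "2" = "c", "3" = "a")[as.character(l)]
  expect_equal(ari(l, renamed), 1.0)
  expect_equal(ami(l, renamed), 1.0)
  # single-cluster prediction vs multi-class truth: H(C|K) = H(C)
  expect_equal(homogeneity(c(1, 1, 2, 2), rep(1, 4)), 0.0)
  # hand contingency [[2,0],[0,2]] on n = 4 evaluates to 1 by the formula
  expect_equal(ari(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1.0)
  expect_error(ari(1:3, 1:4), "length")
  # ARI of random labelings is centered at zero
  set.seed(62)
  vals <- vapply(1:200, function(i)
    ari(sample(1:4, 1000, TRUE), sample(1:4, 1000, TRUE)), numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("spearman matches the printed formula, its oracle, and stats::cor", {
  expect_equal(spearman_rho(1:10, 1:10), 1.0)
  expect_equal(spearman_rho(1:10, 10:1), -1.0)
  # worked example: d = (0, -1, 1, 0) -> 1 - 6*2 / (4*15) = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8,
               tolerance = 1e-12)
  set.seed(63)
  for (trial in 1:10) {
    x <- sample(1:8, 12L, replace = TRUE)  # ties present
    y <- rnorm(12L)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("seeded k-means recovers separated clouds and is deterministic", {
  set.seed(64)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 8), 50))
  lab <- kmeans_cluster(X, 2L, seed = 3)
  expect_equal(ari(rep(1:2, each = 50), lab), 1.0)
  expect_identical(lab, kmeans_cluster(X, 2L, seed = 3))
  expect_equal(kmeans_cluster(X, 1L, seed = 3), rep(0L, 100))
  expect_error(kmeans_cluster(X, 200L, seed = 1), "out of range")
})

test_that("TSS distance annotation follows containment, gap, and tie rules", {
  vocab <- validate_vocabulary(region_set(rep("chr1", 3),
                                          c(100L, 400L, 800L),
                                          c(200L, 500L, 900L)))
  tss <- tss_records(c("chr1", "chr1"), c(150L, 250L), c("+", "+"),
                     c("gA", "gB"))
  ann <- annotate_tss_distance(vocab, tss)
  expect_equal(ann$tss_distance[1L], 0)          # containment
  expect_equal(ann$tss_distance[2L], 150)        # gap: 400 - 250
  expect_equal(ann$nearest_gene[2L], "gB")
  # equidistant TSSs resolve to the first in sorted order
  vocab2 <- validate_vocabulary(region_set("chr1", 140L, 160L))
  tss2 <- tss_records(c("chr1", "chr1"), c(50L, 250L), c("+", "-"),
                      c("left", "right"))
  ann2 <- annotate_tss_distance(vocab2, tss2)
  expect_equal(ann2$tss_distance, 90)
  expect_equal(ann2$nearest_gene, "left")
  # spec example: region (100,200), TSS at 250 -> distance 50
  ann3 <- annotate_tss_distance(validate_vocabulary(region_set("chr1", 100L, 200L)),
                                tss_records("chr1", 250L, "+", "g"))
  expect_equal(ann3$tss_distance, 50)
  expect_error(annotate_tss_distance(vocab, tss[0, ]), "empty")
  expect_warning(
    annotate_tss_distance(validate_vocabulary(region_set("chrX", 0L, 10L)),
                          tss),
    "no TSS")
})

test_that("cCRE annotation picks the largest overlap with fixed tie priority", {
  vocab <- validate_vocabulary(region_set("chr1", 100L, 200L))
  ccre <- as_region_set(data.frame(
    chrom = "chr1", start = c(90L, 140L), end = c(140L, 260L),
    class = c("pELS", "dELS")))
  # overlaps: pELS 40 bases, dELS 60 bases -> dELS wins
  expect_equal(annotate_ccre(vocab, ccre)$ccre_class, "dELS")
  # exact tie -> priority order (pELS beats dELS)
  ccre2 <- as_region_set(data.frame(
    chrom = "chr1", start = c(100L, 150L), end = c(150L, 200L),
    class = c("dELS", "pELS")))
  expect_equal(annotate_ccre(vocab, ccre2)$ccre_class, "pELS")
  # no overlap -> unclassified; unknown class kept verbatim
  far <- as_region_set(data.frame(chrom = "chr1", start = 900L, end = 950L,
                                  class = "mystery"))
  expect_equal(annotate_ccre(vocab, far)$ccre_class, "unclassified")
  near <- as_region_set(data.frame(chrom = "chr1", start = 100L, end = 200L,
                                   class = "mystery"))
  expect_equal(annotate_ccre(vocab, near)$ccre_class, "mystery")
})

test_that("TSS distribution score is 1 for a monotone construction and matches hand arithmetic", {
  ann <- data.frame(id = 0:4, tss_distance = c(10, 100, 1000, 5000, 20000),
                    nearest_gene = NA, ccre_class = c("pELS", "dELS", "dELS",
                                                      "dELS", "dELS"))
  # embeddings on a line: distance to the pELS centroid increases with
  # tss_distance
  emb <- matrix(c(0, 0.4, 2, 5, 9), ncol = 1)
  res <- tss_distribution_score(emb, ann)
  expect_equal(res$score, 1.0)
  # hand computation: centroid = the single pELS point; distances |x - 0|
  d_hand <- abs(emb[, 1])
  expect_equal(res$centroid_distance, d_hand, tolerance = 1e-12)
  expect_equal(tss_distribution_score(emb, ann, method = "pearson")$score,
               cor(ann$tss_distance, d_hand), tolerance = 1e-12)
  expect_error(tss_distribution_score(emb, transform(ann, ccre_class = "dELS")),
               "pELS")
})

test_that("icTSS detection is monotone in its quantiles and empty for proximal-only data", {
  set.seed(65)
  n <- 100L
  ann <- data.frame(id = 0:(n - 1L),
                    tss_distance = c(runif(50, 0, 100), runif(50, 5000, 50000)),
                    ccre_class = rep(c("pELS", "dELS"), each = 50))
  emb <- matrix(rnorm(n * 4), n, 4)
  r1 <- detect_ictss(emb, ann, 0.1, 0.1)
  expect_lte(length(r1$ids), 10L)
  r2 <- detect_ictss(emb, ann, 0.3, 0.3)
  expect_true(all(r1$ids %in% r2$ids))
  # all regions promoter-proximal: no region is simultaneously distal
  ann_prox <- transform(ann, tss_distance = runif(n, 0, 50))
  ann_prox$ccre_class <- rep(c("pELS", "dELS"), each = 50)
  r3 <- detect_ictss(emb, ann_prox, 0.25, 0.25)
  expect_true(length(r3$ids) <= sum(ann_prox$tss_distance >
                                      r3$thresholds["tss_distance"]))
})

test_that("enrichment testing matches a seeded brute-force re-simulation", {
  gv <- generate_vocabulary(genome_length = 2e4, V = 10L, min_len = 100L,
                            max_len = 200L, seed = 66)
  vdf <- as.data.frame(gv$vocab)
  # signal over a few regions
  sig <- as_region_set(data.frame(chrom = vdf$chrom[c(2, 5, 6)],
                                  start = vdf$start[c(2, 5, 6)] - 10L,
                                  end = vdf$end[c(2, 5, 6)] + 10L,
                                  value = c(4, 2, 8)))
  class(sig) <- c("signal_track", class(sig))
  targets <- c(1L, 4L, 5L)  # 0-based ids of rows 2, 5, 6
  res <- enrichment_test(targets, gv$vocab, sig, n_reps = 100L, seed = 7)
  # independent per-base signal means
  base_mean <- vapply(seq_len(nrow(vdf)), function(i) {
    bases <- (vdf$start[i] + 1L):vdf$end[i]
    val <- numeric(length(bases))
    for (j in seq_len(nrow(sig))) {
      inside <- bases > sig$start[j] & bases <= sig$end[j]
      val[inside] <- val[inside] + sig$value[j]
    }
    mean(val)
  }, numeric(1))
  expect_equal(res$observed, mean(base_mean[targets + 1L]), tolerance = 1e-12)
  # brute-force null with the same seeded draw sequence
  set.seed(7)
  null2 <- vapply(1:100, function(r) mean(base_mean[sample.int(10L, 3L)]),
                  numeric(1))
  expect_equal(res$null, null2, tolerance = 1e-12)
  expect_equal(res$fold, res$observed / mean(null2), tolerance = 1e-12)
  expect_equal(res$p_value, (1 + sum(null2 >= res$observed)) / 101,
               tolerance = 1e-12)
})

test_that("enrichment extremes behave as expected", {
  gv <- generate_vocabulary(genome_length = 2e5, V = 100L, seed = 67)
  vdf <- as.data.frame(gv$vocab)
  uniform <- as_region_set(data.frame(chrom = "chrS", start = 0L,
                                      end = 200000L, value = 3))
  class(uniform) <- c("signal_track", class(uniform))
  res_u <- enrichment_test(0:4, gv$vocab, uniform, n_reps = 50L, seed = 1)
  expect_equal(res_u$fold, 1.0, tolerance = 1e-12)
  expect_gt(res_u$p_value, 0.9)
  # signal exclusively on targets: maximal fold, minimal plus-one p
  tgt <- as_region_set(data.frame(chrom = vdf$chrom[1:5],
                                  start = vdf$start[1:5],
                                  end = vdf$end[1:5], value = 10))
  class(tgt) <- c("signal_track", class(tgt))
  res_t <- enrichment_test(0:4, gv$vocab, tgt, n_reps = 50L, seed = 1)
  expect_gt(res_t$fold, 1)
  expect_equal(res_t$p_value, 1 / 51, tolerance = 1e-12)
  expect_equal(enrichment_test(0:4, gv$vocab, tgt, n_reps = 50L, seed = 1,
                               plus_one = FALSE)$p_value, 0)
  expect_error(enrichment_test(0:100, gv$vocab, tgt), "target")
})

test_that("cross-modal neighbor transfer matches an exhaustive sort", {
  set.seed(68)
  R <- matrix(rnorm(40), 20, 2)
  labs <- sample(c("x", "y", "z"), 20, replace = TRUE)
  Q <- matrix(rnorm(10), 5, 2)
  got <- cross_modal_neighbors(Q, R, labs, k = 5L)
  for (i in 1:5) {
    d <- sqrt(colSums((t(R) - Q[i, ])^2))
    nb <- labs[order(d, seq_along(d))[1:5]]
    cnt <- table(nb)
    winners <- names(cnt)[cnt == max(cnt)]
    expect_equal(got[i], nb[nb %in% winners][1L])
  }
  # query equal to a reference point, k = 1 -> that reference's label
  expect_equal(cross_modal_neighbors(R[7, , drop = FALSE], R, labs, 1L),
               labs[7])
  # k = reference size -> global majority
  expect_equal(cross_modal_neighbors(Q[1, , drop = FALSE], R, labs, 20L),
               names(which.max(table(labs))))
  expect_error(cross_modal_neighbors(Q, R, labs, 0L), "k=0")
})
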