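test_that("vocabulary generation is valid, reproducible, and class-coherent", {
  gv <- generate_vocabulary(genome_length = 1e6, V = 100L, seed = 71)
  expect_equal(vocab_size(gv$vocab), 100L)
  expect_s3_class(gv$vocab, "vocabulary")  # implies sorted, non-overlapping
  gv2 <- generate_vocabulary(genome_length = 1e6, V = 100L, seed = 71)
  expect_identical(as.data.frame(gv$vocab), as.data.frame(gv2$vocab))
  expect_identical(gv$tss, gv2$tss)
  # classes are derived from realized TSS distances
  expect_true(all(gv$annotation$ccre_class[gv$annotation$tss_distance == 0] ==
                    "PLS"))
  within <- gv$annotation$tss_distance > 0 & gv$annotation$tss_distance <= 200
  expect_true(all(gv$annotation$ccre_class[within] == "pELS"))
  expect_true(all(gv$annotation$ccre_class[gv$annotation$tss_distance > 200] ==
                    "dELS"))
  expect_error(generate_vocabulary(genome_length = 1e3, V = 100L),
               "packing")
})

test_that("cell generation honors opening probabilities and marker structure", {
  gv <- generate_vocabulary(genome_length = 1e6, V = 400L, seed = 72)
  # deterministic extreme: markers always open, background never
  cfg1 <- synthetic_atlas_config(n_cell_types = 2L, markers_per_type = 30L,
                                 marker_open_prob = 1, background_open_prob = 0,
                                 cells_per_type = 3L, seed = 72)
  g1 <- generate_cells(gv$vocab, cfg1)
  for (i in seq_along(g1$cells)) {
    t <- as.integer(sub("type", "", g1$truth$labels[i]))
    expect_identical(g1$cells[[i]]$tokens, g1$truth$marker_ids[[t]])
  }
  # binomial expectation of tokens per cell, +/- 3 SD over 500 cells
  cfg2 <- synthetic_atlas_config(n_cell_types = 1L, markers_per_type = 50L,
                                 marker_open_prob = 0.8,
                                 background_open_prob = 0.05,
                                 cells_per_type = 500L, seed = 73)
  g2 <- generate_cells(gv$vocab, cfg2)
  nb <- 400L - 50L
  mu <- 50 * 0.8 + nb * 0.05
  sd_cell <- sqrt(50 * 0.8 * 0.2 + nb * 0.05 * 0.95)
  mean_tokens <- mean(lengths(lapply(g2$cells, `[[`, "tokens")))
  expect_lt(abs(mean_tokens - mu), 3 * sd_cell / sqrt(500))
  # reproducibility
  g2b <- generate_cells(gv$vocab, cfg2)
  expect_identical(lapply(g2$cells, `[[`, "tokens"),
                   lapply(g2b$cells, `[[`, "tokens"))
})

test_that("emitted fragments tokenize back to exactly the sampled open sets", {
  gv <- generate_vocabulary(genome_length = 5e5, V = 200L, seed = 74)
  cfg <- synthetic_atlas_config(n_cell_types = 3L, markers_per_type = 30L,
                                cells_per_type = 10L, seed = 74)
  toks <- generate_cells(gv$vocab, cfg, emit = "tokens")
  frs <- generate_cells(gv$vocab, cfg, emit = "fragments")
  back <- tokenize_fragment_store(frs$cells, gv$vocab)
  for (id in names(toks$cells)) {
    expect_identical(back[[id]]$tokens, toks$cells[[id]]$tokens)
  }
})

test_that("raw token-count profiles of a separated atlas are cluster-recoverable", {
  at <- small_atlas()
  V <- 500L
  M <- t(vapply(at$cells, function(ts) {
    v <- numeric(V); v[ts$tokens + 1L] <- 1; v
  }, numeric(V)))
  lab <- kmeans_cluster(M, 5L, seed = 75)
  expect_gte(ari(at$truth$labels, lab), 0.9)
})

test_that("paired multiome generation has type-structured RNA with seeded noise", {
  gv <- generate_vocabulary(genome_length = 5e5, V = 200L, seed = 76)
  cfg <- synthetic_atlas_config(n_cell_types = 3L, markers_per_type = 30L,
                                cells_per_type = 20L, seed = 76)
  pm0 <- generate_paired_multiome(gv$vocab, cfg, noise_sd = 0)
  labels <- vapply(pm0$cells, function(p) p$label, "")
  # zero noise: profiles constant within type
  for (t in unique(labels)) {
    R <- do.call(rbind, lapply(pm0$cells[labels == t], `[[`, "rna"))
    expect_equal(max(apply(R, 2, function(col) diff(range(col)))), 0)
  }
  # marker genes highest in their own type (true means)
  for (t in 1:3) {
    for (g in pm0$truth$gene_markers[[t]]) {
      expect_equal(which.max(pm0$truth$type_means[, g]), t)
    }
  }
  pm1 <- generate_paired_multiome(gv$vocab, cfg, seed = 99)
  pm2 <- generate_paired_multiome(gv$vocab, cfg, seed = 99)
  expect_identical(lapply(pm1$cells, `[[`, "rna"),
                   lapply(pm2$cells, `[[`, "rna"))
})

test_that("icTSS planting marks distal regions and emits a matching signal track", {
  gv <- generate_vocabulary(genome_length = 1e6, V = 300L, seed = 77)
  pl <- plant_ictss(gv$vocab, gv$annotation, n_plant = 8L, signal_value = 12,
                    seed = 77)
  expect_length(pl$planted_ids, 8L)
  ann <- pl$annotation
  expect_true(all(ann$ccre_class[ann$planted] == "dELS"))
  # planted regions are drawn from the most distal pool
  expect_gt(min(ann$tss_distance[ann$planted]),
            quantile(ann$tss_distance, 0.75))
  # planted regions carry the signal value
  sig <- pl$signal
  vdf <- as.data.frame(gv$vocab)
  for (id in pl$planted_ids) {
    row <- which(sig$start == vdf$start[id + 1L])
    expect_equal(sig$value[row], 12)
  }
  en <- enrichment_test(pl$planted_ids, gv$vocab, pl$signal, n_reps = 30L,
                        seed = 1)
  expect_gt(en$fold, 1)
  expect_error(plant_ictss(gv$vocab, gv$annotation, n_plant = 1000L), "distal")
})
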