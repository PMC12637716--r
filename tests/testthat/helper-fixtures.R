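# Shared desk-scale fixtures, built lazily and cached for the test run so
# expensive trained models are constructed once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

tiny_model_cfg <- function(V = 50L) {
  model_config(vocab_size = V, d_model = 16L, n_layers = 2L, n_heads = 2L,
               ffn_dim = 32L)
}

# small atlas + pretrained model shared across model-level tests
small_atlas <- function() fixture("small_atlas", function() {
  gv <- generate_vocabulary(genome_length = 1e6, V = 500L, seed = 2)
  cfg <- synthetic_atlas_config(n_cell_types = 5L, markers_per_type = 40L,
                                cells_per_type = 60L, seed = 2)
  gc <- generate_cells(gv$vocab, cfg)
  list(gv = gv, cfg = cfg, cells = gc$cells, truth = gc$truth)
})

small_base_model <- function() fixture("small_base_model", function() {
  at <- small_atlas()
  m0 <- init_model(model_config(vocab_size = 500L, d_model = 32L,
                                n_layers = 2L, n_heads = 2L, ffn_dim = 64L),
                   seed = 2)
  hold <- with_seed_sample(42, length(at$cells), 60L)
  train <- setdiff(seq_along(at$cells), hold)
  fit <- pretrain(m0, at$cells[train], pretrain_config(epochs = 3L, seed = 2))
  list(model = fit$model, history = fit$history, hold = hold, train = train)
})

with_seed_sample <- function(seed, n, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(n, k)
}

# paired multiome corpus + trained dual encoder, shared by the alignment and
# imputation tests
small_multiome <- function() fixture("small_multiome", function() {
  at <- small_atlas()
  pm <- generate_paired_multiome(at$gv$vocab, at$cfg)
  pm
})

# desk-preset atlas and pretraining run shared by the learnability and
# shuffled-score-control tests
desk_pretrain <- function() fixture("desk_pretrain", function() {
  gv <- generate_vocabulary(genome_length = 2e6, V = 2000L, seed = 1)
  cfg <- synthetic_atlas_config(n_cell_types = 5L, markers_per_type = 100L,
                                cells_per_type = 200L, seed = 1)
  gc <- generate_cells(gv$vocab, cfg)
  model <- init_model(model_config(vocab_size = 2000L, d_model = 64L,
                                   n_layers = 4L, n_heads = 4L,
                                   max_context = 256L), seed = 1)
  fit <- pretrain(model, gc$cells,
                  pretrain_config(epochs = 3L, batch_size = 32L, seed = 1))
  list(fit = fit, gv = gv, cells = gc$cells, truth = gc$truth)
})

small_dual_fit <- function() fixture("small_dual_fit", function() {
  pm <- small_multiome()
  m0 <- init_model(model_config(vocab_size = 500L, d_model = 32L,
                                n_layers = 2L, n_heads = 2L, ffn_dim = 64L),
                   seed = 3)
  enc <- rna_encoder(length(pm$cells[[1L]]$rna), out_dim = 32L, seed = 3)
  train_dual_encoder(m0, enc, pm$cells,
                     craft_config(epochs = 15L, lr = 1e-3, seed = 3))
})
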