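# Scaled-down training study shared by the acceptance tests: 16 synthetic
# 64 x 64 pairs with smooth deformations of <= 5 px and mild acquisition
# degradations, a depth-2 / base-8 model, batch 4. Trained once per test run
# and cached, since several acceptance properties are read off the same run.

acceptance_conditions <- list(
  n_pairs = 16L, size = 64L, amplitude = 5, smoothness = 8,
  n_trees = 2L, branch_depth = 3L, vessel_width = c(1.2, 2.6),
  epochs = 400L, batch_size = 4L, learning_rate = 1e-4,
  suite_seed = 11L, model_seed = 1L, train_seed = 1L
)

.acceptance_env <- new.env(parent = emptyenv())

acceptance_pairs <- function() {
  if (!is.null(.acceptance_env$pairs)) return(.acceptance_env$pairs)
  cond <- acceptance_conditions
  suite <- synth_suite(cond$n_pairs, size = cond$size,
                       amplitude = cond$amplitude,
                       smoothness = cond$smoothness,
                       n_trees = cond$n_trees,
                       branch_depth = cond$branch_depth,
                       vessel_width = cond$vessel_width,
                       seed = cond$suite_seed)
  pairs <- lapply(suite$pairs, function(p) list(
    ref = segment_vessels(p$i_ref), mov = segment_vessels(p$i_mov)))
  .acceptance_env$pairs <- pairs
  pairs
}

acceptance_run <- function() {
  if (!is.null(.acceptance_env$run)) return(.acceptance_env$run)
  cond <- acceptance_conditions
  pairs <- acceptance_pairs()
  model <- build_model(net_config(input_size = cond$size, depth = 2,
                                  base_filters = 8),
                       seed = cond$model_seed)
  model <- train_model(model, pairs,
                       train_config(epochs = cond$epochs,
                                    batch_size = cond$batch_size,
                                    learning_rate = cond$learning_rate,
                                    seed = cond$train_seed))
  warps <- lapply(pairs, function(p) {
    disp <- forward_grid(model, p$ref, p$mov)
    warp_displacement(p$mov, disp)
  })
  .acceptance_env$run <- list(model = model, pairs = pairs, warps = warps)
  .acceptance_env$run
}
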