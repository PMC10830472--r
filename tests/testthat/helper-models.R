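# Desk-scale study artifacts shared across acceptance tests: the
# ground-truth datasets and trained model variants. Built lazily, once per
# test run, under fixed seeds. Problem sizes (2000 training pairs over 200
# scenes, 64 px patches, a few thousand AdamW steps, desk-strength
# augmentation) are the package's desk-scale study conditions described in
# the methods vignette.

desk_training_split <- function() {
  cache_get("desk_split", function() {
    plan <- sampling_plan(200, 10, wd_range = 20, stig_range = 5,
                          image_shape = c(128, 128), blank_frac = 0.1)
    ds <- generate_ground_truth(plan, default_optics(), seed = 101)
    split_dataset(ds, fraction = 0.8, seed = 101)
  })
}

desk_blank_split <- function() {
  cache_get("desk_blank_split", function() {
    plan <- sampling_plan(80, 10, wd_range = 20, stig_range = 5,
                          image_shape = c(128, 128), blank_frac = 0.3)
    ds <- generate_ground_truth(plan, default_optics(), seed = 202)
    split_dataset(ds, fraction = 0.8, seed = 202)
  })
}

desk_train_cfg <- function(..., batch_size = 8) {
  train_config(lr = 1e-3, decay_factor = 0.99, decay_interval = 2000,
               batch_size = batch_size, patch_side = 64, eval_every = 500,
               ...)
}

desk_plain_model <- function() {
  cache_get("desk_plain_model", function() {
    train_model("plain", desk_training_split(),
                desk_train_cfg(max_steps = 3500),
                aug_cfg = desk_augment_config(), seed = 7)$model
  })
}

# The patch-score variant shares the plain variant's encoder design, so at
# desk scale it is initialized from the trained plain encoder and the score
# head plus interactions are learned on the blank-region dataset.
desk_patch_score_model <- function() {
  cache_get("desk_patch_score_model", function() {
    plain <- desk_plain_model()
    ps <- build_correction_model(desk_conv_spec(), 64, outputs = 4,
                                 seed = 11)
    for (i in seq_along(ps$layers)) {
      if (ps$layers[[i]]$type == "conv_block") {
        ps$layers[[i]]$params <- plain$layers[[i]]$params
        ps$layers[[i]]$rm <- plain$layers[[i]]$rm
        ps$layers[[i]]$rv <- plain$layers[[i]]$rv
      }
    }
    train_model("patch-score", desk_blank_split(),
                desk_train_cfg(max_steps = 700, batch_size = 4,
                               patches_per_sample = 5),
                aug_cfg = desk_augment_config(), seed = 7,
                model = ps)$model
  })
}

desk_deepscore_model <- function() {
  cache_get("desk_deepscore_model", function() {
    train_model("deepscore", desk_training_split(),
                desk_train_cfg(max_steps = 3000),
                aug_cfg = desk_augment_config(), seed = 7)$model
  })
}
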