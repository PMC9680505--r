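# Shared fixtures, trained at most once per test run. The heavy models
# (stage-1 network, 3-class student) take a few minutes each; every test
# that needs them goes through these memoised accessors.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

fixture_params <- function() scene_params(size = 64)

# 64 training scenes / 16 held-out scenes at the study scale
fixture_train_scenes <- function() memo("train_scenes", {
  lapply(1:64, function(i) generate_scene(fixture_params(), seed = 100 + i))
})

fixture_test_scenes <- function() memo("test_scenes", {
  lapply(1:16, function(i) generate_scene(fixture_params(), seed = 900 + i))
})

fixture_stage1 <- function() memo("stage1", {
  scenes <- fixture_train_scenes()
  train_stage1(lapply(scenes, `[[`, "image"),
               lapply(scenes, function(s) (s$mask > 0) * 1L),
               seg_config(classes = 2, patch = 64, epochs = 30, batch = 8,
                          seed = 1))
})

fixture_svm <- function() memo("svm", {
  px <- generate_pixel_dataset(300, fixture_params(), seed = 5,
                               subset = default_feature_subset())
  train_svm(px$features, px$labels)
})

fixture_segveg <- function() memo("segveg", {
  segveg(fixture_stage1(), fixture_svm())
})

fixture_unet3c <- function() memo("unet3c", {
  scenes <- fixture_train_scenes()
  pm <- generate_pseudo_masks(fixture_segveg(), lapply(scenes, `[[`, "image"))
  train_unet3c(pm$images, pm$masks,
               seg_config(classes = 3, patch = 64, epochs = 30, batch = 8,
                          seed = 2))
})

# small fast scenes for shape/determinism checks
tiny_scenes <- function(n, size = 32, seed0 = 0) {
  lapply(seq_len(n), function(i) generate_scene(scene_params(size = size),
                                                seed = seed0 + i))
}

binary_masks <- function(scenes) lapply(scenes, function(s) (s$mask > 0) * 1L)
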