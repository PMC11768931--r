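# Desk-scale end-to-end comparison runs (tiny clips, few epochs).

make_split_manifest <- function() {
  man <- synth_manifest(counts = c(roar = 5, rumble = 7, trumpet = 5),
                        duration_s = 0.256, sr = 8000, seed = 2)
  stratified_split(man, seed = 1)
}

test_that("the comparison grid yields one row per combination, reproducibly", {
  man <- make_split_manifest()
  run <- function(dir) {
    run_comparison(man, models = c("yamnet_1d", "rawnet_residual"),
                   pipelines = "raw", regimes = c("none", "approach1"),
                   seeds = 1L, epochs = 2, out_dir = dir)
  }
  tab <- run(withr::local_tempdir())
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$regime, c("none", "approach1"))
  tab2 <- run(withr::local_tempdir())
  attr(tab, "manifests") <- attr(tab2, "manifests") <- NULL
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("approach-1 runs log balanced training manifests", {
  man <- make_split_manifest()
  tab <- run_comparison(man, models = "yamnet_1d", pipelines = "raw",
                        regimes = c("none", "approach1"), seeds = 1L,
                        epochs = 1, out_dir = withr::local_tempdir())
  mans <- attr(tab, "manifests")
  none_train <- mans[["raw_yamnet_1d_none_s1"]]
  a1_train <- mans[["raw_yamnet_1d_approach1_s1"]]
  base <- table(none_train$label[none_train$split == "train"])
  bal <- table(a1_train$label[a1_train$split == "train"])
  target <- ceiling(max(base) / 10) * 10
  expect_true(all(bal == target))
  expect_false(all(base == target))
  expect_equal(tab$n_train[tab$regime == "approach1"], sum(bal))
  # no test clip is ever augmented or duplicated
  for (m in mans) {
    expect_true(all(m$provenance[m$split == "test"] == "original"))
    expect_equal(sum(m$split == "test"), sum(man$split == "test"))
  }
})

test_that("the spectrogram pipeline trains on feature images and SVMs", {
  man <- synth_manifest(counts = c(roar = 5, rumble = 6, trumpet = 5),
                        duration_s = 1, sr = 8000, seed = 5)
  man <- stratified_split(man, seed = 2)
  tab <- run_comparison(man, models = c("feature_cnn", "svm"),
                        pipelines = "spectrogram", regimes = "none",
                        seeds = 1L, epochs = 2,
                        out_dir = withr::local_tempdir())
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(is.na(tab$parameter_count[tab$model == "svm"]))
  expect_gt(tab$parameter_count[tab$model == "feature_cnn"], 0)
})

test_that("unknown models and pipelines are rejected", {
  man <- make_split_manifest()
  expect_error(run_comparison(man, models = "resnet99"),
               class = "tembo_validation_error")
  expect_error(run_comparison(man, models = "svm", pipelines = "video"),
               class = "tembo_validation_error")
})
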