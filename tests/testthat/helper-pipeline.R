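# Full study-condition pipeline: 10 classes x 10 samples at 48x48, split
# 9 train / 1 test per class, reference architecture (Tmax 15, 16@5x5 then
# 20@2x2, 2 + 20 epochs), one-vs-rest linear SVM with C = 2.4.
study_conditions_run <- function(seed = 1) {
  data <- split_dataset(generate_synthetic_dataset(synthetic_spec(seed = seed)), 9)
  run_recognition_pipeline(data, atsnn_config(seed = seed), C = 2.4)
}

# memoized first run so the determinism check performs exactly one repeat
.pipeline_cache <- new.env(parent = emptyenv())

cached_study_run <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- study_conditions_run(seed)
  }
  .pipeline_cache[[key]]
}
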