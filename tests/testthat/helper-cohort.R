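# Full-size synthetic cohort under the default calibrated configuration,
# generated once and shared by the end-to-end recovery tests. Each patient's
# masks are pushed through classify_voxels so the classification stage is
# exercised, not bypassed.

acceptance_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 71)
      tabs <- lapply(seq_len(71), function(i) {
        b <- generate_patient(cfg, i)
        classify_voxels(b$adc, b$pre, b$post, b$haemorrhage,
                        patient_id = sprintf("p%03d", i))
      })
      cache <<- list(config = cfg, pooled = pool_voxel_tables(tabs))
    }
    cache
  }
})
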