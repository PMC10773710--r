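# Small synthetic campaigns shared across test files.

# one-stage campaign with configurable size/noise; returns everything a
# downstream test needs
make_campaign <- function(seed = 1L, stage = "R1", varieties = 10L,
                          reps = 1L, spad_noise_sd = 1.5,
                          reflectance_noise_sd = 0.02) {
  cfg <- campaign_config(
    varieties = varieties, reps = reps, stages = stage,
    spad_noise_sd = spad_noise_sd,
    reflectance_noise_sd = reflectance_noise_sd, seed = seed
  )
  truth <- ground_truth()
  profiles <- generate_profiles(cfg, truth)
  reflectance <- generate_reflectance(profiles, truth, cfg)
  list(cfg = cfg, truth = truth, profiles = profiles,
       reflectance = reflectance)
}

# a hand-built stage_dataset for tests that need exact control over the
# SPAD/VI link
manual_dataset <- function(stage, plot_id, canopy_spad, leaf_spad, vi) {
  structure(
    list(stage = stage, plot_id = plot_id, canopy_spad = canopy_spad,
         leaf_spad = leaf_spad, vi = vi),
    class = "stage_dataset"
  )
}
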