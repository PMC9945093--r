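# Shared fixtures: small deterministic objects rebuilt per test run.

fix_schedule <- function() default_schedule()

fix_input <- function() input_function()

# Noiseless reference-region TAC under the default kinetics.
fix_ref <- function(schedule = fix_schedule()) {
  onetc_forward(fix_input(), 0.45, 0.04, schedule, region = "BS")
}

# A tiny two-region subject scan with hand-set values.
fix_scan <- function(units = "kBq/mL") {
  fs <- frame_schedule(c(0, 1, 2, 4), c(1, 2, 4, 8))
  tacs <- list(
    BS = tac(fs, c(10, 20, 15, 12), "BS", units = units),
    HC = tac(fs, c(12, 30, 25, 20), "HC", units = units))
  subject_scan("m01", "WT", injected_activity = 8, body_weight = 25,
               tacs = tacs, reference_region = "BS", injected_mass = 0.3)
}

# Brute-force ROI means: plain voxel loop, independent of extract_roi_tacs.
brute_roi_means <- function(image, atlas, code) {
  nf <- dim(image)[4]
  sel <- which(atlas == code)
  sapply(seq_len(nf), function(f) {
    vol <- image[, , , f]
    mean(vol[sel])
  })
}
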