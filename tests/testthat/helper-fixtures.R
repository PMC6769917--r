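# Shared fixtures built in code.

# Tiny three-glycan panel for unit tests.
tiny_panel <- function() {
  glycan_panel(data.frame(
    id = c("003", "017", "901"),
    name = c("core pentasaccharide", "plant core", "glycolipid"),
    class = c("high_mannose", "other", "glycolipid"),
    core_pentasaccharide = c(TRUE, FALSE, FALSE),
    plant_fuc_xyl_core = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
}

# A synthetic profile with prescribed Ka values (NA -> below detection),
# bypassing the measurement layer, for classifier/comparison unit tests.
profile_from_ka <- function(ka, calibration, v_min = 0.5,
                            lectin = calibration$lectin_name) {
  below <- is.na(ka) | ka == 0
  structure(
    list(lectin_name = lectin, calibration = calibration, v_min = v_min,
         data = data.frame(glycan_id = names(ka),
                           v_minus_v0 = NA_real_,
                           Kd = ifelse(below, NA_real_, 1 / ka),
                           Ka = ifelse(below, 0, ka),
                           below_detection = below,
                           stringsAsFactors = FALSE)),
    class = "specificity_profile"
  )
}

ref_cals <- faclectin::ppl_reference_calibrations()
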