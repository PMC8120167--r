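# Shared fixtures: small, fast synthetic inputs built in code.

# Small-frame image spec for unit tests (acceptance uses the 512-px
# defaults); geometry and pipeline knobs scaled to the 256-px frame.
small_image_spec <- function(seed = 1, true_stroma_frac = 0.6, ...) {
  args <- utils::modifyList(
    list(width = 256, height = 256, nest_radius_range = c(12, 35),
         true_stroma_frac = true_stroma_frac, seed = seed),
    list(...))
  do.call(image_spec, args)
}

small_params <- function(...) {
  args <- utils::modifyList(list(struct_radius = 3, min_object_area = 60),
                            list(...))
  do.call(pipeline_params, args)
}

# A tiny valid clinical table for IO tests.
tiny_clinical <- function(n = 3) {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = rep(c("<=50", ">50"), length.out = n),
    menopausal = rep(c("pre", "post"), length.out = n),
    histotype = rep(c("IDC", "other"), length.out = n),
    t_stage = rep(c("T1", "T2", "T3"), length.out = n),
    n_status = rep(c("neg", "pos"), length.out = n),
    grade = rep(c("I", "II", "III"), length.out = n),
    er = rep(c("pos", "neg"), length.out = n),
    pr = rep(c("pos", "neg"), length.out = n),
    her2 = rep(c("amp", "non-amp"), length.out = n),
    tsr = seq(0.2, 0.8, length.out = n),
    time_months = seq(10, 60, length.out = n),
    event = rep(c(1L, 0L), length.out = n),
    stringsAsFactors = FALSE)
}

# Cohort with the tsr_group factor attached (model reference =
# stroma-high, as in the reference hazard-ratio table).
cohort_with_group <- function(n, seed, cutoff = 0.555, ...) {
  coh <- generate_cohort(cohort_spec(n_patients = n, seed = seed, ...))
  coh$tsr_group <- factor(
    ifelse(coh$tsr <= cutoff, "stroma-low", "stroma-high"),
    levels = c("stroma-high", "stroma-low"))
  coh
}

nomogram_predictors <- c("t_stage", "n_status", "grade", "er", "her2",
                         "tsr_group")
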