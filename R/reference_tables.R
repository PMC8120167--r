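#' Reference cohort tables from the motivating breast-cancer TMA study
#'
#' The defaults of [cohort_spec()] and the worked examples reuse the
#' published summary tables of the invasive breast-cancer TMA cohort
#' (n = 240) that this toolkit emulates: the covariate-by-TSR-group
#' contingency counts and the multivariable Cox hazard ratios for
#' 5-year disease-free survival.
#'
#' @section Contingency counts:
#' `bc_table1_counts()` returns a named list of 2 x k matrices, rows =
#' (stroma-high, stroma-low), one matrix per characteristic.
#'
#' @section Multivariable hazard ratios:
#' `bc_multivariable_hrs()` returns a named list, one numeric vector per
#' predictor; each vector is named by level and the reference level has
#' HR 1. Note that the TSR predictor is reported with stroma-high as the
#' model reference (stroma-low HR 0.643 < 1, i.e. low stroma is
#' protective).
#'
#' @return See sections above.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
bc_table1_counts <- function() {
  m <- function(high, low, lv) {
    out <- rbind(`stroma-high` = high, `stroma-low` = low)
    colnames(out) <- lv
    t(out) # rows = characteristic levels, cols = TSR group
  }
  list(
    age        = m(c(87, 60),      c(62, 31),     c("<=50", ">50")),
    menopausal = m(c(74, 73),      c(60, 33),     c("pre", "post")),
    histotype  = m(c(115, 32),     c(76, 17),     c("IDC", "other")),
    t_stage    = m(c(19, 102, 26), c(16, 60, 17), c("T1", "T2", "T3")),
    n_status   = m(c(62, 85),      c(47, 46),     c("neg", "pos")),
    grade      = m(c(25, 83, 39),  c(15, 58, 20), c("I", "II", "III")),
    er         = m(c(69, 78),      c(37, 56),     c("pos", "neg")),
    pr         = m(c(63, 84),      c(44, 49),     c("pos", "neg")),
    her2       = m(c(26, 121),     c(25, 68),     c("amp", "non-amp"))
  )
}

#' @rdname reference_tables
#' @export
bc_multivariable_hrs <- function() {
  list(
    t_stage  = c(T1 = 1, T2 = 2.576, T3 = 3.506),
    n_status = c(neg = 1, pos = 3.854),
    grade    = c(I = 1, II = 1.479, III = 4.250),
    er       = c(neg = 1, pos = 0.568),
    her2     = c(`non-amp` = 1, amp = 2.045),
    tsr_group = c(`stroma-high` = 1, `stroma-low` = 0.643)
  )
}

# Marginal level frequencies implied by the contingency counts
# (row sums / 240), used as generate_cohort() defaults.
bc_marginal_freqs <- function() {
  tabs <- bc_table1_counts()
  out <- lapply(tabs, function(tab) {
    p <- rowSums(tab) / sum(tab)
    p / sum(p)
  })
  out
}
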