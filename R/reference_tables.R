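#' Reference clinical-index contingency tables
#'
#' Published low- vs high-m6A-indication contingency tables for the two
#' extreme WRE strata (`WRdL_EH` vs `WRdH_EL`) of two gastric-cancer
#' cohorts: a proteomics-profiled diffuse-GC cohort (`ms_*`, 10 vs 14
#' patients) and TCGA stomach adenocarcinoma (`tcga_*`, 29 vs 30 patients;
#' `n/a` rows already excluded). Columns are the low- and high-indication
#' groups; rows the clinical categories. These serve as worked examples
#' for [fisher_exact_2x2()] and [chi_square()]: e.g. the `ms_gender` table
#' gives a two-sided Fisher P of 0.6785.
#'
#' @return Named list of integer matrices: `ms_gender`, `ms_age`,
#'   `tcga_gender`, `tcga_age`, `tcga_m_stage`, `tcga_lauren`.
#' @examples
#' fisher_exact_2x2(gc_reference_tables()$ms_gender)$p_value
#' @export
gc_reference_tables <- function() {
  list(
    ms_gender = matrix(c(7, 3, 8, 6), 2, 2,
                       dimnames = list(c("Male", "Female"), c("low", "high"))),
    ms_age = matrix(c(6, 4, 7, 7), 2, 2,
                    dimnames = list(c("<=60", ">60"), c("low", "high"))),
    tcga_gender = matrix(c(18, 11, 17, 13), 2, 2,
                         dimnames = list(c("Male", "Female"), c("low", "high"))),
    tcga_age = matrix(c(11, 18, 4, 26), 2, 2,
                      dimnames = list(c("<=60", ">60"), c("low", "high"))),
    tcga_m_stage = matrix(c(27, 2, 26, 2), 2, 2,
                          dimnames = list(c("m0", "m1"), c("low", "high"))),
    tcga_lauren = matrix(c(13, 13, 3, 2, 26, 2), 3, 2,
                         dimnames = list(c("Diffuse", "Intestinal", "Others"),
                                         c("low", "high")))
  )
}
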