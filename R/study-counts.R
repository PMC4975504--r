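# Published summary counts for the HDAC9 SNP rs2107595 two-stage CAD
# case-control study (2317 cases / 2404 controls, Chinese Han), bundled as
# example data so the association, homogeneity, power and interaction
# machinery can be exercised on real printed counts without external files.

#' Genotype counts from the rs2107595 CAD case-control study
#'
#' Discovery (1172 cases / 1086 controls), replication (1145 / 1318) and
#' merged genotype counts of SNP rs2107595 (GG/AG/AA) for coronary artery
#' disease cases and controls.
#'
#' @return Named list of three [genotype_table()] objects: `discovery`,
#'   `replication`, `merged`.
#' @examples
#' g <- rs2107595_genotype_tables()$merged
#' odds_ratio(recode_model(g, "dominant"))   # OR 1.28
#' @export
rs2107595_genotype_tables <- function() {
  list(
    discovery = genotype_table(cases = c(495, 558, 119),
                               controls = c(526, 463, 97),
                               label = "discovery"),
    replication = genotype_table(cases = c(481, 529, 135),
                                 controls = c(632, 560, 126),
                                 label = "replication"),
    merged = genotype_table(cases = c(976, 1087, 254),
                            controls = c(1158, 1023, 223),
                            label = "merged"))
}

#' Dominant-model subgroup counts from the rs2107595 CAD study
#'
#' Carrier (AG + AA) versus GG counts for cases and controls within each
#' level of the stratifying risk factors, for the merged two-stage sample.
#' Each element is a list with `exposed` and `unexposed` [two_by_two()]
#' tables (exposed = risk-factor present; table columns exposed = carrier).
#'
#' @return Named list over `t2dm`, `hyperlipidemia`, `bmi` (BMI > 25),
#'   `smoking`, `drinking`, `hypertension`, `age_over60`, `male`.
#' @examples
#' s <- rs2107595_subgroup_tables()$t2dm
#' interaction_test(ge_strata_data(s$exposed, s$unexposed),
#'                  "g", "e", weights = "n")$p   # 0.004
#' @export
rs2107595_subgroup_tables <- function() {
  tab <- function(case_car, case_gg, ctl_car, ctl_gg, label)
    two_by_two(case_car, case_gg, ctl_car, ctl_gg, label = label)
  list(
    t2dm = list(
      exposed = tab(487, 263, 325, 289, "T2DM yes"),
      unexposed = tab(854, 713, 921, 869, "T2DM no")),
    hyperlipidemia = list(
      exposed = tab(443, 238, 283, 266, "hyperlipidemia yes"),
      unexposed = tab(898, 738, 963, 892, "hyperlipidemia no")),
    bmi = list(
      exposed = tab(673, 444, 455, 456, "BMI > 25"),
      unexposed = tab(668, 532, 791, 702, "BMI <= 25")),
    smoking = list(
      exposed = tab(490, 315, 360, 309, "smoking yes"),
      unexposed = tab(851, 661, 886, 849, "smoking no")),
    drinking = list(
      exposed = tab(450, 307, 304, 281, "drinking yes"),
      unexposed = tab(891, 669, 942, 877, "drinking no")),
    hypertension = list(
      exposed = tab(792, 582, 461, 435, "hypertension yes"),
      unexposed = tab(549, 394, 785, 723, "hypertension no")),
    age_over60 = list(
      exposed = tab(674, 483, 696, 630, "age > 60"),
      unexposed = tab(667, 493, 550, 528, "age <= 60")),
    male = list(
      exposed = tab(743, 535, 692, 631, "male"),
      unexposed = tab(598, 441, 554, 527, "female")))
}

#' CAD-subtype dominant-model counts from the rs2107595 study
#'
#' Carrier (AG + AA) versus GG counts for each clinical CAD subtype against
#' the shared merged control group.
#'
#' @return Named list of [two_by_two()] tables over `SAP`, `UAP`, `NSTEMI`,
#'   `STEMI`.
#' @export
rs2107595_subtype_tables <- function() {
  list(
    SAP = two_by_two(345, 335, 1246, 1158, label = "SAP"),
    UAP = two_by_two(456, 320, 1246, 1158, label = "UAP"),
    NSTEMI = two_by_two(338, 205, 1246, 1158, label = "NSTEMI"),
    STEMI = two_by_two(202, 116, 1246, 1158, label = "STEMI"))
}
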