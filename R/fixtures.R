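#' Packaged reference tables
#'
#' The published study tables shipped with the package as plain CSV,
#' transcribed verbatim from the source publication:
#'
#' * `table1_diets` — formulation and analysed nutrient levels of the six
#'   experimental diets (%, as-fed; GE MJ/kg as-fed).
#' * `table4_ingredients` — nutrient characteristics, protein deposition
#'   and lipid deposition of 47 ingredients (19 energy, 7 lipid, 21
#'   protein).
#' * `table5_digestibility` — treatment means: body weight, intake,
#'   digestibility and nitrogen balance.
#' * `table6_energy` — treatment means: energy balance, energy values and
#'   utilization ratios.
#' * `table7_nutrient_energy` — energy values and efficiencies of the five
#'   tested nutrients (reference values; the per-pig replicates behind them
#'   are unpublished).
#' * `table8_equations` — published prediction-equation ladder for PD and
#'   LD with fit metrics.
#'
#' @param name table name (see above).
#' @return A data frame.
#' @examples
#' nrow(nep_fixture("table4_ingredients")) # 47
#' @export
nep_fixture <- function(name = c("table1_diets", "table4_ingredients",
                                 "table5_digestibility", "table6_energy",
                                 "table7_nutrient_energy",
                                 "table8_equations")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "nepartition", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
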