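#' Read a diet formulation table
#'
#' CSV with one row per diet: a `diet` id column, ingredient percentage
#' columns (as-fed, summing to 100 within 0.01), and analysed nutrient
#' columns `dm`, `ash`, `ee`, `ndf`, `adf`, `cp` (% as-fed) and `ge`
#' (MJ/kg as-fed).  The packaged formulation table
#' (`nep_fixture("table1_diets")`) is the reference layout.
#'
#' @param path CSV path.
#' @param ingredient_cols ingredient columns; defaults to every column that
#'   is neither `diet` nor an analysed-nutrient column.
#' @return Validated data frame.
#' @export
read_diets <- function(path, ingredient_cols = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_diets(d, ingredient_cols)
}

validate_diets <- function(d, ingredient_cols = NULL) {
  nutrient_cols <- c("dm", "ash", "ee", "ndf", "adf", "cp", "ge")
  stopifnot("diet" %in% names(d), all(nutrient_cols %in% names(d)))
  if (is.null(ingredient_cols)) {
    ingredient_cols <- setdiff(names(d), c("diet", nutrient_cols))
  }
  totals <- rowSums(d[ingredient_cols])
  if (any(abs(totals - 100) > 0.01)) {
    stop("ingredient percentages must sum to 100 (got ",
         paste(round(totals, 3), collapse = ", "), ")", call. = FALSE)
  }
  pct <- unlist(d[c(ingredient_cols, setdiff(nutrient_cols, "ge"))])
  if (any(pct < 0 | pct > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  if (any(d$dm <= 0)) stop("dm must be positive", call. = FALSE)
  attr(d, "ingredient_cols") <- ingredient_cols
  d
}

#' Read per-pig balance records
#'
#' CSV with one row per pig-period: `pig_id`, `diet_id`, `dmi` (kg DM/d),
#' `ge_intake`, `fecal_ge`, `urinary_ge`, `ch4_energy` (MJ/d), `n_intake`,
#' `fecal_n`, `urinary_n` (g/d) and `bw_start`, `bw_end` (kg).  Optional
#' columns `thp_kjd`, `fhp_kjd` (kJ/d) carry externally summarised heat
#' production when no gas trace is available.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_balance_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_balance_records(d)
}

validate_balance_records <- function(d) {
  needed <- c("pig_id", "diet_id", "dmi", "ge_intake", "fecal_ge",
              "urinary_ge", "n_intake", "fecal_n", "urinary_n",
              "bw_start", "bw_end")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("missing balance-record columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- c("dmi", "ge_intake", "fecal_ge", "urinary_ge", "n_intake",
           "fecal_n", "urinary_n")
  if (any(unlist(d[num]) < 0, na.rm = TRUE)) {
    stop("masses and energies must be non-negative", call. = FALSE)
  }
  if (any(d$bw_start <= 0 | d$bw_end <= 0)) {
    stop("body weights must be positive", call. = FALSE)
  }
  if (any(d$fecal_ge > d$ge_intake)) {
    warning("fecal energy exceeds GE intake in some records", call. = FALSE)
  }
  d
}

#' Read gas traces
#'
#' CSV with columns `pig_id`, `time` (minutes from the start of the
#' measurement), `o2`, `co2`, `ch4` (L per interval) and `state`
#' (`fed`/`fasted`); timestamps must be strictly increasing within each pig.
#'
#' @param path CSV path.
#' @param interval interval length, minutes.
#' @return A list of [gas_trace()] objects, named by `pig_id`.
#' @export
read_gas_traces <- function(path, interval = 5) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pig_id", "time", "o2", "co2", "state") %in% names(d)))
  if (is.null(d$ch4)) d$ch4 <- 0
  traces <- lapply(split(d, d$pig_id), function(g) {
    g <- g[order(g$time), ]
    gas_trace(g$time, g$o2, g$co2, g$ch4, g$state, pig_id = g$pig_id[1],
              interval = interval)
  })
  traces
}

#' Write a delimited table
#'
#' Thin CSV writer used for all pipeline outputs (UTF-8, `.` decimal mark,
#' no row names).
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
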