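#' Apparent total tract digestibility
#'
#' `attd(intake, fecal)` returns `(intake - fecal)/intake`, the fraction of
#' an ingested quantity (energy or a nutrient) not recovered in faeces.
#' Vectorised.  A fecal output exceeding intake is physically suspicious but
#' is returned as a negative digestibility with a warning rather than being
#' clamped, so that bad records stay visible downstream.
#'
#' @param intake daily intake of the quantity (any unit, > 0).
#' @param fecal daily fecal output of the same quantity (>= 0).
#' @return Digestibility as a fraction (multiply by 100 for percent).
#' @examples
#' attd(39.39, 3.94) # CP digestibility of the casein diet, ~0.90
#' @export
attd <- function(intake, fecal) {
  stopifnot(is.numeric(intake), is.numeric(fecal))
  if (any(intake <= 0)) stop("intake must be positive", call. = FALSE)
  if (any(fecal < 0)) stop("fecal output must be non-negative", call. = FALSE)
  if (any(fecal > intake)) {
    warning("fecal output exceeds intake; negative digestibility returned",
            call. = FALSE)
  }
  (intake - fecal) / intake
}

#' Nitrogen retention and net protein availability
#'
#' Nitrogen retention is the signed balance `N intake - fecal N - urinary N`
#' (g/d); it may be negative in catabolic states.  Net protein availability
#' is the same balance expressed as a fraction of nitrogen intake.
#'
#' @param n_intake,fecal_n,urinary_n daily nitrogen flows, g/d (>= 0).
#' @return `nitrogen_retention()`: g/d.  `net_protein_availability()`:
#'   a fraction.
#' @export
nitrogen_retention <- function(n_intake, fecal_n, urinary_n) {
  stopifnot(is.numeric(n_intake), is.numeric(fecal_n), is.numeric(urinary_n))
  if (any(n_intake < 0) || any(fecal_n < 0) || any(urinary_n < 0)) {
    stop("nitrogen flows must be non-negative", call. = FALSE)
  }
  n_intake - fecal_n - urinary_n
}

#' @rdname nitrogen_retention
#' @export
net_protein_availability <- function(n_intake, fecal_n, urinary_n) {
  if (any(n_intake <= 0)) stop("n_intake must be positive", call. = FALSE)
  nitrogen_retention(n_intake, fecal_n, urinary_n) / n_intake
}

#' Metabolic body weight
#'
#' Body weight raised to the power 0.6, the scaling basis used for all
#' energy rates in this package.  For a balance period the body weight is
#' the arithmetic mean of the start and end weights.
#'
#' @param bw body weight, kg (> 0).
#' @param exponent scaling exponent; fixed default 0.6.
#' @return kg^0.6.
#' @export
metabolic_weight <- function(bw, exponent = 0.6) {
  stopifnot(is.numeric(bw))
  if (any(bw <= 0)) stop("body weight must be positive", call. = FALSE)
  bw^exponent
}

#' Digestible and metabolizable energy of balance records
#'
#' DE is gross energy intake minus fecal energy; ME additionally deducts
#' urinary and methane energy.  Densities (MJ/kg DM) are the daily values
#' divided by dry matter intake.
#'
#' @param records a balance-record data frame with columns `ge_intake`,
#'   `fecal_ge`, `urinary_ge`, `ch4_energy` (MJ/d) and `dmi` (kg DM/d).
#'   `ch4_energy` may be absent or NA; it is then derived from a `ch4` column
#'   (L/d) at `ch4_kj_per_l`, or taken as zero, with a message.
#' @param ch4_kj_per_l combustion energy of methane used when only a gas
#'   volume is available, kJ/L.
#' @return `records` with columns `de`, `me` (MJ/d) and, when `dmi` is
#'   present and positive, `de_density`, `me_density` (MJ/kg DM).
#' @export
de_me_values <- function(records, ch4_kj_per_l = 39.54) {
  records <- as.data.frame(records)
  needed <- c("ge_intake", "fecal_ge", "urinary_ge")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ch4e <- records$ch4_energy
  if (is.null(ch4e) || all(is.na(ch4e))) {
    if (!is.null(records$ch4)) {
      ch4e <- records$ch4 * ch4_kj_per_l / 1000
      message("ch4_energy derived from CH4 volume at ", ch4_kj_per_l, " kJ/L")
    } else {
      ch4e <- 0
      message("no methane data; ch4_energy assumed 0")
    }
    records$ch4_energy <- ch4e
  }
  if (any(records$fecal_ge > records$ge_intake)) {
    warning("fecal energy exceeds gross energy intake in some records",
            call. = FALSE)
  }
  records$de <- records$ge_intake - records$fecal_ge
  records$me <- records$de - records$urinary_ge - records$ch4_energy
  if (!is.null(records$dmi)) {
    if (any(records$dmi <= 0)) {
      stop("dmi must be positive to compute energy densities", call. = FALSE)
    }
    records$de_density <- records$de / records$dmi
    records$me_density <- records$me / records$dmi
  }
  records
}

#' Energy partition of balance records
#'
#' Combines a balance record with its total and fasting heat production to
#' produce the complete energy partition on the kJ/kg BW^0.6/d scale:
#' heat increment `hi = thp - fhp`, net energy `ne = me - hi`, retained
#' energy `re = me - thp`, protein deposition from retained nitrogen
#' (`pd = NR x 6.25 x 23.86`), `pd_free_ne = ne - pd` and `ld = re - pd`.
#' The identities `mei = thp + re` and `re = pd + ld` hold exactly by
#' construction.
#'
#' @param records balance-record data frame (see [read_balance_records()]
#'   for the column contract); must carry `bw_start`/`bw_end` or `bw`.
#' @param thp,fhp total and fasting heat production, kJ/d, one value per
#'   record (recycled if length 1).  `fhp` may contain NA when no fasted
#'   measurement exists; the partition columns depending on it are then NA.
#' @param coef a [brouwer_coefficients()] set (protein factors).
#' @return A data frame of class `energy_partition`: one row per record with
#'   rate columns `mei`, `thp`, `fhp`, `hi`, `re`, `pd`, `ld`, `ne`,
#'   `pd_free_ne` (kJ/kg BW^0.6/d) and density columns `de_density`,
#'   `me_density`, `ne_density` (MJ/kg DM).
#' @export
energy_partition <- function(records, thp, fhp, coef = brouwer_coefficients()) {
  if (is.null(records$dmi)) {
    stop("records need a dmi column (kg DM/d)", call. = FALSE)
  }
  records <- de_me_values(records)
  n <- nrow(records)
  thp <- rep_len(as.numeric(thp), n)
  fhp <- rep_len(as.numeric(fhp), n)
  bw <- if (!is.null(records$bw)) records$bw else {
    if (is.null(records$bw_start) || is.null(records$bw_end)) {
      stop("records need bw or bw_start/bw_end columns", call. = FALSE)
    }
    (records$bw_start + records$bw_end) / 2
  }
  if (any(bw <= 0)) stop("body weight must be positive", call. = FALSE)
  if (any(!is.na(fhp) & thp < fhp)) {
    warning("THP below FHP in some records (negative heat increment)",
            call. = FALSE)
  }
  mbw <- metabolic_weight(bw)

  nr <- nitrogen_retention(records$n_intake, records$fecal_n,
                           records$urinary_n)
  pd_kjd <- nr * coef$n_to_protein * coef$protein_energy

  out <- data.frame(
    pig_id = if (!is.null(records$pig_id)) records$pig_id else seq_len(n),
    diet_id = if (!is.null(records$diet_id)) records$diet_id else NA_character_,
    bw = bw,
    mbw = mbw,
    mei = records$me * 1000 / mbw,
    thp = thp / mbw,
    fhp = fhp / mbw,
    stringsAsFactors = FALSE
  )
  out$hi <- out$thp - out$fhp
  out$ne <- out$mei - out$hi
  out$re <- out$mei - out$thp
  out$pd <- pd_kjd / mbw
  out$pd_free_ne <- out$ne - out$pd
  out$ld <- out$re - out$pd
  out$de_density <- records$de / records$dmi
  out$me_density <- records$me / records$dmi
  out$ne_density <- out$ne * mbw / records$dmi / 1000
  class(out) <- c("energy_partition", "data.frame")
  out
}

#' @export
print.energy_partition <- function(x, digits = 2, ...) {
  cat("Energy partition (kJ/kg BW^0.6/d; densities MJ/kg DM):",
      nrow(x), "records\n")
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}
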