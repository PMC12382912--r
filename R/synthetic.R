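#' Specification of a synthetic balance trial
#'
#' Describes a substitution trial with known ground truth: one basal diet
#' plus one test diet per nutrient, each fed to `n_pigs_per_diet` pigs at a
#' fixed metabolizable-energy level on the metabolic body-weight scale.
#' The latent parameters default to the study conditions of the reference
#' experiment: feeding level 1.92 MJ ME/kg BW^0.6/d, initial body weight
#' 28.1 +/- 0.8 kg, mean fasting heat production 840 kJ/kg BW^0.6/d,
#' nutrient efficiencies and energy densities from the packaged nutrient
#' reference table, K_BR = 0.96 and NE_PD = 0.35.
#'
#' Noise channels (`noise_sd`) are independent Gaussian standard
#' deviations: `fecal_ge`, `urinary_ge` (MJ/d), `fecal_n`, `urinary_n`
#' (g/d), `gas` (L per 5-min interval), `fhp_pig` (between-animal fasting
#' heat production, kJ/kg BW^0.6/d) and `fhp_lof` (nested-model
#' lack-of-fit on test pigs, same scale).  Defaults are matched to the
#' published pooled SEMs (sd = SEM x sqrt(6)).  Pass `noise_sd = 0` for a
#' noise-free trial.
#'
#' @param n_pigs_per_diet replicate pigs per diet (>= 1).
#' @param diets diet formulation table (used for ids and inclusion
#'   proportions); defaults to the packaged formulation table.
#' @param schemes named list of [inclusion_scheme()]s per test diet.
#' @param basal basal diet id.
#' @param latent named list overriding any latent parameter (see Details).
#' @param noise_sd named list overriding any noise channel, or a single 0.
#' @param seed integer seed.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(n_pigs_per_diet = 6, diets = NULL, schemes = NULL,
                       basal = "T1", latent = list(), noise_sd = list(),
                       seed = 1) {
  if (is.null(diets)) diets <- nep_fixture("table1_diets")
  if (is.null(schemes)) schemes <- schemes_from_diets(diets, basal = basal)
  stopifnot(n_pigs_per_diet >= 1)

  tab7 <- nep_fixture("table7_nutrient_energy")
  t7 <- function(item, col) tab7[[col]][match(item, tab7$item)]
  nutrient_names <- c(T2 = "corn_starch", T3 = "pea_starch",
                      T4 = "tapioca_starch", T5 = "soybean_oil",
                      T6 = "casein")
  nutrient_names <- nutrient_names[names(schemes)]
  nut <- data.frame(
    diet = names(schemes),
    nutrient = unname(nutrient_names),
    pj = vapply(nutrient_names, t7, numeric(1), item = "pj"),
    kj = vapply(nutrient_names, t7, numeric(1), item = "kj"),
    ge = vapply(nutrient_names, t7, numeric(1), item = "ge"),
    dj = vapply(nutrient_names, function(x) t7("de", x) / t7("ge", x),
                numeric(1)),
    mj = vapply(nutrient_names, function(x) t7("me", x) / t7("de", x),
                numeric(1)),
    cp = unname(c(T2 = 0.3, T3 = 0.3, T4 = 0.3, T5 = 0, T6 = 95)[
      names(schemes)]),
    stringsAsFactors = FALSE
  )

  lat <- list(
    mei = 1920,              # kJ ME/kg BW^0.6/d feeding level
    fhp = 840,               # mean fasting heat production, same scale
    k_br = 0.96,
    ne_pd = 0.35,
    basal_pj = 0.19, basal_kj = 0.81,
    basal_ge = 18.36, basal_de = 16.02, basal_me = 15.52,  # MJ/kg DM
    basal_cp = 18.97,        # % of DM
    attd_cp = c(T1 = 0.8690, T2 = 0.8868, T3 = 0.8774, T4 = 0.8926,
                T5 = 0.8626, T6 = 0.9001),
    bw_mean = 28.1, bw_sd = 0.8, bw_gain = 5,
    rq_fed = 1.03, rq_fasted = 0.82,
    ch4_frac = 0.004,        # CH4 energy as a fraction of GE intake
    nutrients = nut
  )
  lat[names(latent)] <- latent
  stopifnot(lat$mei > 0, lat$fhp > 0,
            lat$k_br > 0, lat$k_br <= 1 + 1e-9,
            all(lat$nutrients$pj > 0 & lat$nutrients$pj < 1),
    all(lat$nutrients$kj > 0 & lat$nutrients$kj <= 1 + 1e-9))

  ns <- list(fecal_ge = 0.15, urinary_ge = 0.04, fecal_n = 0.39,
             urinary_n = 0.93, gas = 0.05, fhp_pig = 118, fhp_lof = 30)
  if (identical(noise_sd, 0) || identical(noise_sd, 0L)) {
    ns[] <- 0
  } else {
    ns[names(noise_sd)] <- noise_sd
  }
  if (any(unlist(ns) < 0)) stop("noise_sd must be non-negative",
                                call. = FALSE)

  structure(list(n_pigs_per_diet = n_pigs_per_diet, diets = diets,
                 schemes = schemes, basal = basal, latent = lat,
                 noise_sd = ns, seed = seed),
            class = "trial_spec")
}

#' Generate a synthetic balance trial with known ground truth
#'
#' Forward simulation of the whole trial.  For each pig the generator draws
#' a body weight, fixes metabolizable-energy intake at the feeding level,
#' computes latent protein and lipid deposition from the nutrient
#' efficiencies, and emits a balance record (intake, fecal/urinary
#' energies and nitrogen, body weights) plus, optionally, a 5-min gas
#' trace whose Brouwer inversion returns the latent heat production.
#'
#' Basal pigs receive between-animal variation in fasting heat production;
#' each test pig's fasting measurement is then constructed so that after
#' per-replicate differencing the nutrient-level observations satisfy the
#' nested partition model `LD = PD-free NE - K_BR*FHP + NE_PD*PD` exactly
#' (plus the lack-of-fit noise channel).  All bookkeeping identities
#' (`mei = thp + re`, `re = pd + ld`) hold exactly before measurement
#' noise, so a noise-free trial is recovered perfectly by the analysis
#' chain.
#'
#' @param spec a [trial_spec()].
#' @param traces emit gas traces (`TRUE`) or attach summarised `thp_kjd`/
#'   `fhp_kjd` columns only (`FALSE`, much faster for simulation studies).
#' @return List with `records` (balance records), `traces` (list of
#'   [gas_trace()] or `NULL`), `diet_info` (synthetic diet energy/CP
#'   densities), `schemes`, and `ground_truth` (all latent values,
#'   including the noise-free nutrient-level observation table).
#' @examples
#' trial <- generate_trial(trial_spec(n_pigs_per_diet = 2, noise_sd = 0),
#'                         traces = FALSE)
#' head(trial$records)
#' @export
generate_trial <- function(spec, traces = TRUE) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  lat <- spec$latent
  ns <- spec$noise_sd
  m <- lat$mei
  npig <- spec$n_pigs_per_diet
  nut <- lat$nutrients

  # nutrient-level latents on the rate scale (kJ/kg BW^0.6/d)
  q <- vapply(spec$schemes, function(s) s$r1 / s$r0, numeric(1))
  r2 <- vapply(spec$schemes, function(s) s$r2, numeric(1))
  me_rate_j <- m * (1 - q) / r2
  pd_j <- nut$pj * me_rate_j
  pfn_j <- nut$kj * (1 - nut$pj) * me_rate_j

  # densities (MJ/kg DM)
  de_j <- nut$dj * nut$ge
  me_j <- nut$mj * de_j
  ge_d <- c(lat$basal_ge, lat$basal_ge * q + nut$ge * r2)
  de_d <- c(lat$basal_de, lat$basal_de * q + de_j * r2)
  me_d <- c(lat$basal_me, lat$basal_me * q + me_j * r2)
  cp_d <- c(lat$basal_cp, lat$basal_cp * q + nut$cp * r2)
  diet_ids <- c(spec$basal, nut$diet)
  diet_info <- data.frame(diet = diet_ids, ge_density = ge_d,
                          de_density = de_d, me_density = me_d,
                          cp_dm = cp_d, stringsAsFactors = FALSE)

  pd_b <- lat$basal_pj * m
  pfn_b <- lat$basal_kj * (1 - lat$basal_pj) * m

  # between-animal FHP of the basal replicates; test pigs derive from the
  # replicate they are differenced against
  # feasibility of the latent (noise-free) construction
  if (pfn_b - lat$fhp <= 0) {
    stop("infeasible latent combination: basal lipid deposition ",
         "(kj*(1-pj)*mei - fhp) is not positive", call. = FALSE)
  }
  fhp_t0_bar <- (lat$fhp * q - r2 * lat$ne_pd * pd_j) / (1 - r2 * lat$k_br)
  ld_j_bar <- pfn_j - lat$k_br * fhp_t0_bar + lat$ne_pd * pd_j
  if (any(ld_j_bar <= 0)) {
    stop("infeasible latent combination: implied lipid deposition of ",
         paste(nut$nutrient[ld_j_bar <= 0], collapse = ", "),
         " is not positive", call. = FALSE)
  }

  fhp_b <- truncnorm(npig, lat$fhp, ns$fhp_pig)
  ld_b <- pfn_b - fhp_b
  if (any(ld_b <= 0)) {
    stop("drawn basal fasting heat production exceeds PD-free net energy; ",
         "reduce the fhp_pig noise channel", call. = FALSE)
  }

  records <- list()
  trace_list <- list()
  truth_rows <- list()

  for (d in seq_along(diet_ids)) {
    id <- diet_ids[d]
    is_basal <- d == 1L
    if (!is_basal) {
      j <- d - 1L
      fhp_t0 <- (fhp_b * q[j] - r2[j] * lat$ne_pd * pd_j[j]) /
        (1 - r2[j] * lat$k_br)
      # noisy realizations may mobilise lipid (ld_jk < 0); only the
      # noise-free construction is required to be feasible (checked above)
      ld_jk <- pfn_j[j] - lat$k_br * fhp_t0 + lat$ne_pd * pd_j[j]
      pd_rate <- rep(pd_b * q[j] + pd_j[j] * r2[j], npig)
      ld_rate <- ld_b * q[j] + ld_jk * r2[j]
      fhp_meas <- fhp_t0 + stats::rnorm(npig, 0, ns$fhp_lof)
    } else {
      pd_rate <- rep(pd_b, npig)
      ld_rate <- ld_b
      fhp_meas <- fhp_b
    }
    re_rate <- pd_rate + ld_rate
    thp_rate <- m - re_rate

    bw_start <- truncnorm(npig, lat$bw_mean, lat$bw_sd)
    bw_end <- bw_start + lat$bw_gain
    mbw <- metabolic_weight((bw_start + bw_end) / 2)

    dmi <- m * mbw / (me_d[d] * 1000)
    ge_intake <- ge_d[d] * dmi
    de <- de_d[d] * dmi
    me <- me_d[d] * dmi
    fecal_ge <- ge_intake - de
    ch4_energy <- pmin(lat$ch4_frac * ge_intake, 0.8 * (de - me))
    urinary_ge <- de - me - ch4_energy

    n_intake <- dmi * cp_d[d] * 10 / 6.25
    nr <- pd_rate * mbw / (6.25 * 23.86)
    fecal_n <- (1 - lat$attd_cp[[id]]) * n_intake
    urinary_n <- n_intake - fecal_n - nr
    if (any(urinary_n < 0)) {
      stop("infeasible latent combination: implied urinary nitrogen is ",
           "negative for diet ", id, call. = FALSE)
    }

    # measurement noise (truncated at zero where a negative mass is
    # physically impossible)
    fecal_ge <- pmax(fecal_ge + stats::rnorm(npig, 0, ns$fecal_ge), 0)
    urinary_ge <- pmax(urinary_ge + stats::rnorm(npig, 0, ns$urinary_ge), 0)
    fecal_n <- pmax(fecal_n + stats::rnorm(npig, 0, ns$fecal_n), 0)
    urinary_n <- pmax(urinary_n + stats::rnorm(npig, 0, ns$urinary_n), 0)

    rec <- data.frame(
      pig_id = sprintf("%s_p%d", id, seq_len(npig)),
      diet_id = id,
      dmi = dmi, ge_intake = ge_intake, fecal_ge = fecal_ge,
      urinary_ge = urinary_ge, ch4_energy = ch4_energy,
      n_intake = n_intake, fecal_n = fecal_n, urinary_n = urinary_n,
      bw_start = bw_start, bw_end = bw_end,
      thp_kjd = thp_rate * mbw, fhp_kjd = fhp_meas * mbw,
      stringsAsFactors = FALSE
    )
    records[[d]] <- rec

    if (traces) {
      ch4_l <- ch4_energy * 1000 / 39.54
      for (k in seq_len(npig)) {
        trace_list[[rec$pig_id[k]]] <- synth_trace(
          thp_kjd = rec$thp_kjd[k], fhp_kjd = rec$fhp_kjd[k],
          urinary_n = urinary_n[k], ch4_l = ch4_l[k],
          rq_fed = lat$rq_fed, rq_fasted = lat$rq_fasted,
          gas_sd = ns$gas, pig_id = rec$pig_id[k])
      }
    }
    truth_rows[[d]] <- data.frame(
      diet = id, pd = mean(pd_rate), ld = mean(ld_rate),
      thp = mean(thp_rate), fhp = mean(fhp_meas),
      stringsAsFactors = FALSE)
  }

  # noise-free nutrient-level observation table (evaluated at the mean FHP)
  truth_nut <- data.frame(
    nutrient = nut$nutrient, diet = nut$diet,
    pj = nut$pj, kj = nut$kj,
    ge = nut$ge, de = de_j, me = me_j,
    me_rate = me_rate_j, pd = pd_j, pd_free_ne = pfn_j,
    ld = pfn_j - lat$k_br * fhp_t0_bar + lat$ne_pd * pd_j,
    fhp = fhp_t0_bar, stringsAsFactors = FALSE)

  list(records = do.call(rbind, records),
       traces = if (traces) trace_list else NULL,
       diet_info = diet_info,
       schemes = spec$schemes,
       ground_truth = list(k_br = lat$k_br, ne_pd = lat$ne_pd,
                           mei = m, fhp = lat$fhp,
                           basal_pj = lat$basal_pj, basal_kj = lat$basal_kj,
                           nutrients = truth_nut,
                           diets = do.call(rbind, truth_rows)))
}

truncnorm <- function(n, mean, sd, lower = mean - 3 * sd,
                      upper = mean + 3 * sd) {
  if (sd == 0) return(rep(mean, n))
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

# one fed day (288 intervals) plus one 8-h fasted window (96 intervals)
synth_trace <- function(thp_kjd, fhp_kjd, urinary_n, ch4_l, rq_fed,
                        rq_fasted, gas_sd, pig_id) {
  n_fed <- 288L
  n_fasted <- 96L
  o2_fed <- (thp_kjd + 5.99 * urinary_n + 2.17 * ch4_l) /
    (16.18 + 5.02 * rq_fed)
  o2_fast <- (fhp_kjd + 5.99 * urinary_n) / (16.18 + 5.02 * rq_fasted)
  o2 <- c(rep(o2_fed, n_fed), rep(o2_fast, n_fasted)) / 288
  co2 <- o2 * c(rep(rq_fed, n_fed), rep(rq_fasted, n_fasted))
  ch4 <- c(rep(ch4_l / 288, n_fed), rep(0, n_fasted))
  n <- n_fed + n_fasted
  if (gas_sd > 0) {
    o2 <- pmax(o2 + stats::rnorm(n, 0, gas_sd), 0)
    co2 <- pmax(co2 + stats::rnorm(n, 0, gas_sd), 0)
  }
  gas_trace(time = seq_len(n) * 5, o2 = o2, co2 = co2, ch4 = ch4,
            state = rep(c("fed", "fasted"), c(n_fed, n_fasted)),
            pig_id = pig_id)
}

#' Specification of a synthetic ingredient table
#'
#' Covariates (GE, CP, EE, starch, NDF, ADF, ash) are drawn from a
#' multivariate normal with the given moments, truncated to their valid
#' ranges; PD and LD follow a known linear model plus Gaussian noise.
#' Defaults reproduce the statistical shape of the packaged 47-ingredient
#' table: its sample means and covariance, the published four-term PD and
#' five-term LD equations as generating coefficients, and residual
#' standard deviations equal to the published RMSEs.
#'
#' @param n number of ingredients (>= 10).
#' @param means named mean vector of the covariates.
#' @param sigma covariance matrix (must be positive semi-definite).
#' @param beta_pd,beta_ld named coefficient vectors (`intercept` plus any
#'   covariate names).
#' @param noise_sd named list/vector with `pd` and `ld` residual sds.
#' @param seed integer seed.
#' @return An object of class `ingredient_table_spec`.
#' @export
ingredient_table_spec <- function(n = 47, means = NULL, sigma = NULL,
                                  beta_pd = NULL, beta_ld = NULL,
                                  noise_sd = c(pd = 105.15, ld = 172.85),
                                  seed = 1) {
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  covars <- c("ge", "cp", "ee", "starch", "ndf", "adf", "ash")
  if (is.null(means) || is.null(sigma)) {
    tab4 <- nep_fixture("table4_ingredients")
    if (is.null(means)) means <- colMeans(tab4[covars])
    if (is.null(sigma)) sigma <- stats::cov(tab4[covars])
  }
  stopifnot(identical(names(means), covars),
            identical(dim(sigma), c(7L, 7L)))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  if (is.null(beta_pd)) {
    beta_pd <- c(intercept = 364.36, ge = -18.44, cp = 29.10, ee = -3.79,
                 adf = -21.37)
  }
  if (is.null(beta_ld)) {
    beta_ld <- c(intercept = -1503.50, cp = 21.58, ee = 51.98,
                 starch = 26.30, ndf = 26.81, adf = -23.87)
  }
  stopifnot("intercept" %in% names(beta_pd),
            "intercept" %in% names(beta_ld),
            all(setdiff(names(beta_pd), "intercept") %in% covars),
            all(setdiff(names(beta_ld), "intercept") %in% covars),
            all(c("pd", "ld") %in% names(noise_sd)))
  structure(list(n = n, covars = covars, means = means, sigma = sigma,
                 beta_pd = beta_pd, beta_ld = beta_ld,
                 noise_sd = noise_sd, seed = seed),
            class = "ingredient_table_spec")
}

#' Generate a synthetic ingredient table
#'
#' @param spec an [ingredient_table_spec()].
#' @return Data frame with `ingredient`, the seven covariates and `pd`,
#'   `ld` responses; the generating coefficients are attached as
#'   attributes `beta_pd` and `beta_ld`.
#' @examples
#' tab <- generate_ingredient_table(ingredient_table_spec(n = 20, seed = 7))
#' @export
generate_ingredient_table <- function(spec) {
  stopifnot(inherits(spec, "ingredient_table_spec"))
  set.seed(spec$seed)
  p <- length(spec$covars)
  ev <- eigen(spec$sigma, symmetric = TRUE)
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  z <- matrix(stats::rnorm(spec$n * p), spec$n, p)
  x <- sweep(z %*% t(root), 2, as.numeric(spec$means), `+`)
  colnames(x) <- spec$covars
  x[, "ge"] <- pmax(x[, "ge"], 0)
  pct <- setdiff(spec$covars, "ge")
  x[, pct] <- pmin(pmax(x[, pct], 0), 100)

  lin <- function(beta) {
    v <- setdiff(names(beta), "intercept")
    beta[["intercept"]] + as.numeric(x[, v, drop = FALSE] %*% beta[v])
  }
  pd <- lin(spec$beta_pd) + stats::rnorm(spec$n, 0, spec$noise_sd[["pd"]])
  ld <- lin(spec$beta_ld) + stats::rnorm(spec$n, 0, spec$noise_sd[["ld"]])
  out <- data.frame(ingredient = sprintf("synthetic_%02d", seq_len(spec$n)),
                    as.data.frame(x), pd = pmax(pd, 0), ld = pmax(ld, 0),
                    stringsAsFactors = FALSE)
  attr(out, "beta_pd") <- spec$beta_pd
  attr(out, "beta_ld") <- spec$beta_ld
  out
}
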