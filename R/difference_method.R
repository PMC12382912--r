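#' Inclusion scheme for the difference method
#'
#' In a substitution (difference) trial the test diet replaces part of the
#' basal diet's energy-supplying fraction with the tested nutrient.  The
#' scheme records `r0`, the energy-supplying fraction (corn + soybean meal)
#' of the basal diet; `r1`, the proportion of those basal ingredients in the
#' test diet; and `r2`, the proportion of the tested nutrient in the test
#' diet.  Proportions are on the as-fed basis by default.
#'
#' @param r0,r1,r2 fractions; `0 < r0, r2 <= 1`, `0 <= r1 < 1`,
#'   `r1 + r2 <= 1`.
#' @param basis `"as_fed"` or `"dm"`.
#' @return An object of class `inclusion_scheme`.
#' @export
inclusion_scheme <- function(r0, r1, r2, basis = c("as_fed", "dm")) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(r0), is.numeric(r1), is.numeric(r2))
  if (!(r0 > 0 && r0 <= 1)) stop("r0 must be in (0, 1]", call. = FALSE)
  if (!(r2 > 0 && r2 <= 1)) stop("r2 must be in (0, 1]", call. = FALSE)
  if (!(r1 >= 0 && r1 < 1)) stop("r1 must be in [0, 1)", call. = FALSE)
  if (r1 + r2 > 1 + 1e-9) stop("r1 + r2 must not exceed 1", call. = FALSE)
  structure(list(r0 = r0, r1 = r1, r2 = r2, basis = basis),
            class = "inclusion_scheme")
}

#' Derive inclusion schemes from a diet formulation table
#'
#' Reads the energy-supplying fractions straight off the formulation table:
#' `r0` is corn + soybean meal in the basal diet, `r1` the same pair in each
#' test diet, and `r2` the inclusion of the tested nutrient, all as-fed.
#'
#' @param diets diet formulation table (see [read_diets()]).
#' @param basal id of the basal diet.
#' @param nutrients named character vector mapping diet id to the column
#'   holding its tested nutrient, e.g. `c(T2 = "corn_starch")`.
#' @return Named list of [inclusion_scheme()]s, one per test diet.
#' @export
schemes_from_diets <- function(diets, basal = "T1",
                               nutrients = c(T2 = "corn_starch",
                                             T3 = "pea_starch",
                                             T4 = "tapioca_starch",
                                             T5 = "soybean_oil",
                                             T6 = "casein")) {
  diets <- as.data.frame(diets)
  stopifnot(all(c("diet", "corn", "soybean_meal") %in% names(diets)))
  row_of <- function(id) {
    i <- match(id, diets$diet)
    if (is.na(i)) stop("diet not found: ", id, call. = FALSE)
    diets[i, ]
  }
  b <- row_of(basal)
  r0 <- (b$corn + b$soybean_meal) / 100
  out <- lapply(names(nutrients), function(id) {
    d <- row_of(id)
    col <- nutrients[[id]]
    if (is.null(d[[col]])) stop("no column ", col, " in diet table",
                                call. = FALSE)
    inclusion_scheme(r0 = r0, r1 = (d$corn + d$soybean_meal) / 100,
                     r2 = d[[col]] / 100)
  })
  names(out) <- names(nutrients)
  out
}

#' Single-nutrient value by the difference method
#'
#' `(test - basal/r0 * r1) / r2`: the basal diet's contribution, rescaled by
#' the proportion of basal ingredients retained in the test diet, is removed
#' from the test-diet value and the remainder attributed to the tested
#' nutrient.  Applies to energy densities (MJ/kg DM) and equally to rates on
#' the metabolic body-weight scale.  Vectorised.
#'
#' @param test,basal diet-level values.
#' @param scheme an [inclusion_scheme()].
#' @return The nutrient-level value, same units as the inputs.
#' @export
nutrient_energy <- function(test, basal, scheme) {
  stopifnot(inherits(scheme, "inclusion_scheme"))
  (test - basal / scheme$r0 * scheme$r1) / scheme$r2
}

#' Nutrient-level energetic efficiencies
#'
#' From a nutrient's energy values and deposition rates: `dj = DE/GE`,
#' `mj = ME/DE`, `pj = PD/ME` (PD and ME on the kJ/kg BW^0.6/d scale) and
#' `kj`, the efficiency of using ME for net energy not deposited as protein.
#' The default `kj` form divides PD-free NE by `ME * (1 - pj)` so that the
#' nested prediction `kj * (1 - pj) * ME` returns PD-free NE exactly; the
#' multiplicative form `PD-free NE/ME * (1 - pj)` is available as
#' `kj_form = "printed"`.
#'
#' @param ge,de,me energy values, MJ/kg DM (`ge`, `de`, `me` > 0).
#' @param pd,pd_free_ne deposition rates, kJ/kg BW^0.6/d.
#' @param me_rate metabolizable energy on the same rate scale as `pd`.
#' @param kj_form `"consistent"` (default) or `"printed"`.
#' @return Named list with `dj`, `mj`, `pj`, `kj`.
#' @export
nutrient_efficiencies <- function(ge, de, me, pd, pd_free_ne, me_rate,
                                  kj_form = c("consistent", "printed")) {
  kj_form <- match.arg(kj_form)
  stopifnot(is.na(ge) || ge > 0, de > 0, me > 0, me_rate > 0)
  pj <- pd / me_rate
  if (any(pj >= 1)) stop("pj must be below 1 to define kj", call. = FALSE)
  kj <- switch(kj_form,
               consistent = pd_free_ne / (me_rate * (1 - pj)),
               printed = pd_free_ne / me_rate * (1 - pj))
  list(dj = de / ge, mj = me / de, pj = pj, kj = kj)
}

#' Nutrient energy profile from basal and test partitions
#'
#' Applies the difference method to per-pig energy partitions of a basal
#' and a test diet, pairing replicates in order (replicate k of the test
#' diet against replicate k of the basal diet), and averages the per-pair
#' differences; `mode = "means"` instead differences the treatment means.
#' Densities (GE, DE, ME, NE) and rates (MEI, PD, PD-free NE, LD) are both
#' differenced; efficiencies come from [nutrient_efficiencies()].
#'
#' @param test,basal `energy_partition` data frames.
#' @param scheme an [inclusion_scheme()].
#' @param nutrient label for the tested nutrient.
#' @param ge_test,ge_basal gross energy densities of the two diets,
#'   MJ/kg DM.
#' @param mode `"pairs"` (default) or `"means"`.
#' @param kj_form passed to [nutrient_efficiencies()].
#' @return One-row data frame of class `nutrient_profile` with the
#'   nutrient's ge/de/me/ne densities, rates (`me_rate`, `pd`, `pd_free_ne`,
#'   `ld`), the mean measured fasting and total heat production of the test
#'   pigs (`fhp`, `thp`), efficiencies `dj`, `mj`, `pj`, `kj`, and `n_pairs`.
#' @export
nutrient_profile <- function(test, basal, scheme, nutrient = "nutrient",
                             ge_test = NA, ge_basal = NA,
                             mode = c("pairs", "means"),
                             kj_form = "consistent") {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "inclusion_scheme"))
  diff_of <- function(var) {
    tv <- test[[var]]
    bv <- basal[[var]]
    if (is.null(tv) || is.null(bv)) return(NA_real_)
    if (mode == "means") {
      nutrient_energy(mean(tv), mean(bv), scheme)
    } else {
      k <- min(length(tv), length(bv))
      mean(nutrient_energy(tv[seq_len(k)], bv[seq_len(k)], scheme))
    }
  }
  ge_j <- nutrient_energy(ge_test, ge_basal, scheme)
  de_j <- diff_of("de_density")
  me_j <- diff_of("me_density")
  ne_j <- diff_of("ne_density")
  me_rate <- diff_of("mei")
  pd_j <- diff_of("pd")
  pfn_j <- diff_of("pd_free_ne")
  ld_j <- diff_of("ld")
  eff <- nutrient_efficiencies(ge = ge_j, de = de_j, me = me_j,
                               pd = pd_j, pd_free_ne = pfn_j,
                               me_rate = me_rate, kj_form = kj_form)
  out <- data.frame(nutrient = nutrient, ge = ge_j, de = de_j, me = me_j,
                    ne = ne_j, me_rate = me_rate, pd = pd_j,
                    pd_free_ne = pfn_j, ld = ld_j,
                    thp = mean(test$thp), fhp = mean(test$fhp),
                    dj = eff$dj, mj = eff$mj, pj = eff$pj, kj = eff$kj,
                    n_pairs = min(nrow(test), nrow(basal)),
                    stringsAsFactors = FALSE)
  class(out) <- c("nutrient_profile", "data.frame")
  out
}

#' Fit the nested net-energy partition model
#'
#' Least-squares estimation of the body-reserve coefficient `K_BR` and the
#' protein-deposition cost coefficient `NE_PD` in
#' `LD = PD-free NE - K_BR * x2 + NE_PD * PD`, where `x2` is the fasting
#' heat production (default) or total heat production of the observation.
#' The model is affine in the two parameters, so the Newton-Raphson
#' iteration used here converges in a single step from any start and must
#' agree with the normal-equations solution to machine precision; the
#' iterative solver is retained so that convergence diagnostics, the
#' stopping tolerance and the iteration cap stay explicit and configurable.
#'
#' @param ld lipid deposition, kJ/kg BW^0.6/d.
#' @param pd_free_ne net energy not deposited as protein, same scale.
#' @param x2 fasting (or total) heat production, same scale.
#' @param pd protein deposition, same scale.
#' @param init numeric vector `c(a, b)` of start values for `K_BR` and
#'   `NE_PD`.
#' @param tol stopping tolerance on the objective change and gradient.
#' @param max_iter iteration cap.
#' @return An object of class `nested_fit`: `k_br`, `ne_pd`, `residuals`,
#'   `iterations`, `converged`, standard errors `se` and the residual sum
#'   of squares `sse`.
#' @examples
#' x2 <- c(840, 860, 820, 850, 830)
#' pd <- c(100, 250, 400, 700, 950)
#' pfn <- c(1700, 1500, 1300, 900, 650)
#' ld <- pfn - 0.96 * x2 + 0.35 * pd
#' fit_kbr_nepd(ld, pfn, x2, pd)
#' @export
fit_kbr_nepd <- function(ld, pd_free_ne, x2, pd, init = c(a = 1, b = 0.5),
                         tol = 1e-15, max_iter = 1000) {
  n <- length(ld)
  stopifnot(length(pd_free_ne) == n, length(x2) == n, length(pd) == n)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  # z = pd_free_ne - ld = a * x2 - b * pd; SSE(a, b) is quadratic
  z <- pd_free_ne - ld
  X <- cbind(x2 = x2, pd = -pd)
  xtx <- crossprod(X)
  if (abs(det(xtx)) < 1e-8 * prod(diag(xtx) + .Machine$double.eps)) {
    stop("collinear regressors: K_BR and NE_PD are not identifiable",
         call. = FALSE)
  }
  theta <- as.numeric(init)
  obj <- function(th) sum((z - X %*% th)^2)
  f_old <- obj(theta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grad <- -2 * crossprod(X, z - X %*% theta)
    hess <- 2 * xtx
    theta <- theta - solve(hess, grad)[, 1]
    f_new <- obj(theta)
    if (max(abs(grad)) < tol || abs(f_old - f_new) < tol) {
      converged <- TRUE
      break
    }
    f_old <- f_new
  }
  res <- as.numeric(z - X %*% theta)
  sse <- sum(res^2)
  dfree <- n - 2L
  se <- if (dfree > 0) sqrt(diag(solve(xtx)) * sse / dfree) else rep(NA_real_, 2)
  structure(list(k_br = unname(theta[1]), ne_pd = unname(theta[2]),
                 residuals = res,
                 iterations = iter, converged = converged,
                 se = c(k_br = se[[1]], ne_pd = se[[2]]), sse = sse, n = n),
            class = "nested_fit")
}

#' @export
print.nested_fit <- function(x, ...) {
  cat(sprintf("Nested net-energy partition fit (n = %d)\n", x$n))
  cat(sprintf("  K_BR  = %.4f (se %.4f)\n", x$k_br, x$se[["k_br"]]))
  cat(sprintf("  NE_PD = %.4f (se %.4f)\n", x$ne_pd, x$se[["ne_pd"]]))
  cat(sprintf("  converged: %s after %d iteration(s); SSE = %.4g\n",
              x$converged, x$iterations, x$sse))
  invisible(x)
}

#' Predict lipid deposition from the nested model
#'
#' Evaluates `LD = kj * (1 - pj) * ME - K_BR * FHP + NE_PD * PD`.
#'
#' @param kj,pj nutrient efficiencies (fractions).
#' @param me metabolizable energy, kJ/kg BW^0.6/d.
#' @param fhp fasting heat production, kJ/kg BW^0.6/d.
#' @param pd protein deposition, kJ/kg BW^0.6/d.
#' @param fit a [fit_kbr_nepd()] result supplying `K_BR` and `NE_PD`
#'   (must have converged), or `NULL` when both are given directly.
#' @param k_br,ne_pd coefficients, used when `fit` is `NULL`.
#' @return Predicted lipid deposition, kJ/kg BW^0.6/d.
#' @export
predict_ld <- function(kj, pj, me, fhp, pd, fit = NULL,
                       k_br = NULL, ne_pd = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "nested_fit"))
    if (!fit$converged) stop("nested fit did not converge", call. = FALSE)
    k_br <- fit$k_br
    ne_pd <- fit$ne_pd
  }
  stopifnot(is.numeric(k_br), is.numeric(ne_pd))
  kj * (1 - pj) * me - k_br * fhp + ne_pd * pd
}
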