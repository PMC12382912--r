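# Independent least-squares oracle for the nested partition model:
# pd_free_ne - ld = a*x2 - b*pd fitted by lm without intercept.
ols_nested_oracle <- function(ld, pd_free_ne, x2, pd) {
  z <- pd_free_ne - ld
  fit <- stats::lm(z ~ 0 + x2 + pd)
  c(k_br = unname(coef(fit)[["x2"]]), ne_pd = -unname(coef(fit)[["pd"]]))
}

# Exhaustive enumeration oracle: all candidate subsets that are stable
# under the entry/removal p-rules (every included term significant, no
# excluded candidate would enter).
stable_subsets <- function(data, response, candidates, p = 0.05) {
  subsets <- unlist(lapply(0:length(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  Filter(function(s) {
    if (length(s)) {
      fit <- stats::lm(stats::reformulate(s, response), data)
      if (any(coef(summary(fit))[s, 4] > p)) return(FALSE)
    }
    out <- setdiff(candidates, s)
    p_out <- vapply(out, function(v) {
      fit <- stats::lm(stats::reformulate(c(s, v), response), data)
      coef(summary(fit))[v, 4]
    }, numeric(1))
    all(p_out >= p)
  }, subsets)
}

# small noise-free trial reused across tests
noise_free_trial <- function(n = 2, seed = 1, traces = FALSE) {
  generate_trial(trial_spec(n_pigs_per_diet = n, noise_sd = 0, seed = seed),
                 traces = traces)
}

analyze_generated <- function(trial, ...) {
  analyze_trial(trial$records, trial$schemes, traces = trial$traces,
                ge_density = stats::setNames(trial$diet_info$ge_density,
                                             trial$diet_info$diet), ...)
}
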