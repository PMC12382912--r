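tab4 <- nep_fixture("table4_ingredients")

test_that("correlations over the ingredient table match the published values", {
  cm <- correlation_matrix(tab4)
  expect_equal(cm$r["pd", "cp"], 0.92, tolerance = 0.02 / 0.92)
  expect_equal(cm$r["ld", "ge"], -0.94, tolerance = 0.02 / 0.94)
  expect_equal(cm$r["ld", "ee"], 0.93, tolerance = 0.02 / 0.93)
  expect_equal(cm$r["cp", "cp"], 1)
  expect_true(isSymmetric(cm$r))
  expect_true(all(abs(cm$r) <= 1))
  expect_lt(cm$p["pd", "cp"], 1e-10)
})

test_that("correlations are invariant to affine rescaling of a column", {
  scaled <- tab4
  scaled$cp <- 3.7 * scaled$cp - 12
  expect_equal(correlation_matrix(scaled)$r["pd", "cp"],
               correlation_matrix(tab4)$r["pd", "cp"])
})

test_that("degenerate correlation input is flagged", {
  d <- data.frame(a = c(1, 1, 1, 1), b = 1:4)
  expect_warning(cm <- correlation_matrix(d), "zero-variance")
  expect_true(is.na(cm$r["a", "b"]))
  expect_error(correlation_matrix(tab4[1:2, ]), "3 records")
  d2 <- tab4
  d2$ge[1] <- NA
  expect_error(correlation_matrix(d2), "missing")
})

test_that("the 70/30 split is exhaustive, disjoint and seed-deterministic", {
  s <- split_train_valid(tab4, seed = 99)
  expect_equal(nrow(s$train), 33) # round(0.7 * 47)
  expect_equal(nrow(s$valid), 14)
  expect_length(intersect(rownames(s$train), rownames(s$valid)), 0)
  expect_equal(sort(c(rownames(s$train), rownames(s$valid))),
               sort(rownames(tab4)))
  expect_identical(split_train_valid(tab4, seed = 99), s)
  expect_false(identical(split_train_valid(tab4, seed = 100)$train, s$train))
  expect_error(split_train_valid(tab4, fraction = 0), "between")
  expect_error(split_train_valid(tab4, fraction = 1), "between")
  expect_error(split_train_valid(tab4[1:4, ]), "5 records")
})

test_that("stepwise selection finds the single true covariate", {
  set.seed(3)
  n <- 200
  d <- data.frame(cp = runif(n, 0, 50), ge = runif(n, 14, 22),
                  ee = runif(n, 0, 20), ndf = runif(n, 0, 40),
                  adf = runif(n, 0, 25))
  d$pd <- 50 + 20 * d$cp + rnorm(n, 0, 5)
  m <- stepwise_fit(d, "pd", c("ge", "cp", "ee", "ndf", "adf"))
  expect_identical(m$terms, "cp")
  # noise-free: perfect fit (summary.lm warns about it; that is expected)
  d$pd <- 50 + 20 * d$cp
  m0 <- suppressWarnings(stepwise_fit(d, "pd", c("ge", "cp", "ee", "ndf",
                                                 "adf")))
  expect_identical(m0$terms, "cp")
  expect_equal(m0$r2, 1)
  expect_equal(unname(m0$coefficients), c(50, 20))
})

test_that("stepwise equals the exhaustive p-rule-stable oracle on the fixture", {
  cands <- c("ge", "cp", "ee", "starch", "ndf", "adf")
  stable_pd <- stable_subsets(tab4, "pd", cands)
  sel_pd <- stepwise_fit(tab4, "pd", cands)$terms
  expect_length(stable_pd, 1)
  expect_setequal(sel_pd, stable_pd[[1]])
  stable_ld <- stable_subsets(tab4, "ld", cands)
  sel_ld <- stepwise_fit(tab4, "ld", cands)$terms
  expect_true(any(vapply(stable_ld, setequal, logical(1), y = sel_ld)))
})

test_that("perfectly collinear candidates are dropped with a warning", {
  d <- tab4
  d$cp2 <- 2 * d$cp
  expect_warning(m <- stepwise_fit(d, "pd", c("cp", "cp2", "adf")),
                 "collinear")
  expect_false("cp2" %in% m$terms)
})

test_that("model metrics use the stated formulas and penalties", {
  # zero-residual fit
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  fit <- lm(y ~ x, d)
  met <- model_metrics(fit, d)
  expect_equal(met$r2, 1)
  expect_equal(met$rmse, 0)
  # hand-computed metrics for a noisy fit
  set.seed(5)
  d$y <- d$y + rnorm(10)
  fit <- lm(y ~ x, d)
  sse <- sum(resid(fit)^2)
  met <- model_metrics(fit, d, valid = d)
  expect_equal(met$rmse, sqrt(sse / (10 - 2)))
  expect_equal(met$aic, 10 * log(sse / 10) + 4)
  expect_equal(met$bic, 10 * log(sse / 10) + 2 * log(10))
  expect_equal(met$validation_r2, cor(predict(fit, d), d$y)^2)
  # identical SSE, more terms: information criteria must grow
  expect_gt(10 * log(sse / 10) + 2 * 3, met$aic)
  expect_error(model_metrics(lm(y ~ x, d[1:2, ]), d[1:2, ]), "few rows")
})

test_that("the full-data univariate protein equation has the published strength", {
  met <- model_metrics(lm(pd ~ cp, tab4), tab4)
  expect_equal(met$r2, 0.8457, tolerance = 1e-3)
})

test_that("the model ladder is monotone in SSE and self-consistent", {
  ladder <- model_table(tab4, responses = "pd", seed = 1)
  expect_equal(ladder$n_terms, 1:7)
  # training R2 never decreases as terms are added
  expect_true(all(diff(ladder$r2) >= -1e-12))
  expect_equal(sum(ladder$optimal), 1)
  expect_true(any(ladder$stepwise))
  # ladder metrics reproduce model_metrics row by row
  s <- split_train_valid(tab4, seed = 1)
  for (i in c(1, 4)) {
    terms <- strsplit(ladder$terms[i], "+", fixed = TRUE)[[1]]
    fit <- lm(reformulate(terms, "pd"), s$train)
    met <- model_metrics(fit, s$train, s$valid)
    expect_equal(ladder$r2[i], met$r2)
    expect_equal(ladder$rmse[i], met$rmse)
    expect_equal(ladder$validation_r2[i], met$validation_r2)
  }
  # single-candidate ladder has length one
  l1 <- model_table(tab4, responses = "pd", candidates = "cp", seed = 1)
  expect_equal(nrow(l1), 1)
})

test_that("stepwise on orthogonal covariates equals marginal screening", {
  set.seed(1)
  n <- 80
  x <- qr.Q(qr(matrix(rnorm(n * 4), n, 4))) # orthonormal columns
  d <- as.data.frame(x)
  names(d) <- c("a", "b", "c", "e")
  d$y <- 3 * d$a + 2.5 * d$b + rnorm(n, 0, 0.4)
  marginal <- names(d)[1:4][vapply(names(d)[1:4], function(v) {
    coef(summary(lm(reformulate(v, "y"), d)))[v, 4] < 0.05
  }, logical(1))]
  sel <- stepwise_fit(d, "y", c("a", "b", "c", "e"))$terms
  expect_setequal(sel, marginal)
})
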