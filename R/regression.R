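#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations over the numeric columns of an ingredient
#' table, with two-sided p-values from the t distribution on n - 2 degrees
#' of freedom.  Zero-variance columns yield NA correlations and a warning.
#'
#' @param records data frame of ingredient records.
#' @param vars columns to correlate; defaults to all numeric columns.
#' @return An object of class `correlation_matrix`: list with `labels`,
#'   symmetric matrices `r` and `p`, and `n`.
#' @examples
#' tab4 <- nep_fixture("table4_ingredients")
#' cm <- correlation_matrix(tab4)
#' cm$r["pd", "cp"]
#' @export
correlation_matrix <- function(records, vars = NULL) {
  records <- as.data.frame(records)
  if (is.null(vars)) {
    vars <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  x <- as.matrix(records[vars])
  if (anyNA(x)) stop("missing values in correlation input", call. = FALSE)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s): ",
            paste(vars[sds == 0], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(x))
  r[cbind(seq_along(vars), seq_along(vars))] <- ifelse(sds == 0, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  structure(list(labels = vars, r = r, p = p, n = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlations (n =", x$n, ")\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Seeded train/validation split
#'
#' Random, disjoint, exhaustive partition with `round(fraction * n)` rows in
#' the training set.  The split is drawn from its own RNG stream so that the
#' same seed always reproduces the same split without disturbing the
#' caller's RNG state.
#'
#' @param records data frame to split (n >= 5).
#' @param fraction training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return List with `train` and `valid` data frames.
#' @export
split_train_valid <- function(records, fraction = 0.7, seed = 1) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n < 5) stop("need at least 5 records to split", call. = FALSE)
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  }
  n_train <- round(fraction * n)
  if (n_train == 0 || n_train == n) {
    stop("fraction leaves an empty train or validation set", call. = FALSE)
  }
  idx <- local_seed_sample(n, n_train, seed)
  list(train = records[sort(idx), , drop = FALSE],
       valid = records[setdiff(seq_len(n), idx), , drop = FALSE])
}

# sample() under a temporary seed; restores the caller's RNG state
local_seed_sample <- function(n, size, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n, size)
}

#' Forward-backward stepwise regression at a p-value threshold
#'
#' Classical stepwise selection on partial-F (equivalently t) p-values: at
#' each step the excluded candidate with the smallest p below `p_enter` is
#' added, then any included term with p above `p_remove` is dropped
#' (largest p first).  Ties are broken by candidate order.  Terminates when
#' no move is possible; deterministic given the data.  Perfectly collinear
#' candidates are dropped (later-ordered loses) with a warning.
#'
#' @param train training data frame.
#' @param response response column name.
#' @param candidates candidate covariate names, in tie-break order.
#' @param p_enter,p_remove entry and removal thresholds.
#' @return An object of class `regression_model`: `response`, `terms`,
#'   `coefficients` (intercept first), the underlying `lm` fit, and training
#'   metrics `r2`, `rmse`, `aic`, `bic`, `n_train` (see [model_metrics()]).
#' @export
stepwise_fit <- function(train, response, candidates,
                         p_enter = 0.05, p_remove = 0.05) {
  train <- as.data.frame(train)
  stopifnot(response %in% names(train), all(candidates %in% names(train)))
  if (nrow(train) <= length(candidates) + 2) {
    stop("too few training rows for the candidate set", call. = FALSE)
  }
  candidates <- drop_collinear(train, candidates)
  selected <- character(0)
  repeat {
    moved <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        term_p(train, response, c(selected, v))[v]
      }, numeric(1))
      if (any(pvals < p_enter)) {
        selected <- c(selected, pool[which.min(pvals)])
        moved <- TRUE
      }
    }
    if (length(selected)) {
      pvals <- term_p(train, response, selected)[selected]
      if (max(pvals) > p_remove) {
        selected <- setdiff(selected, selected[which.max(pvals)])
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  fit_model(train, response, selected)
}

# p-values of each non-intercept term in the OLS fit response ~ terms
term_p <- function(data, response, terms) {
  f <- if (length(terms)) stats::reformulate(terms, response) else {
    stats::reformulate("1", response)
  }
  fit <- stats::lm(f, data = data)
  ct <- stats::coef(summary(fit))
  out <- ct[setdiff(rownames(ct), "(Intercept)"), 4]
  names(out) <- setdiff(rownames(ct), "(Intercept)")
  out
}

drop_collinear <- function(data, candidates) {
  if (length(candidates) < 2) return(candidates)
  x <- cbind(1, as.matrix(data[candidates]))
  keep <- qr(x)$pivot[seq_len(qr(x)$rank)]
  keep <- sort(setdiff(keep, 1L)) - 1L
  if (length(keep) < length(candidates)) {
    warning("dropping collinear candidate(s): ",
            paste(setdiff(candidates, candidates[keep]), collapse = ", "),
            call. = FALSE)
  }
  candidates[keep]
}

fit_model <- function(train, response, terms) {
  f <- if (length(terms)) stats::reformulate(terms, response) else {
    stats::reformulate("1", response)
  }
  fit <- stats::lm(f, data = train)
  m <- structure(list(response = response, terms = terms,
                      coefficients = stats::coef(fit), fit = fit,
                      n_train = nrow(train)),
                 class = "regression_model")
  m[c("r2", "rmse", "aic", "bic")] <- model_metrics(m, train)[
    c("r2", "rmse", "aic", "bic")]
  m
}

#' @export
print.regression_model <- function(x, digits = 2, ...) {
  co <- x$coefficients
  rhs <- if (length(x$terms)) {
    paste(sprintf("%+.*f x %s", digits, co[x$terms], x$terms),
          collapse = " ")
  } else ""
  cat(sprintf("%s = %.*f %s\n", x$response, digits, co[["(Intercept)"]], rhs))
  cat(sprintf("  n = %d, R2 = %.3f, RMSE = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$n_train, x$r2, x$rmse, x$aic, x$bic))
  invisible(x)
}

#' Training and validation metrics of a regression model
#'
#' Training metrics: `r2 = 1 - SSE/SST`, `rmse = sqrt(SSE/(n - k - 1))`,
#' `aic = n*log(SSE/n) + 2*(k + 1)` and `bic = n*log(SSE/n) + (k + 1)*log(n)`
#' with `k` the number of covariates.  The validation R-squared is the
#' squared Pearson correlation of predicted and observed responses on the
#' validation set.
#'
#' @param model a `regression_model` (from [stepwise_fit()]) or `lm` fit.
#' @param train training data (defaults to the data the model was fitted
#'   on).
#' @param valid optional validation data frame.
#' @return Named list: `r2`, `rmse`, `aic`, `bic` and (when `valid` is
#'   given) `validation_r2`.
#' @export
model_metrics <- function(model, train = NULL, valid = NULL) {
  if (inherits(model, "regression_model")) {
    fit <- model$fit
    response <- model$response
    k <- length(model$terms)
  } else {
    fit <- model
    response <- all.vars(stats::formula(fit))[1]
    k <- length(stats::coef(fit)) - 1L
  }
  if (is.null(train)) train <- stats::model.frame(fit)
  n <- nrow(train)
  if (n <= k + 1) stop("too few rows for the residual degrees of freedom",
                       call. = FALSE)
  obs <- train[[response]]
  sse <- sum((obs - stats::predict(fit, train))^2)
  sst <- sum((obs - mean(obs))^2)
  out <- list(r2 = 1 - sse / sst,
              rmse = sqrt(sse / (n - k - 1)),
              aic = n * log(sse / n) + 2 * (k + 1),
              bic = n * log(sse / n) + (k + 1) * log(n))
  if (!is.null(valid)) {
    pred <- stats::predict(fit, valid)
    out$validation_r2 <- suppressWarnings(
      stats::cor(pred, valid[[response]])^2)
  }
  out
}

#' Ladder of prediction models for PD and LD
#'
#' For each response, builds the sequence of forward-selection models of
#' increasing size up to the full candidate set (a machine-readable
#' analogue of a stepwise model-comparison table), evaluates every model on
#' a seeded 70/30 train/validation split, marks which rows lie on the
#' stepwise path at `p_enter`, and flags the criterion-optimal row: the
#' model winning the majority of {highest R2, highest validation R2, lowest
#' RMSE, lowest AIC, lowest BIC}, smaller models winning ties.
#'
#' @param records ingredient table with the candidate columns and
#'   responses.
#' @param responses response column names.
#' @param candidates candidate covariates.
#' @param seed seed for the split.
#' @param fraction training fraction.
#' @param p_enter,p_remove stepwise thresholds.
#' @return A data frame of class `model_ladder`: one row per model with
#'   `response`, `n_terms`, `terms` (collapsed by `+`), one coefficient
#'   column per candidate, metrics, `stepwise` and `optimal` flags.
#' @export
model_table <- function(records, responses = c("pd", "ld"),
                        candidates = c("ge", "cp", "ee", "starch",
                                       "ndf", "adf", "ash"),
                        seed = 1, fraction = 0.7,
                        p_enter = 0.05, p_remove = 0.05) {
  records <- as.data.frame(records)
  split <- split_train_valid(records, fraction = fraction, seed = seed)
  rows <- list()
  for (response in responses) {
    cands <- drop_collinear(split$train, candidates)
    path <- character(0)
    ladder <- list()
    while (length(path) < length(cands)) {
      pool <- setdiff(cands, path)
      pvals <- vapply(pool, function(v) {
        term_p(split$train, response, c(path, v))[v]
      }, numeric(1))
      path <- c(path, pool[which.min(pvals)])
      ladder[[length(path)]] <- path
    }
    selected <- stepwise_fit(split$train, response, cands,
                             p_enter = p_enter, p_remove = p_remove)$terms
    for (terms in ladder) {
      m <- fit_model(split$train, response, terms)
      met <- model_metrics(m, split$train, split$valid)
      row <- data.frame(response = response, n_terms = length(terms),
                        terms = paste(terms, collapse = "+"),
                        intercept = m$coefficients[["(Intercept)"]],
                        stringsAsFactors = FALSE)
      for (v in candidates) {
        row[[v]] <- if (v %in% terms) m$coefficients[[v]] else NA_real_
      }
      row$r2 <- met$r2
      row$rmse <- met$rmse
      row$aic <- met$aic
      row$bic <- met$bic
      row$validation_r2 <- met$validation_r2
      row$stepwise <- setequal(terms, selected)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$optimal <- FALSE
  for (response in responses) {
    i <- which(out$response == response)
    votes <- rep(0, length(i))
    for (m in c("r2", "validation_r2")) {
      votes[best_rows(out[[m]][i], decreasing = TRUE)] <-
        votes[best_rows(out[[m]][i], decreasing = TRUE)] + 1
    }
    for (m in c("rmse", "aic", "bic")) {
      votes[best_rows(out[[m]][i], decreasing = FALSE)] <-
        votes[best_rows(out[[m]][i], decreasing = FALSE)] + 1
    }
    out$optimal[i[which.max(votes)]] <- TRUE  # ties: smallest model wins
  }
  rownames(out) <- NULL
  class(out) <- c("model_ladder", "data.frame")
  attr(out, "n_train") <- nrow(split$train)
  attr(out, "n_valid") <- nrow(split$valid)
  out
}

best_rows <- function(x, decreasing) {
  r <- round(x, 10)
  which(r == if (decreasing) max(r) else min(r))
}
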