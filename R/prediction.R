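#' Per-person summaries of the daily composite
#'
#' The daily composite is the mean of the two item responses. Over each
#' person's in-window ratings this computes the mean, sample SD, minimum,
#' maximum, least-squares slope per day (on the calendar day offset, so
#' gaps matter) and the number of rating days. SD and slope are `NA` when
#' fewer than 2 rating days are available.
#'
#' @param daily filtered daily table (in-window rows only).
#' @return Data frame with one row per person: `person_id`, `mean`, `sd`,
#'   `min`, `max`, `slope`, `n_days`.
#' @export
summarize_daily <- function(daily) {
  f <- factor(daily$person_id)
  comp <- (daily$item1 + daily$item2) / 2
  one <- function(idx) {
    s <- comp[idx]
    d <- daily$day[idx]
    n <- length(s)
    slope <- if (n >= 2L && length(unique(d)) >= 2L)
      unname(stats::coef(stats::lm.fit(cbind(1, d), s))[2]) else NA_real_
    c(mean = mean(s), sd = if (n >= 2L) stats::sd(s) else NA_real_,
      min = min(s), max = max(s), slope = slope, n_days = n)
  }
  m <- t(vapply(split(seq_along(comp), f), one, numeric(6)))
  out <- data.frame(person_id = levels(f), m, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

model_predictor_sets <- function() {
  list(`1` = "phq9_week4",
       `2` = "phq2_mean",
       `3` = c("phq9_week4", "phq2_mean"),
       `4` = c("phq2_mean", "phq2_slope", "phq2_max", "phq2_min",
               "phq2_sd"))
}

#' Assemble design and outcome matrices for one prediction model
#'
#' Predictor rosters: model 1 — anchor-week questionnaire sum only;
#' model 2 — daily composite mean only; model 3 — both; model 4 — daily
#' mean, slope, maximum, minimum and SD. Both outcome equations (week-8
#' questionnaire sum and week-8 disability sum) share the same design.
#' Persons missing any required predictor or either outcome are dropped
#' listwise; an intercept column is always included.
#'
#' @param panel panel table (anchor- and outcome-week rows used).
#' @param summaries output of [summarize_daily()].
#' @param model_id 1, 2, 3 or 4.
#' @param anchor_week,outcome_week study weeks.
#' @return List with `X` (design matrix incl. intercept), `Y` (2-column
#'   outcome matrix `phq9_wk8`, `sds_wk8`), `n`, `person_id`.
#' @export
build_model_matrices <- function(panel, summaries, model_id,
                                 anchor_week = 4L, outcome_week = 8L) {
  model_id <- as.character(model_id)
  roster <- model_predictor_sets()[[model_id]]
  if (is.null(roster)) stop("model_id must be 1..4", call. = FALSE)
  a <- panel[panel$week == anchor_week, c("person_id", "phq9_sum")]
  o <- panel[panel$week == outcome_week,
             c("person_id", "phq9_sum", "sds_sum")]
  names(a)[2] <- "phq9_week4"
  names(o)[2:3] <- c("phq9_wk8", "sds_wk8")
  s <- summaries
  names(s)[match(c("mean", "sd", "min", "max", "slope"), names(s))] <-
    c("phq2_mean", "phq2_sd", "phq2_min", "phq2_max", "phq2_slope")
  df <- merge(merge(a, s, by = "person_id"), o, by = "person_id")
  keep <- stats::complete.cases(df[, c(roster, "phq9_wk8", "sds_wk8")])
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("empty design after listwise deletion", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, roster, drop = FALSE]))
  Y <- as.matrix(df[, c("phq9_wk8", "sds_wk8")])
  list(X = X, Y = Y, n = nrow(df), person_id = df$person_id,
       model_id = model_id)
}

#' Seemingly unrelated regression by feasible generalized least squares
#'
#' Two-step FGLS for a system of equations: per-equation OLS, residual
#' covariance from the OLS residuals (ML divisor `n`), then joint GLS on
#' the stacked system. With identical regressors across equations the GLS
#' estimate coincides with per-equation OLS (Kruskal), but the
#' cross-equation residual covariance still sharpens joint inference.
#' Optionally iterates the residual-covariance / GLS steps to convergence.
#'
#' @param X design matrix shared by the equations, or a list of one design
#'   per equation.
#' @param Y matrix with one outcome column per equation.
#' @param iterate iterate FGLS until the coefficients stabilize.
#' @param max_iter,tol iteration control.
#' @return Object of class `phq_sur`: per-equation `coefficients`, `se`,
#'   `z`, `p` (asymptotic normal), `sigma` (residual covariance), `r2`,
#'   `n`, `iterations`.
#' @export
fit_sur <- function(X, Y, iterate = FALSE, max_iter = 50L, tol = 1e-10) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  Xs <- if (is.list(X)) X else rep(list(X), k)
  stopifnot(length(Xs) == k)
  n <- nrow(Y)
  for (j in seq_len(k)) {
    qr_j <- qr(Xs[[j]])
    if (qr_j$rank < ncol(Xs[[j]])) {
      bad <- colnames(Xs[[j]])[setdiff(seq_len(ncol(Xs[[j]])),
                                       qr_j$pivot[seq_len(qr_j$rank)])]
      stop("singular design in equation ", j, ": collinear column(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  ols <- lapply(seq_len(k), function(j) qr.coef(qr(Xs[[j]]), Y[, j]))
  resid_of <- function(beta) {
    sapply(seq_len(k), function(j) Y[, j] - drop(Xs[[j]] %*% beta[[j]]))
  }
  beta <- ols
  it <- 0L
  repeat {
    E <- resid_of(beta)
    Sigma <- crossprod(E) / n
    Om_inv <- solve(Sigma)
    # stacked GLS: solve sum_j sum_l winv[j,l] X_j' X_l style normal eqns
    pdims <- vapply(Xs, ncol, 1L)
    off <- c(0L, cumsum(pdims))
    A <- matrix(0, sum(pdims), sum(pdims))
    b <- numeric(sum(pdims))
    for (j in seq_len(k)) for (l in seq_len(k)) {
      A[off[j] + seq_len(pdims[j]), off[l] + seq_len(pdims[l])] <-
        Om_inv[j, l] * crossprod(Xs[[j]], Xs[[l]])
    }
    for (j in seq_len(k)) {
      b[off[j] + seq_len(pdims[j])] <-
        rowSums(sapply(seq_len(k), function(l)
          Om_inv[j, l] * crossprod(Xs[[j]], Y[, l])))
    }
    bvec <- solve(A, b)
    new_beta <- lapply(seq_len(k), function(j) {
      v <- bvec[off[j] + seq_len(pdims[j])]
      names(v) <- colnames(Xs[[j]])
      v
    })
    it <- it + 1L
    delta <- max(abs(unlist(new_beta) - unlist(beta)))
    beta <- new_beta
    if (!iterate || delta < tol || it >= max_iter) break
  }
  E <- resid_of(beta)
  Sigma <- crossprod(E) / n
  V <- solve(A)
  pdims <- vapply(Xs, ncol, 1L)
  off <- c(0L, cumsum(pdims))
  eqs <- lapply(seq_len(k), function(j) {
    se <- sqrt(diag(V)[off[j] + seq_len(pdims[j])])
    z <- beta[[j]] / se
    sst <- sum((Y[, j] - mean(Y[, j]))^2)
    list(coefficients = beta[[j]], se = se, z = z,
         p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         r2 = 1 - sum(E[, j]^2) / sst)
  })
  names(eqs) <- colnames(Y)
  structure(list(equations = eqs, sigma = Sigma, n = n, iterations = it,
                 r2 = vapply(eqs, `[[`, numeric(1), "r2")),
            class = "phq_sur")
}

#' @export
print.phq_sur <- function(x, ...) {
  cat(sprintf("Seemingly unrelated regression (FGLS), n = %d\n", x$n))
  for (nm in names(x$equations)) {
    eq <- x$equations[[nm]]
    cat(sprintf("  %s: R2 = %.3f\n", nm, eq$r2))
    tab <- cbind(estimate = eq$coefficients, se = eq$se, p = eq$p)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Fit the four outcome-prediction models and tabulate them
#'
#' Builds the four predictor rosters over the same cohort, fits each by
#' SUR, and returns a comparison table of coefficients, p-values,
#' R-squared and analysis N per model (persons with undefined slope/SD are
#' dropped from model 4 only, so Ns can differ across models).
#'
#' @param panel panel table.
#' @param summaries output of [summarize_daily()].
#' @param models integer vector of model ids to fit.
#' @param anchor_week,outcome_week study weeks.
#' @param iterate iterate the FGLS step.
#' @return List of class `phq_prediction`: `fits` (per-model `phq_sur`),
#'   `table` (long data frame: model, outcome, term, estimate, p, r2, n).
#' @export
predict_report <- function(panel, summaries, models = 1:4,
                           anchor_week = 4L, outcome_week = 8L,
                           iterate = FALSE) {
  fits <- list()
  rows <- list()
  for (m in models) {
    mm <- build_model_matrices(panel, summaries, m, anchor_week,
                               outcome_week)
    fit <- fit_sur(mm$X, mm$Y, iterate = iterate)
    fits[[as.character(m)]] <- fit
    for (outc in names(fit$equations)) {
      eq <- fit$equations[[outc]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, outcome = outc,
        term = names(eq$coefficients),
        estimate = unname(eq$coefficients), se = unname(eq$se),
        p = unname(eq$p), r2 = eq$r2, n = fit$n,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(fits = fits, table = do.call(rbind, rows)),
            class = "phq_prediction")
}
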