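# Marginal Gaussian likelihood for the joint model.
#
# For person j with n_j daily 2-item vectors y_j1..y_jn and questionnaire
# p-vector z_j, the stacked (p + 2 n_j)-vector is multivariate normal with
#   Cov(z_j)        = S_qq
#   Cov(z_j, y_ji)  = S_qy                      (same for every day)
#   Cov(y_ji, y_ji')= S_b          (i != i')    (person-level component)
#   Cov(y_ji, y_ji) = S_b + S_w                 (plus the day-level part)
# and mean (mu_q, mu_y, mu_y, ...). Days are exchangeable under this
# structure, so an orthogonal within-person transformation splits each
# person's likelihood exactly into
#   (a) n_j - 1 independent within-day contrasts, iid N(0, S_w), whose
#       contribution depends on the data only through the pooled
#       within-person scatter matrix, and
#   (b) the (p + 2)-vector (z_j, ybar_j) with Cov(ybar) = S_b + S_w / n_j
#       and Cov(z, ybar) = S_qy.
# Persons are grouped by (has questionnaire, n_j) and each group is
# evaluated from sufficient statistics (mean and centered scatter of the
# reduced vector), so one likelihood evaluation costs O(groups * (p+2)^3)
# independent of the number of persons or of cluster sizes.

#' Prepare grouped sufficient statistics for the joint FIML likelihood
#'
#' Persons missing the questionnaire block or all daily rows contribute the
#' marginal density of their observed block only. Daily rows with a missing
#' item and questionnaire rows with missing items are dropped (the
#' likelihood requires complete vectors within a block).
#'
#' @param daily long daily table (filtered sample).
#' @param panel panel table; its anchor-week rows supply the questionnaire
#'   vectors.
#' @param anchor_week week whose panel rows enter the factor model.
#' @param n_items number of questionnaire items to use (first `n_items`
#'   item columns); smaller rosters are useful for reduced-scale
#'   simulation studies.
#' @return Object of class `phq_cfa_data`: list of groups, each with
#'   `has_q`, `n_days`, `m` (person count), `xbar`, `scatter`; plus item
#'   summary statistics used for starting values.
#' @export
prepare_cfa_data <- function(daily, panel, anchor_week = 4L, n_items = 9L) {
  item_cols <- panel_item_cols()[seq_len(n_items)]
  pr <- panel[panel$week == anchor_week, , drop = FALSE]
  z <- as.matrix(pr[, item_cols, drop = FALSE])
  keep <- stats::complete.cases(z)
  z <- z[keep, , drop = FALSE]
  z_ids <- pr$person_id[keep]

  dr <- daily[stats::complete.cases(daily[, c("item1", "item2")]), ,
              drop = FALSE]
  ids <- sort(unique(c(z_ids, dr$person_id)))
  zi <- match(ids, z_ids)
  f <- factor(dr$person_id, levels = ids)
  n_days <- as.integer(table(f))
  ord <- order(dr$person_id, dr$day, method = "radix")
  dr <- dr[ord, , drop = FALSE]

  # split daily rows per person (already sorted by person)
  y_split <- split(seq_len(nrow(dr)), factor(dr$person_id, levels = ids))

  # pooled within-person scatter of the daily items and per-person means
  ybar <- matrix(NA_real_, length(ids), 2L)
  W_sum <- matrix(0, 2L, 2L)
  df_within <- 0L
  for (j in seq_along(ids)) {
    rows <- y_split[[j]]
    if (!length(rows)) next
    Y <- cbind(dr$item1[rows], dr$item2[rows])
    mu <- colMeans(Y)
    ybar[j, ] <- mu
    if (nrow(Y) > 1L) {
      Yc <- sweep(Y, 2L, mu)
      W_sum <- W_sum + crossprod(Yc)
      df_within <- df_within + nrow(Y) - 1L
    }
  }

  key <- paste(!is.na(zi), n_days)
  groups <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    has_q <- !is.na(zi[sel[1]])
    nd <- n_days[sel[1]]
    if (!has_q && nd == 0L) next
    X <- cbind(if (has_q) z[zi[sel], , drop = FALSE],
               if (nd > 0L) ybar[sel, , drop = FALSE])
    m <- nrow(X)
    xbar <- colMeans(X)
    Xc <- sweep(X, 2L, xbar)
    groups[[length(groups) + 1L]] <-
      list(has_q = has_q, n_days = nd, m = m, xbar = xbar,
           scatter = crossprod(Xc))
  }
  item_means <- colMeans(z)
  item_vars <- apply(z, 2L, stats::var)
  structure(list(groups = groups, W_sum = W_sum,
                 df_within = as.integer(df_within),
                 n_items = as.integer(n_items),
                 n_persons = length(ids), person_ids = ids,
                 q_means = item_means, q_vars = item_vars,
                 y_means = c(mean(dr$item1), mean(dr$item2)),
                 y_vars = c(stats::var(dr$item1), stats::var(dr$item2)),
                 n_daily_rows = nrow(dr)),
            class = "phq_cfa_data")
}

# Stacked covariance and mean for one group given moment blocks.
stack_moments <- function(blocks, has_q, n_days) {
  p <- length(blocks$mu_q)
  if (has_q && n_days > 0L) {
    # days are stacked day-major (item1, item2 per day)
    top <- cbind(blocks$S_qq, matrix(1, 1L, n_days) %x% blocks$S_qy)
    yy <- diag(n_days) %x% blocks$S_w +
      matrix(1, n_days, n_days) %x% blocks$S_b
    bottom <- cbind(matrix(1, n_days, 1L) %x% t(blocks$S_qy), yy)
    list(mu = c(blocks$mu_q, rep.int(blocks$mu_y, n_days)),
         S = rbind(top, bottom))
  } else if (has_q) {
    list(mu = blocks$mu_q, S = blocks$S_qq)
  } else {
    yy <- diag(n_days) %x% blocks$S_w +
      matrix(1, n_days, n_days) %x% blocks$S_b
    list(mu = rep.int(blocks$mu_y, n_days), S = yy)
  }
}

#' Joint marginal log-likelihood of a parameter set
#'
#' Evaluates the full-information Gaussian log-likelihood of prepared data
#' under the moment structure implied by `params` (latents integrated out
#' analytically).
#'
#' @param params a `phq_params` object (questionnaire roster length must
#'   match the prepared data).
#' @param data a `phq_cfa_data` object from [prepare_cfa_data()].
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(params, data) {
  stopifnot(inherits(data, "phq_cfa_data"))
  if (length(params$lambda_q) != data$n_items)
    stop("parameter roster does not match prepared data", call. = FALSE)
  blocks_loglik(implied_blocks(params), data)
}

# Core evaluator shared by the structured, saturated and independence
# models: takes arbitrary moment blocks.
blocks_loglik <- function(blocks, data) {
  ll <- 0
  if (data$df_within > 0L) {
    Lw <- tryCatch(chol(blocks$S_w), error = function(e) NULL)
    if (is.null(Lw))
      stop("implied within-level covariance not positive definite",
           call. = FALSE)
    Swinv <- chol2inv(Lw)
    ll <- ll - 0.5 * (data$df_within *
                        (2 * log(2 * pi) + 2 * sum(log(diag(Lw)))) +
                      sum(Swinv * data$W_sum))
  }
  for (g in data$groups) {
    if (g$has_q && g$n_days > 0L) {
      Syy <- blocks$S_b + blocks$S_w / g$n_days
      S <- rbind(cbind(blocks$S_qq, blocks$S_qy),
                 cbind(t(blocks$S_qy), Syy))
      mu <- c(blocks$mu_q, blocks$mu_y)
    } else if (g$has_q) {
      S <- blocks$S_qq
      mu <- blocks$mu_q
    } else {
      S <- blocks$S_b + blocks$S_w / g$n_days
      mu <- blocks$mu_y
    }
    d <- length(mu)
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L))
      stop(sprintf(
        "implied covariance not positive definite (block: %s, %d days, dim %d)",
        if (g$has_q) "questionnaire+daily" else "daily only", g$n_days, d),
        call. = FALSE)
    Sinv <- chol2inv(L)
    dev <- g$xbar - mu
    quad <- sum(Sinv * g$scatter) + g$m * drop(crossprod(dev, Sinv %*% dev))
    ll <- ll - 0.5 * (g$m * (d * log(2 * pi) + 2 * sum(log(diag(L)))) + quad)
    # Jacobian of the (day-mean, contrasts) transform: the day mean uses
    # weight 1/n rather than the orthonormal 1/sqrt(n), contributing
    # -log(n) per person across the two items.
    if (g$n_days > 0L) ll <- ll - g$m * log(g$n_days)
  }
  ll
}

# Relaxed evaluator used inside optimization: returns -Inf on a
# non-positive-definite proposal instead of erroring, so line searches can
# back off.
blocks_loglik_safe <- function(blocks, data) {
  tryCatch(blocks_loglik(blocks, data), error = function(e) -Inf)
}

#' Dense-covariance log-density oracle
#'
#' Reference implementation that assembles, for every person, the full
#' stacked mean and covariance and evaluates the multivariate normal
#' log-density directly — no grouping, no sufficient statistics. Intended
#' for validating [marginal_loglik()] on small instances.
#'
#' @param params a `phq_params` object.
#' @param daily,panel filtered tables.
#' @param anchor_week anchor week.
#' @param n_items questionnaire roster size.
#' @return Scalar log-likelihood.
#' @export
dense_loglik <- function(params, daily, panel, anchor_week = 4L,
                         n_items = length(params$lambda_q)) {
  blocks <- implied_blocks(params)
  item_cols <- panel_item_cols()[seq_len(n_items)]
  pr <- panel[panel$week == anchor_week, , drop = FALSE]
  ids <- sort(unique(c(pr$person_id, daily$person_id)))
  ll <- 0
  for (id in ids) {
    zrow <- pr[pr$person_id == id, item_cols, drop = FALSE]
    z <- if (nrow(zrow) && all(!is.na(zrow))) as.numeric(zrow[1, ]) else NULL
    dsub <- daily[daily$person_id == id, , drop = FALSE]
    dsub <- dsub[order(dsub$day), , drop = FALSE]
    n <- nrow(dsub)
    has_q <- !is.null(z)
    if (!has_q && n == 0L) next
    sm <- stack_moments(blocks, has_q, n)
    x <- c(if (has_q) z, if (n > 0L) as.vector(rbind(dsub$item1, dsub$item2)))
    d <- length(x)
    L <- chol(sm$S)
    dev <- x - sm$mu
    w <- backsolve(L, dev, transpose = TRUE)
    ll <- ll - 0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + sum(w^2))
  }
  ll
}
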