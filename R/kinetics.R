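# One-phase exponential decay fits for in vitro plasmid-cleavage time
# courses: y(t) = A * exp(-t / tau) + c, with k = 1/tau the cleavage rate
# constant. The assay follows consumption of the intact circular plasmid
# under single-turnover conditions, so the plateau is fixed at zero by
# default; a free plateau is available for incomplete cleavage.

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `y(t) = A * exp(-t/tau) + c` to one replicate's
#' time course. Initialization comes from a log-linear regression; the fit
#' is then refined with [stats::nls()] (port algorithm) and falls back to
#' Nelder-Mead on the residual sum of squares if `nls` fails. Fits are
#' unweighted.
#'
#' @param timepoints seconds, strictly increasing, length >= 3.
#' @param intact_fraction intact-plasmid fraction in [0, 1].
#' @param plateau `"fixed0"` (default; single-turnover consumption) or
#'   `"free"`.
#' @return an object of class `decay_fit`: `A`, `k` (1/s), `tau` (s),
#'   `plateau`, `rss`, `converged` and `flag` (`"no_decay"` for
#'   non-decreasing series, with `k` unset).
#' @export
fit_decay <- function(timepoints, intact_fraction,
                      plateau = c("fixed0", "free")) {
  plateau <- match.arg(plateau)
  t <- as.numeric(timepoints)
  y <- as.numeric(intact_fraction)
  if (length(t) < 3) stopf("need at least 3 timepoints")
  if (length(t) != length(y)) stopf("timepoints and fractions differ in length")
  if (is.unsorted(t, strictly = TRUE)) stopf("timepoints must be strictly increasing")
  if (any(y < -1e-9 | y > 1 + 1e-9)) stopf("intact fractions must lie in [0, 1]")

  if (all(diff(y) >= 0)) {
    return(structure(list(A = NA_real_, k = NA_real_, tau = NA_real_,
                          plateau = if (plateau == "fixed0") 0 else NA_real_,
                          rss = NA_real_, converged = FALSE,
                          flag = "no_decay", n = length(t)),
                     class = "decay_fit"))
  }

  c0 <- if (plateau == "fixed0") 0 else max(min(y), 0)
  pos <- which(y - c0 > 1e-12)
  if (length(pos) >= 2) {
    lf <- stats::lm(log(y[pos] - c0) ~ t[pos])
    A0 <- exp(unname(stats::coef(lf)[1]))
    k0 <- max(-unname(stats::coef(lf)[2]), 1e-12)
  } else {
    A0 <- max(y) - c0
    k0 <- 1 / max(t[length(t)], 1e-12)
  }
  tau0 <- 1 / k0

  rss_of <- function(par) {
    A <- par[1]; tau <- par[2]; cc <- if (plateau == "free") par[3] else 0
    if (tau <= 0) return(Inf)
    sum((y - (A * exp(-t / tau) + cc))^2)
  }
  start_par <- if (plateau == "free") c(A0, tau0, c0) else c(A0, tau0)
  best <- list(par = start_par, rss = rss_of(start_par), converged = TRUE)

  fitted <- tryCatch({
    if (plateau == "free") {
      fm <- stats::nls(y ~ A * exp(-t / tau) + cc,
                       start = list(A = A0, tau = tau0, cc = c0),
                       algorithm = "port",
                       lower = c(A = 0, tau = 1e-12, cc = -0.5),
                       control = stats::nls.control(maxiter = 200))
    } else {
      fm <- stats::nls(y ~ A * exp(-t / tau),
                       start = list(A = A0, tau = tau0),
                       algorithm = "port",
                       lower = c(A = 0, tau = 1e-12),
                       control = stats::nls.control(maxiter = 200))
    }
    par <- unname(stats::coef(fm))
    list(par = par, rss = sum(stats::resid(fm)^2), converged = TRUE)
  }, error = function(e) NULL)
  if (!is.null(fitted) && fitted$rss <= best$rss + 1e-15) best <- fitted

  if (is.null(fitted)) {
    # nls failed (e.g. zero-residual start): polish with Nelder-Mead
    om <- stats::optim(start_par, rss_of, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    if (om$value < best$rss) {
      best <- list(par = om$par, rss = om$value, converged = om$convergence == 0)
    }
  }

  A <- best$par[1]; tau <- best$par[2]
  cc <- if (plateau == "free") best$par[3] else 0
  k <- 1 / tau
  flag <- if (k <= 0) "no_decay" else NA_character_
  structure(list(A = A, k = k, tau = tau, plateau = cc,
                 rss = best$rss, converged = isTRUE(best$converged),
                 flag = flag, n = length(t)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!is.na(x$flag) && x$flag == "no_decay") {
    cat("Decay fit: no decay detected\n")
  } else {
    cat(sprintf("Decay fit: k = %.4g 1/s (tau = %.4g s), plateau = %.3f, RSS = %.3g\n",
                x$k, x$tau, x$plateau, x$rss))
  }
  invisible(x)
}

#' Fit every replicate of a time-course table
#'
#' @param curves data.frame with columns `variant_id`, `target_id`,
#'   `replicate`, `t_seconds`, `intact_fraction`.
#' @param plateau passed to [fit_decay()].
#' @return data.frame of per-replicate fits (`k`, `tau`, `A`, `plateau`,
#'   `rss`, `converged`, `flag`).
#' @export
fit_decay_table <- function(curves, plateau = "fixed0") {
  assert_cols(curves, c("variant_id", "target_id", "replicate", "t_seconds",
                        "intact_fraction"), "time-course table")
  key <- interaction(curves$variant_id, curves$target_id, curves$replicate,
                     drop = TRUE)
  out <- lapply(split(curves, key), function(g) {
    g <- g[order(g$t_seconds), , drop = FALSE]
    f <- fit_decay(g$t_seconds, g$intact_fraction, plateau = plateau)
    data.frame(variant_id = g$variant_id[1], target_id = g$target_id[1],
               replicate = g$replicate[1], k = f$k, tau = f$tau, A = f$A,
               plateau = f$plateau, rss = f$rss, converged = f$converged,
               flag = f$flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize rate constants per variant/target and group
#'
#' Mean `k` across replicate fits for each (variant, target) pair, then
#' median/IQR per group (e.g. in cellulo cleavage category). Groups with
#' no converged fit are omitted with a warning.
#'
#' @param fits per-replicate fit table (see [fit_decay_table()]).
#' @param grouping data.frame with `variant_id`, `target_id`, `group`
#'   assigning each pair to a category; pairs without an assignment are
#'   dropped.
#' @return list with `per_pair` (mean k per variant/target) and
#'   `per_group` (n, median, IQR per group).
#' @export
summarize_rates <- function(fits, grouping = NULL) {
  assert_cols(fits, c("variant_id", "target_id", "replicate", "k",
                      "converged"), "fit table")
  conv <- fits[fits$converged & !is.na(fits$k), , drop = FALSE]
  key <- interaction(conv$variant_id, conv$target_id, drop = TRUE)
  per_pair <- do.call(rbind, lapply(split(conv, key), function(g) {
    data.frame(variant_id = g$variant_id[1], target_id = g$target_id[1],
               mean_k = mean(g$k), n_fits = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(per_pair) <- NULL
  if (is.null(grouping)) return(list(per_pair = per_pair, per_group = NULL))
  assert_cols(grouping, c("variant_id", "target_id", "group"), "grouping")
  merged <- merge(per_pair, grouping, by = c("variant_id", "target_id"))
  empty <- setdiff(unique(grouping$group), unique(merged$group))
  if (length(empty)) {
    warning(sprintf("group(s) with no converged fits omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  per_group <- do.call(rbind, lapply(split(merged, merged$group), function(g) {
    q <- stats::quantile(g$mean_k, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g$group[1], n = nrow(g), median_k = q[2],
               iqr_lo = q[1], iqr_hi = q[3], stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_pair = per_pair, per_group = per_group)
}

#' Compare two groups of rate constants
#'
#' Thin, routine-statistics wrapper: a Shapiro-Wilk normality screen
#' selects between Welch's two-sample t-test (both groups consistent with
#' normality) and the two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#' Either test can also be requested explicitly.
#'
#' @param group_a,group_b numeric vectors, each of length >= 3.
#' @param method `"auto"` (default), `"welch"` or `"wilcox"`.
#' @param shapiro_alpha normality-screen significance level.
#' @return list with `method`, `p_value`, `estimate` (difference of group
#'   medians, a - b) and `direction`.
#' @export
compare_rate_groups <- function(group_a, group_b, method = c("auto", "welch", "wilcox"),
                                shapiro_alpha = 0.05) {
  method <- match.arg(method)
  if (length(group_a) < 3 || length(group_b) < 3) {
    stopf("each group needs at least 3 values")
  }
  if (method == "auto") {
    normal <- function(x) {
      if (stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value > shapiro_alpha
    }
    method <- if (normal(group_a) && normal(group_b)) "welch" else "wilcox"
  }
  if (method == "welch") {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  } else {
    ht <- stats::wilcox.test(group_a, group_b, exact = TRUE)
  }
  est <- stats::median(group_a) - stats::median(group_b)
  list(method = method,
       p_value = unname(ht$p.value),
       estimate = est,
       direction = if (est > 0) "a > b" else if (est < 0) "a < b" else "none")
}
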