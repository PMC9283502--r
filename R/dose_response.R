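# Three-parameter log-logistic dose-mortality model fitted by binomial
# maximum likelihood:  p(x) = d / (1 + (x/e)^(-b)),  lower limit 0.
# b is the slope (positive when mortality increases with dose), d the upper
# mortality limit in (0, 1], e the LC50 in dose units. p(e) = d/2 by design.

ll3_p <- function(x, b, d, e) d / (1 + (x / e)^(-b))

# negative binomial log-likelihood over positive-dose groups
ll3_nll <- function(theta, x, n, dead, fixed_d = NULL) {
  b <- exp(theta[1L])
  e <- exp(theta[length(theta)])
  d <- if (is.null(fixed_d)) stats::plogis(theta[2L]) else fixed_d
  p <- pmin(pmax(ll3_p(x, b, d, e), 1e-12), 1 - 1e-12)
  -sum(dead * log(p) + (n - dead) * log1p(-p))
}

#' Validate and pool a bioassay record table
#'
#' Pools counts per concentration (replicate structure is collapsed), checks
#' count invariants, splits off dose-0 control rows, and warns when control
#' mortality reaches 10%.
#'
#' @param records data.frame with columns `dose`, `n`, `dead` (extra columns
#'   such as `population`/`treatment` are ignored).
#' @return list with `groups` (pooled positive-dose data.frame) and
#'   `control_mortality` (proportion, NA when no control rows).
#' @export
pool_bioassay <- function(records) {
  stopifnot(all(c("dose", "n", "dead") %in% names(records)))
  if (any(records$dead < 0 | records$dead > records$n)) {
    stop_kdr("dead counts must satisfy 0 <= dead <= n", "kdr_invalid_bioassay")
  }
  if (any(records$dose < 0)) {
    stop_kdr("doses must be >= 0", "kdr_invalid_bioassay")
  }
  ctrl <- records[records$dose == 0, , drop = FALSE]
  pos <- records[records$dose > 0, , drop = FALSE]
  groups <- aggregate(cbind(n, dead) ~ dose, data = pos, FUN = sum)
  groups <- groups[order(groups$dose), , drop = FALSE]
  if (nrow(groups) < 3L) {
    stop_kdr("need >= 3 distinct positive concentrations", "kdr_invalid_bioassay")
  }
  control_mortality <- if (nrow(ctrl)) sum(ctrl$dead) / sum(ctrl$n) else NA_real_
  if (!is.na(control_mortality) && control_mortality >= 0.10) {
    warning(sprintf("control mortality %.1f%% >= 10%%", 100 * control_mortality))
  }
  list(groups = groups, control_mortality = control_mortality)
}

#' Fit the three-parameter log-logistic dose-mortality model
#'
#' Maximises the binomial likelihood of per-concentration mortality counts
#' under `p(x) = d / (1 + (x/e)^(-b))` over positive doses (controls are
#' excluded from the likelihood and only reported). Starting values come from
#' a coarse grid (b in 0.5/1/2/4, d in 0.9/1, e over the dose range); the best
#' starts are polished with BFGS to 1e-8 relative tolerance. When the upper
#' limit is driven to its boundary the model is refitted with d fixed at 1 and
#' one fewer parameter (flagged via `d_fixed`).
#'
#' @param records bioassay data.frame (see [pool_bioassay()]).
#' @return object of class `ll3_fit`: estimates `b`, `d`, `e` (LC50),
#'   `slope_se`, `vcov` (on the working scale log b / logit d / log e),
#'   `lc50_se`, `chi2`, `df`, `lc50_ci`, `d_fixed`, `control_mortality`,
#'   `groups`, `logLik`.
#' @export
fit_ll3 <- function(records) {
  pooled <- pool_bioassay(records)
  g <- pooled$groups
  x <- g$dose; n <- g$n; dead <- g$dead
  if (sum(dead) == 0L || sum(dead) == sum(n)) {
    stop_kdr("all-alive or all-dead across doses: LL.3 not identifiable",
             "kdr_nonidentifiable")
  }
  if (all(dead == 0L | dead == n)) {
    # every group saturated: the curve location is only interval-identified
    stop_kdr("no group with partial mortality: LL.3 not identifiable",
             "kdr_nonidentifiable")
  }

  starts <- expand.grid(
    b = c(0.5, 1, 2, 4), d = c(0.9, 1.0),
    e = exp(seq(log(min(x)), log(max(x)), length.out = 5))
  )
  # logit(1) is infinite; nudge inside
  theta_of <- function(b, d, e) c(log(b), stats::qlogis(pmin(d, 1 - 1e-6)), log(e))
  nlls <- apply(starts, 1L, function(s) ll3_nll(theta_of(s[1], s[2], s[3]), x, n, dead))
  best <- order(nlls)[1:3]
  fits <- lapply(best, function(i) {
    s <- starts[i, ]
    tryCatch(
      stats::optim(theta_of(s$b, s$d, s$e), ll3_nll, x = x, n = n, dead = dead,
                   method = "BFGS", hessian = FALSE,
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
  })
  fits <- Filter(function(f) !is.null(f) && f$convergence == 0, fits)
  if (!length(fits)) {
    stop_kdr("LL.3 optimisation failed to converge from all starts",
             "kdr_convergence_error")
  }
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  d_hat <- stats::plogis(fit$par[2L])
  d_fixed <- FALSE
  if (d_hat > 0.995) {
    # refit with d fixed at 1 (2-parameter model)
    fit2 <- stats::optim(fit$par[c(1L, 3L)], ll3_nll, x = x, n = n, dead = dead,
                         fixed_d = 1, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-10), hessian = TRUE)
    if (fit2$convergence != 0) {
      stop_kdr("LL.3 refit with fixed upper limit failed to converge",
               "kdr_convergence_error")
    }
    theta <- fit2$par
    H <- fit2$hessian
    b_hat <- exp(theta[1L]); d_hat <- 1; e_hat <- exp(theta[2L])
    df <- nrow(g) - 2L
    d_fixed <- TRUE
    par_names <- c("log_b", "log_e")
  } else {
    h <- stats::optimHess(fit$par, ll3_nll, x = x, n = n, dead = dead)
    theta <- fit$par
    H <- h
    b_hat <- exp(theta[1L]); e_hat <- exp(theta[3L])
    df <- nrow(g) - 3L
    par_names <- c("log_b", "logit_d", "log_e")
  }
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
    vcov <- matrix(NA_real_, nrow(H), ncol(H))
  }
  dimnames(vcov) <- list(par_names, par_names)
  ke <- length(par_names)
  lc50_se <- e_hat * sqrt(vcov[ke, ke])           # delta method from log e
  slope_se <- b_hat * sqrt(vcov[1L, 1L])          # delta method from log b

  p_hat <- ll3_p(x, b_hat, d_hat, e_hat)
  chi2 <- sum((dead - n * p_hat)^2 / (n * p_hat * (1 - p_hat)))

  out <- structure(
    list(
      b = b_hat, d = d_hat, e = e_hat,
      slope_se = slope_se, lc50_se = lc50_se, vcov = vcov,
      chi2 = chi2, df = df, d_fixed = d_fixed,
      control_mortality = pooled$control_mortality,
      groups = g, logLik = -if (d_fixed) fit2$value else fit$value
    ),
    class = "ll3_fit"
  )
  out$lc50_ci <- lc50_interval(out)
  out
}

#' @export
print.ll3_fit <- function(x, ...) {
  cat(sprintf(
    "<ll3_fit> LC50 %.4g (95%% CI %.4g-%.4g), slope %.3g +/- %.3g, d %.3g%s, chi2 %.3g on %d df\n",
    x$e, x$lc50_ci[1], x$lc50_ci[2], x$b, x$slope_se, x$d,
    if (x$d_fixed) " (fixed)" else "", x$chi2, x$df
  ))
  invisible(x)
}

#' Delta-method Wald 95% interval for the LC50
#'
#' @param fit an `ll3_fit`.
#' @return numeric length-2 vector; the lower bound is truncated at 0.
#' @export
lc50_interval <- function(fit) {
  if (!is.finite(fit$lc50_se)) {
    stop_kdr("singular covariance: no LC50 interval available", "kdr_inference_error")
  }
  c(max(0, fit$e - 1.96 * fit$lc50_se), fit$e + 1.96 * fit$lc50_se)
}

#' Pearson chi-square lack-of-fit test for an LL.3 fit
#'
#' `chi2 = sum (dead - n p)^2 / (n p (1-p))` over positive-dose groups;
#' `df = groups - 3` (or `groups - 2` when the upper limit was fixed at 1).
#'
#' @param fit an `ll3_fit`.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
lack_of_fit <- function(fit) {
  list(chi2 = fit$chi2, df = fit$df,
       p_value = stats::pchisq(fit$chi2, fit$df, lower.tail = FALSE))
}

#' Resistance or synergist ratio of two LC50s
#'
#' Ratio of LC50 point estimates (numerator / denominator); following the
#' source analyses, the two LC50s are declared significantly different when
#' their 95% confidence intervals do not overlap.
#'
#' @param fit_num,fit_den `ll3_fit`s (e.g. test population over susceptible
#'   reference for RR; untreated over synergist-treated for SR).
#' @param kind `"RR"` or `"SR"` (label only).
#' @return list with `ratio`, `kind`, `significant`, and the two CIs.
#' @export
ratio <- function(fit_num, fit_den, kind = c("RR", "SR")) {
  kind <- match.arg(kind)
  ci_n <- fit_num$lc50_ci
  ci_d <- fit_den$lc50_ci
  list(
    ratio = fit_num$e / fit_den$e, kind = kind,
    significant = (ci_n[1] > ci_d[2]) || (ci_d[1] > ci_n[2]),
    ci_num = ci_n, ci_den = ci_d
  )
}
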