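# Genotype-phenotype association and allele-frequency trend statistics:
# resistant allele frequency (RAF), exact 2xk contingency tests by full
# enumeration, allele-count odds ratios, and the binomial logit model with
# equal-weight pooling of per-location contrasts.

#' Build a genotype count table for one (location, year, group) stratum
#'
#' @param location,year,group stratum labels; `group` is typically one of
#'   `moribund`, `survivor`, `pre`, `post`.
#' @param counts named non-negative integer vector; names must be a subset of
#'   [GENOTYPE_CLASSES_9] (missing classes count 0).
#' @return object of class `genotype_count_table` with `n = sum(counts)`.
#' @export
genotype_count_table <- function(location, year, group, counts) {
  bad <- setdiff(names(counts), GENOTYPE_CLASSES_9)
  if (length(bad)) {
    stop_kdr(paste("unknown genotype class(es):", paste(bad, collapse = ", ")),
             "kdr_invalid_counts")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_kdr("genotype counts must be non-negative integers", "kdr_invalid_counts")
  }
  full <- setNames(integer(9L), GENOTYPE_CLASSES_9)
  full[names(counts)] <- as.integer(counts)
  structure(
    list(location = location, year = year, group = group,
         counts = full, n = sum(full)),
    class = "genotype_count_table"
  )
}

#' @export
print.genotype_count_table <- function(x, ...) {
  cat(sprintf("<genotype_count_table> %s %s %s (n=%d)\n", x$location, x$year,
              x$group, x$n))
  print(x$counts)
  invisible(x)
}

# accept a genotype_count_table, a 9-class named vector, or a 3-vector
# (hom-wt, het, hom-mut) and return the 3-class margin at a locus
marginal_counts <- function(x, locus = c("1014", "918")) {
  locus <- match.arg(as.character(locus), c("1014", "918"))
  if (inherits(x, "genotype_count_table")) x <- x$counts
  if (length(x) == 3L && is.null(names(x))) {
    return(setNames(as.integer(x), c("hom-wt", "het", "hom-mut")))
  }
  stopifnot(all(names(x) %in% GENOTYPE_CLASSES_9))
  part <- if (locus == "1014") {
    substr(names(x), 1L, 3L)
  } else {
    substr(names(x), 5L, 7L)
  }
  zyg <- c("L/L" = "hom-wt", "L/F" = "het", "F/F" = "hom-mut",
           "M/M" = "hom-wt", "M/I" = "het", "I/I" = "hom-mut")[part]
  out <- tapply(as.integer(x), zyg, sum)
  setNames(as.integer(out[c("hom-wt", "het", "hom-mut")]),
           c("hom-wt", "het", "hom-mut"))
}

#' Resistant allele frequency (RAF) as a percentage
#'
#' `RAF = 100 * (2 * hom_mut + het) / (2n)` over n diploid individuals.
#'
#' @param x a `genotype_count_table`, a named 9-class count vector, or an
#'   unnamed length-3 vector `(hom-wt, het, hom-mut)`.
#' @param locus `"1014"` or `"918"` (which marginal to take from 9-class input).
#' @return RAF in percent (full precision; round at report time).
#' @export
raf <- function(x, locus = "1014") {
  m <- marginal_counts(x, locus)
  n <- sum(m)
  if (n == 0L) stop_kdr("empty sample: n = 0", "kdr_empty_sample")
  100 * (2 * m[["hom-mut"]] + m[["het"]]) / (2 * n)
}

#' Resistant/susceptible allele counts at one locus
#'
#' Heterozygotes contribute one allele to each class, homozygous mutants two
#' resistant alleles; `n_res + n_sus = 2n`.
#'
#' @inheritParams raf
#' @return list with `n_res`, `n_sus`.
#' @export
allele_counts <- function(x, locus = "1014") {
  m <- marginal_counts(x, locus)
  list(n_res = 2L * m[["hom-mut"]] + m[["het"]],
       n_sus = 2L * m[["hom-wt"]] + m[["het"]])
}

# log-probability of the first row `a` of a 2xk table given column margins
# `colsums` and first-row margin r1 (multivariate hypergeometric)
log_table_prob <- function(a, colsums, r1) {
  sum(lchoose(colsums, a)) - lchoose(sum(colsums), r1)
}

# enumerate p-value by iterating over all first rows consistent with the
# margins; the largest column is left implicit (determined by the row sum)
fisher_2xk_enumerate <- function(colsums, r1, log_p_obs) {
  k <- length(colsums)
  big <- which.max(colsums)
  rest <- setdiff(seq_len(k), big)
  pools <- lapply(colsums[rest], function(cj) 0:cj)
  grid <- as.matrix(expand.grid(pools, KEEP.OUT.ATTRS = FALSE))
  a_big <- r1 - rowSums(grid)
  ok <- a_big >= 0 & a_big <= colsums[big]
  grid <- grid[ok, , drop = FALSE]
  a_big <- a_big[ok]
  # vectorised log-probabilities
  lp <- lchoose(colsums[big], a_big) - lchoose(sum(colsums), r1)
  for (j in seq_along(rest)) lp <- lp + lchoose(colsums[rest[j]], grid[, j])
  sum(exp(lp[lp <= log_p_obs + 1e-7]))
}

#' Exact two-sided test for a 2 x k contingency table
#'
#' Computes the conventional two-sided exact p-value: the sum of the null
#' (fixed-margins, multivariate hypergeometric) probabilities of all tables
#' whose probability does not exceed that of the observed table (ties
#' included). Enumeration is over all first rows consistent with the margins;
#' when the enumeration size exceeds `max_tables`, a Monte Carlo estimate over
#' `mc_draws` Patefield-sampled null tables is returned instead (flagged).
#'
#' @param tab 2 x k matrix of non-negative integer counts (k <= 9). Columns
#'   with zero margin are dropped before testing.
#' @param max_tables enumeration budget (candidate first rows).
#' @param mc_draws Monte Carlo sample size for the fallback.
#' @param mc_seed seed for the fallback (logged in the result).
#' @return list with `p_value`, `method` (`"enumeration"` or `"monte-carlo"`),
#'   and `mc_seed` when applicable.
#' @export
fisher_exact <- function(tab, max_tables = 5e6, mc_draws = 1e6, mc_seed = 20190801) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, ncol(tab) <= 9L, all(tab >= 0), all(tab == round(tab)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) == 0L || any(rowSums(tab) == 0)) {
    stop_kdr("degenerate table: a zero row (or all-zero table)", "kdr_degenerate_table")
  }
  if (ncol(tab) == 1L) return(list(p_value = 1, method = "enumeration"))
  colsums <- colSums(tab)
  r1 <- sum(tab[1L, ])
  log_p_obs <- log_table_prob(tab[1L, ], colsums, r1)
  n_cand <- prod(colsums[-which.max(colsums)] + 1)
  if (n_cand <= max_tables) {
    p <- fisher_2xk_enumerate(colsums, r1, log_p_obs)
    return(list(p_value = min(1, p), method = "enumeration"))
  }
  # Monte Carlo fallback over null tables with the observed margins
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(mc_seed)
  sims <- stats::r2dtable(mc_draws, rowSums(tab), colsums)
  lp <- vapply(sims, function(s) log_table_prob(s[1L, ], colsums, r1), numeric(1))
  list(p_value = mean(lp <= log_p_obs + 1e-7), method = "monte-carlo",
       mc_seed = mc_seed)
}

#' Odds ratio for resistant-allele counts between two samples
#'
#' `OR = (post_res/post_sus) / (pre_res/pre_sus)` with Wald 95% CI
#' `exp(ln OR +/- 1.96 sqrt(sum 1/count))`. Any zero cell triggers the
#' Haldane-Anscombe 0.5 correction (flagged).
#'
#' @param pre,post lists with `n_res`, `n_sus` (see [allele_counts()]).
#' @return object of class `odds_ratio_result`: `estimate`, `ci`, `log_se`,
#'   `p_value` (Wald), `corrected`, `pooling = "single-location"`.
#' @export
allele_or <- function(pre, post) {
  cells <- c(pre$n_res, pre$n_sus, post$n_res, post$n_sus)
  corrected <- any(cells == 0)
  if (corrected) {
    warning("zero allele-count cell: applying Haldane-Anscombe 0.5 correction")
    cells <- cells + 0.5
  }
  est <- (cells[3] / cells[4]) / (cells[1] / cells[2])
  log_se <- sqrt(sum(1 / cells))
  z <- log(est) / log_se
  structure(
    list(
      estimate = est, ci = exp(log(est) + c(-1.96, 1.96) * log_se),
      log_se = log_se, p_value = 2 * stats::pnorm(-abs(z)),
      corrected = corrected, pooling = "single-location"
    ),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("<odds_ratio_result> OR %.2f (95%% CI %.2f-%.2f), p %.4g [%s]%s\n",
              x$estimate, x$ci[1], x$ci[2], x$p_value, x$pooling,
              if (isTRUE(x$corrected)) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Fit the binomial logit model for allele frequency over time and location
#'
#' Fits `logit P(resistant allele) ~ time * location` to allele counts by
#' iteratively reweighted least squares ([stats::glm()]). The interaction term
#' makes the model saturated in the 2 x L design, so fitted per-location log
#' odds equal the closed-form log odds of the raw counts.
#'
#' @param data data.frame with columns `location`, `time` (`"pre"`/`"post"`),
#'   `n_res`, `n_sus` (allele counts).
#' @return object of class `allele_glm`: the `glm` fit plus location/time
#'   bookkeeping.
#' @export
fit_allele_glm <- function(data) {
  stopifnot(all(c("location", "time", "n_res", "n_sus") %in% names(data)))
  data$time <- factor(data$time, levels = c("pre", "post"))
  data$location <- factor(data$location)
  if (anyNA(data$time)) {
    stop_kdr("time must be 'pre' or 'post'", "kdr_invalid_counts")
  }
  separation <- any(data$n_res == 0 | data$n_sus == 0)
  if (separation) {
    warning("zero allele-count cell(s): complete separation; estimates use a 0.5 correction")
    data$n_res <- data$n_res + 0.5
    data$n_sus <- data$n_sus + 0.5
  }
  form <- if (nlevels(data$location) > 1L) {
    cbind(n_res, n_sus) ~ time * location
  } else {
    cbind(n_res, n_sus) ~ time
  }
  fit <- stats::glm(form, family = stats::binomial("logit"), data = data)
  if (!fit$converged) stop_kdr("GLM did not converge", "kdr_convergence_error")
  structure(
    list(glm = fit, locations = levels(data$location), separation = separation),
    class = "allele_glm"
  )
}

# contrast vector (in coefficient space) for the post-minus-pre logit
# difference at one location
location_contrast <- function(fit, location) {
  grid <- data.frame(time = factor(c("pre", "post"), levels = c("pre", "post")),
                     location = factor(location, levels = fit$locations))
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$glm)), grid)
  mm[2L, ] - mm[1L, ]
}

or_from_contrast <- function(fit, cvec, pooling) {
  beta <- stats::coef(fit$glm)
  est <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% stats::vcov(fit$glm) %*% cvec))
  z <- est / se
  structure(
    list(
      estimate = exp(est), ci = exp(est + c(-1.96, 1.96) * se), log_se = se,
      p_value = 2 * stats::pnorm(-abs(z)), corrected = fit$separation,
      pooling = pooling
    ),
    class = "odds_ratio_result"
  )
}

#' Per-location odds ratios from the allele GLM
#'
#' @param fit an `allele_glm`.
#' @return named list of `odds_ratio_result`, one per location.
#' @export
location_or <- function(fit) {
  stopifnot(inherits(fit, "allele_glm"))
  out <- lapply(fit$locations, function(l) {
    or_from_contrast(fit, location_contrast(fit, l), "single-location")
  })
  names(out) <- fit$locations
  out
}

#' Equal-weight pooled odds ratio over locations
#'
#' Averages the per-location (post minus pre) logit differences with equal
#' weight and exponentiates -- the geometric mean of per-location allele-count
#' odds ratios -- with the CI taken from the averaged contrast's variance
#' under the interaction GLM (the estimated-marginal-means contrast).
#'
#' Given a bare numeric vector of per-location ORs instead of a fit, returns
#' just the geometric-mean estimate (no CI).
#'
#' @param fit an `allele_glm`, or a numeric vector of per-location ORs.
#' @return an `odds_ratio_result` (CI/p only available from a fit).
#' @export
pooled_or <- function(fit) {
  if (is.numeric(fit)) {
    return(structure(
      list(estimate = exp(mean(log(fit))), ci = c(NA_real_, NA_real_),
           log_se = NA_real_, p_value = NA_real_, corrected = FALSE,
           pooling = "equal-weight-over-locations"),
      class = "odds_ratio_result"
    ))
  }
  stopifnot(inherits(fit, "allele_glm"))
  cvecs <- lapply(fit$locations, function(l) location_contrast(fit, l))
  cvec <- Reduce(`+`, cvecs) / length(cvecs)
  or_from_contrast(fit, cvec, "equal-weight-over-locations")
}

#' Per-class genotype percentages and percentage-point shifts
#'
#' @param tab_a,tab_b `genotype_count_table`s (moribund vs survivor, or pre vs
#'   post application).
#' @return data.frame with class, counts, percentages (1 decimal, as printed
#'   in field reports) and `change = pct_b - pct_a` in percentage points.
#' @export
genotype_shift <- function(tab_a, tab_b) {
  stopifnot(inherits(tab_a, "genotype_count_table"),
            inherits(tab_b, "genotype_count_table"))
  pct <- function(t) if (t$n == 0L) rep(0, 9L) else round(100 * t$counts / t$n, 1)
  data.frame(
    class = GENOTYPE_CLASSES_9,
    count_a = unname(tab_a$counts), pct_a = unname(pct(tab_a)),
    count_b = unname(tab_b$counts), pct_b = unname(pct(tab_b)),
    change = unname(pct(tab_b) - pct(tab_a)),
    stringsAsFactors = FALSE
  )
}
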