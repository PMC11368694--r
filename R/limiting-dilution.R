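#' Validate a limiting-dilution outcome table
#'
#' @param exp Data frame with columns dose, tested, responding.
#' @return The table as a tibble, after validation.
#' @keywords internal
validate_ld <- function(exp) {
  needed <- c("dose", "tested", "responding")
  missing <- setdiff(needed, names(exp))
  if (length(missing) > 0) {
    stop("limiting-dilution table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(exp) == 0) stop("empty limiting-dilution experiment", call. = FALSE)
  with(exp, {
    if (any(dose < 1) || any(dose != round(dose))) {
      stop("doses must be positive integers", call. = FALSE)
    }
    if (any(responding < 0) || any(responding > tested) || any(tested < 1)) {
      stop("need 0 <= responding <= tested and tested >= 1", call. = FALSE)
    }
  })
  tibble::as_tibble(exp)
}

#' Single-hit log-likelihood of a limiting-dilution experiment
#'
#' Under the single-hit Poisson model the probability that a recipient given
#' dose d responds is `1 - exp(-f * d)`, so the binomial log-likelihood is
#' `sum(responding * log(1 - exp(-f d)) - (tested - responding) * f d)`
#' (dropping binomial coefficients, which do not depend on f).
#'
#' @param f Frequency value(s) in \[0, 1\].
#' @param exp Limiting-dilution table (dose, tested, responding).
#' @return Log-likelihood, vectorized over `f`.
#' @export
ld_loglik <- function(f, exp) {
  exp <- validate_ld(exp)
  vapply(f, function(fi) {
    if (fi < 0) return(-Inf)
    p_term <- ifelse(exp$responding > 0,
                     exp$responding * log(-expm1(-fi * exp$dose)), 0)
    if (any(exp$responding > 0) && fi == 0) return(-Inf)
    sum(p_term - (exp$tested - exp$responding) * fi * exp$dose)
  }, numeric(1))
}

#' Estimate repopulating-unit frequency by single-hit maximum likelihood
#'
#' Fits the single-hit Poisson model `P(response | dose d) = 1 - exp(-f d)`
#' to a dose-titration outcome table by maximizing the binomial
#' log-likelihood over log f (bracketed in \[1e-8, 1\]). The default 95%
#' confidence interval is the profile-likelihood set
#' `{f : 2 (l(f_hat) - l(f)) <= qchisq(0.95, 1)}`, which stays well behaved
#' near the boundary; a Wald interval on the log-f (complementary log-log)
#' scale, from a cloglog GLM with log-dose offset, is attached for
#' cross-checking. With no responders the estimate is 0 with a one-sided
#' upper bound; with all recipients responding the likelihood is monotone and
#' the estimate sits at the upper bracket with only a finite lower bound —
#' both cases carry a boundary flag.
#'
#' @param exp Limiting-dilution table (dose, tested, responding).
#' @param conf_level Confidence level (default 0.95).
#' @param f_min,f_max Optimization bracket for f.
#' @return An object of class `frequency_estimate`: a list with `f_hat`,
#'   `denominator` (1/f_hat), `ci_lower`, `ci_upper` (on f), `method`,
#'   `boundary`, `loglik`, `wald` (list with f_hat, ci_lower, ci_upper where
#'   the GLM fit is available) and the input `data`.
#' @examples
#' exp <- data.frame(dose = c(10, 50, 100, 1000), tested = 5,
#'                   responding = c(0, 3, 4, 5))
#' estimate_frequency(exp)
#' @export
estimate_frequency <- function(exp, conf_level = 0.95,
                               f_min = 1e-8, f_max = 1) {
  exp <- validate_ld(exp)
  q <- qchisq(conf_level, df = 1)
  total_resp <- sum(exp$responding)
  total_nonresp <- sum(exp$tested - exp$responding)
  ll <- function(f) ld_loglik(f, exp)

  if (total_resp == 0) {
    # l(f) = -f * sum(tested * dose); upper bound solves 2(0 - l(f)) = q
    f_up <- q / (2 * sum(exp$tested * exp$dose))
    est <- list(f_hat = 0, ci_lower = 0, ci_upper = f_up,
                boundary = TRUE, loglik = 0)
  } else if (total_nonresp == 0) {
    # monotone increasing likelihood: boundary at the upper bracket
    l_max <- ll(f_max)
    lo <- uniroot(function(f) 2 * (l_max - ll(f)) - q,
                  lower = f_min, upper = f_max, tol = 1e-12)$root
    est <- list(f_hat = f_max, ci_lower = lo, ci_upper = Inf,
                boundary = TRUE, loglik = l_max)
  } else {
    opt <- optimize(function(lf) -ll(exp(lf)),
                    interval = c(log(f_min), log(f_max)), tol = 1e-12)
    f_hat <- exp(opt$minimum)
    l_max <- -opt$objective
    drop_fun <- function(f) 2 * (l_max - ll(f)) - q
    lo <- if (drop_fun(f_min) > 0) {
      uniroot(drop_fun, lower = f_min, upper = f_hat, tol = 1e-12)$root
    } else f_min
    up <- if (drop_fun(f_max) > 0) {
      uniroot(drop_fun, lower = f_hat, upper = f_max, tol = 1e-12)$root
    } else f_max
    est <- list(f_hat = f_hat, ci_lower = lo, ci_upper = up,
                boundary = FALSE, loglik = l_max)
  }

  wald <- tryCatch({
    fit <- suppressWarnings(glm(
      cbind(responding, tested - responding) ~ 1,
      offset = log(dose), family = binomial(link = "cloglog"), data = exp
    ))
    est_log_f <- coef(fit)[[1]]
    se <- sqrt(diag(stats::vcov(fit)))[[1]]
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    list(f_hat = exp(est_log_f),
         ci_lower = exp(est_log_f - z * se),
         ci_upper = exp(est_log_f + z * se))
  }, error = function(e) NULL)

  structure(
    list(f_hat = est$f_hat,
         denominator = if (est$f_hat > 0) 1 / est$f_hat else Inf,
         ci_lower = est$ci_lower, ci_upper = est$ci_upper,
         conf_level = conf_level, method = "profile-likelihood",
         boundary = est$boundary, loglik = est$loglik,
         wald = wald, data = exp),
    class = "frequency_estimate"
  )
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat("Single-hit frequency estimate (", x$method, ")\n", sep = "")
  if (is.finite(x$denominator)) {
    cat(sprintf("  f_hat = %.6g  (1/%.5g, ~1/%d)\n", x$f_hat, x$denominator,
                round(x$denominator)))
  } else {
    cat(sprintf("  f_hat = %.6g\n", x$f_hat))
  }
  cat(sprintf("  %d%% CI on f: [%.6g, %.6g]", round(100 * x$conf_level),
              x$ci_lower, x$ci_upper))
  if (x$boundary) cat("  [boundary]")
  cat("\n")
  invisible(x)
}

as_frequency <- function(est) {
  if (inherits(est, "frequency_estimate")) est$f_hat else as.numeric(est)
}

#' Adjust a frequency estimate to an immunophenotypic subfraction
#'
#' If all active units lie inside a subfraction holding `fraction` of the
#' population's cells, the frequency among subfraction cells is `f / fraction`
#' — equivalently the denominator shrinks to `denominator * fraction`. CI
#' bounds scale identically. The canonical use: a 1-in-34 frequency restricted
#' to the 56% CD45+ subfraction becomes 1 in 19.04, reported as ~1/19.
#'
#' @param est A `frequency_estimate` or a bare frequency.
#' @param fraction Subfraction of cells containing all active units, in
#'   (0, 1\].
#' @return A `frequency_estimate` with scaled frequency and CI; for bare
#'   numeric input, CI fields are `NA`.
#' @examples
#' adjust_frequency_for_subfraction(1 / 34, 0.56)$denominator # 19.04
#' @export
adjust_frequency_for_subfraction <- function(est, fraction) {
  if (length(fraction) != 1 || !is.finite(fraction) || fraction <= 0 ||
      fraction > 1) {
    stop("`fraction` must be a single value in (0, 1]", call. = FALSE)
  }
  f <- as_frequency(est)
  f_sub <- f / fraction
  if (f_sub > 1) {
    stop("adjusted frequency exceeds 1 unit per cell; `fraction` is ",
         "implausibly small for this frequency", call. = FALSE)
  }
  if (inherits(est, "frequency_estimate")) {
    out <- est
    out$f_hat <- f_sub
    out$denominator <- if (f_sub > 0) 1 / f_sub else Inf
    out$ci_lower <- est$ci_lower / fraction
    out$ci_upper <- est$ci_upper / fraction
    out$method <- paste0(est$method, " (subfraction-adjusted)")
    out
  } else {
    structure(
      list(f_hat = f_sub,
           denominator = if (f_sub > 0) 1 / f_sub else Inf,
           ci_lower = NA_real_, ci_upper = NA_real_, conf_level = NA_real_,
           method = "subfraction-adjusted", boundary = FALSE,
           loglik = NA_real_, wald = NULL, data = NULL),
      class = "frequency_estimate"
    )
  }
}

#' Absolute repopulating-unit pool size in an organ
#'
#' Multiplies an estimated frequency by a population census (absolute cells
#' per organ) to give the absolute number of active units; the frequency CI
#' is propagated by the same scaling.
#'
#' @param est A `frequency_estimate` or bare frequency.
#' @param cells_per_organ Absolute cell count of the population per organ.
#' @param population Optional population label.
#' @return A list of class `pool_estimate` with `population`, `pool`,
#'   `ci_lower`, `ci_upper`, `cells_per_organ`, `f_hat`.
#' @export
estimate_pool_size <- function(est, cells_per_organ, population = NA) {
  if (length(cells_per_organ) != 1 || !is.finite(cells_per_organ) ||
      cells_per_organ < 0) {
    stop("`cells_per_organ` must be a single non-negative count",
         call. = FALSE)
  }
  f <- as_frequency(est)
  lo <- if (inherits(est, "frequency_estimate")) est$ci_lower else NA_real_
  up <- if (inherits(est, "frequency_estimate")) est$ci_upper else NA_real_
  structure(
    list(population = population,
         pool = cells_per_organ * f,
         ci_lower = cells_per_organ * lo,
         ci_upper = cells_per_organ * up,
         cells_per_organ = cells_per_organ,
         f_hat = f),
    class = "pool_estimate"
  )
}

#' Compare absolute pool sizes between populations
#'
#' Given two or more pool estimates, reports each population's share of the
#' summed pool (in percent, summing to 100) and the matrix of pairwise
#' ratios. A pool ratio of 2 between two populations corresponds to shares of
#' 66.7% and 33.3%.
#'
#' @param pools Named numeric vector of pool sizes, or a list of
#'   `pool_estimate` objects.
#' @return List with `pools` (named vector), `shares_percent` (named vector
#'   summing to 100) and `ratio` (square matrix, `ratio[i, j]` = pool i /
#'   pool j).
#' @export
compare_pools <- function(pools) {
  if (is.list(pools) && all(vapply(pools, inherits, TRUE, "pool_estimate"))) {
    nms <- vapply(seq_along(pools), function(i) {
      p <- pools[[i]]$population
      if (is.na(p)) paste0("pool", i) else as.character(p)
    }, character(1))
    pools <- setNames(vapply(pools, `[[`, numeric(1), "pool"), nms)
  }
  pools <- unlist(pools)
  if (length(pools) < 2) stop("need at least two pools", call. = FALSE)
  if (any(pools < 0)) stop("pool sizes must be non-negative", call. = FALSE)
  if (sum(pools) == 0) stop("all pools are zero", call. = FALSE)
  if (is.null(names(pools))) names(pools) <- paste0("pool", seq_along(pools))
  shares <- 100 * pools / sum(pools)
  ratio <- outer(pools, pools, "/")
  list(pools = pools, shares_percent = shares, ratio = ratio)
}

#' Single-hit adequacy diagnostic (slope test)
#'
#' Checks whether the dose-response data are consistent with the single-hit
#' model by fitting a complementary log-log regression
#' `log(-log(1 - p)) ~ log(dose)` and testing the slope against 1. Under the
#' single-hit model the slope is 1; a k-hit response (e.g. probability
#' `(1 - exp(-f d))^k`) inflates the small-dose slope towards k.
#'
#' @param exp Limiting-dilution table (dose, tested, responding).
#' @return List with `available`, and when available `slope`, `se`,
#'   `p_value` (Wald test of slope = 1) and the fitted `glm` object.
#' @export
single_hit_adequacy <- function(exp) {
  exp <- validate_ld(exp)
  informative <- sum(exp$responding) > 0 &&
    sum(exp$tested - exp$responding) > 0
  if (length(unique(exp$dose)) < 2 || !informative) {
    return(list(available = FALSE, slope = NA_real_, se = NA_real_,
                p_value = NA_real_, fit = NULL))
  }
  fit <- suppressWarnings(glm(
    cbind(responding, tested - responding) ~ log(dose),
    family = binomial(link = "cloglog"), data = exp
  ))
  slope <- coef(fit)[["log(dose)"]]
  se <- sqrt(diag(stats::vcov(fit)))[["log(dose)"]]
  z <- (slope - 1) / se
  list(available = TRUE, slope = slope, se = se,
       p_value = 2 * pnorm(-abs(z)), fit = fit)
}
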