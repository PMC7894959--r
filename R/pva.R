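#' Fit a growth-multiplier distribution from a census series
#'
#' Annual growth multipliers `R_t = N(t+1)/N(t)` from yearly totals of
#' mature individuals, summarised on both the arithmetic and log scale.
#' The log-scale mean and sd parameterise the lognormal environmental
#' deviates of [simulate_pva()].
#'
#' @param totals numeric vector of yearly mature counts (>= 3 years)
#' @return list with `ratios`, `arith_mean`, `arith_sd`, `log_mean`,
#'   `log_sd`
#' @export
fit_growth <- function(totals) {
  if (length(totals) < 3) {
    stop_endemica("fit_growth needs at least 3 census years (2 ratios)",
                  "endemica_validation_error")
  }
  r <- growth_ratios(totals)
  list(ratios = r,
       arith_mean = mean(r), arith_sd = stats::sd(r),
       log_mean = mean(log(r)), log_sd = stats::sd(log(r)))
}

#' PVA configuration
#'
#' Settings for the scalar stochastic projection. The growth multiplier is
#' lognormal with log-scale parameters `growth_log_mean` / `growth_log_sd`
#' (environmental stochasticity). With `demographic_stochasticity`, the
#' next-year abundance is Poisson around its expectation; if `survival` is
#' supplied the draw is decomposed into binomial survivors plus Poisson
#' recruits.
#'
#' @param n0 initial number of mature individuals
#' @param horizon_years projection horizon
#' @param n_replicates trajectory replicates (default 10000)
#' @param growth_log_mean,growth_log_sd lognormal parameters of the annual
#'   multiplier
#' @param survival optional annual survival rate Sa of mature individuals
#' @param demographic_stochasticity draw integer abundances (default TRUE)
#' @param extinction_threshold absorb trajectories at or below this count
#'   (default 0, true extinction)
#' @param seed RNG seed
#' @return a `pva_config` list
#' @export
pva_config <- function(n0, horizon_years, n_replicates = 10000,
                       growth_log_mean = 0, growth_log_sd = 0,
                       survival = NULL, demographic_stochasticity = TRUE,
                       extinction_threshold = 0, seed = NULL) {
  if (n0 < 0 || horizon_years < 1 || n_replicates < 1 || growth_log_sd < 0) {
    stop_endemica("invalid PVA configuration", "endemica_validation_error")
  }
  structure(list(n0 = n0, horizon_years = as.integer(horizon_years),
                 n_replicates = as.integer(n_replicates),
                 growth_log_mean = growth_log_mean,
                 growth_log_sd = growth_log_sd,
                 survival = survival,
                 demographic_stochasticity = demographic_stochasticity,
                 extinction_threshold = extinction_threshold,
                 seed = seed),
            class = "pva_config")
}

#' Stochastic population projection
#'
#' Scalar (unstructured) projection with environmental stochasticity (a
#' lognormal annual growth multiplier shared by the whole population) and
#' optional demographic stochasticity (Poisson abundance draws, or a
#' binomial-survivor + Poisson-recruit decomposition when a survival rate
#' is supplied). No density dependence. Trajectories are absorbed once
#' abundance falls to or below the extinction threshold.
#'
#' @param config a [pva_config()]
#' @return a `pva_result` list: `summary` (per year: mean, sd, min, max of
#'   abundance and cumulative extinction risk with exact binomial CI),
#'   `terminal` (per-replicate final sizes), and the `config`
#' @export
simulate_pva <- function(config) {
  stopifnot(inherits(config, "pva_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nrep <- config$n_replicates
  horizon <- config$horizon_years
  thr <- config$extinction_threshold
  N <- matrix(0, nrep, horizon + 1)
  N[, 1] <- config$n0
  absorbed <- rep(config$n0 <= thr, nrep)
  for (t in seq_len(horizon)) {
    cur <- N[, t]
    R <- stats::rlnorm(nrep, config$growth_log_mean, config$growth_log_sd)
    if (config$demographic_stochasticity) {
      if (!is.null(config$survival)) {
        sa <- config$survival
        surv <- stats::rbinom(nrep, cur, min(sa, 1))
        rec <- stats::rpois(nrep, cur * pmax(R - sa, 0))
        nxt <- surv + rec
      } else {
        nxt <- stats::rpois(nrep, R * cur)
      }
    } else {
      nxt <- round(R * cur)
    }
    nxt[absorbed] <- N[absorbed, t]
    absorbed <- absorbed | nxt <= thr
    nxt[absorbed & nxt <= thr] <- pmin(nxt[absorbed & nxt <= thr], thr)
    N[, t + 1] <- nxt
  }
  ext_year <- apply(N <= thr, 1, function(z) {
    w <- which(z)
    if (length(w) == 0) NA_integer_ else w[1] - 1L
  })
  years <- 0:horizon
  risk <- vapply(years, function(y) mean(!is.na(ext_year) & ext_year <= y),
                 numeric(1))
  ci <- t(vapply(years, function(y) {
    k <- sum(!is.na(ext_year) & ext_year <= y)
    as.numeric(stats::binom.test(k, nrep)$conf.int)
  }, numeric(2)))
  summary <- data.frame(
    year = years,
    mean = colMeans(N), sd = apply(N, 2, stats::sd),
    min = apply(N, 2, min), max = apply(N, 2, max),
    risk = risk, risk_lo = ci[, 1], risk_hi = ci[, 2])
  structure(list(summary = summary, terminal = N[, horizon + 1],
                 ext_year = ext_year, config = config),
            class = "pva_result")
}

#' Extinction risk at a given year
#'
#' Fraction of replicate trajectories absorbed at or below the extinction
#' threshold by the given year, with an exact binomial confidence interval.
#'
#' @param result a `pva_result`
#' @param year projection year (0..horizon)
#' @return list with `risk`, `ci`, `year`, `n_replicates`
#' @export
extinction_risk <- function(result, year) {
  stopifnot(inherits(result, "pva_result"))
  if (year < 0 || year > result$config$horizon_years) {
    stop_endemica("year outside the projection horizon",
                  "endemica_validation_error")
  }
  row <- result$summary[result$summary$year == year, ]
  list(risk = row$risk, ci = c(row$risk_lo, row$risk_hi), year = year,
       n_replicates = result$config$n_replicates)
}
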