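#' Per-year census totals
#'
#' Sums each stage class (mature, seedlings, non-reproductive, dead) across
#' subpopulations, per census year. Additive over any partition of the rows
#' and invariant to row order.
#'
#' @param records a validated monitoring table
#' @return data.frame with one row per year: `year`, `n_mature`,
#'   `n_seedlings`, `n_nonreproductive`, `n_dead`, `local_eoo_m2` (summed)
#' @export
census_totals <- function(records) {
  agg <- stats::aggregate(
    records[, c("n_mature", "n_seedlings", "n_nonreproductive", "n_dead",
                "local_eoo_m2")],
    by = list(year = records$year), FUN = sum)
  agg[order(agg$year), , drop = FALSE]
}

#' Stage structure of a census
#'
#' Proportions of mature, non-reproductive and seedling individuals among
#' the living plants of one scope-year. Dead individuals are recorded
#' separately in monitoring tables and are excluded from the denominator.
#'
#' @param records monitoring table
#' @param scope a subpopulation label, or `"TOTAL"` for the whole population
#' @return data.frame per year: `p_mature`, `p_nonreproductive`,
#'   `p_seedlings` (each in `[0,1]`, summing to 1)
#' @export
stage_structure <- function(records, scope = "TOTAL") {
  if (!identical(scope, "TOTAL")) {
    records <- records[records$subpopulation == scope, , drop = FALSE]
    if (nrow(records) == 0) {
      stop_endemica(sprintf("no records for subpopulation '%s'", scope),
                    "endemica_validation_error")
    }
  }
  tot <- census_totals(records)
  denom <- tot$n_mature + tot$n_nonreproductive + tot$n_seedlings
  if (any(denom == 0)) {
    stop_endemica("stage structure undefined: no living individuals",
                  "endemica_validation_error")
  }
  data.frame(year = tot$year, scope = scope,
             p_mature = tot$n_mature / denom,
             p_nonreproductive = tot$n_nonreproductive / denom,
             p_seedlings = tot$n_seedlings / denom)
}

#' Annual population growth multipliers
#'
#' Forward ratios `R_t = N(t+1) / N(t)` of consecutive yearly totals of
#' mature individuals.
#'
#' @param totals numeric vector of yearly mature counts in year order
#' @return numeric vector of length `length(totals) - 1`
#' @export
growth_ratios <- function(totals) {
  if (length(totals) < 2) {
    stop_endemica("need at least two census years", "endemica_validation_error")
  }
  head_t <- totals[-length(totals)]
  if (any(head_t <= 0)) {
    stop_endemica("zero census in a non-final year: growth ratio undefined",
                  "endemica_validation_error")
  }
  totals[-1] / head_t
}

#' Flowers per individual
#'
#' `F = Fl x St`: mean flowers per stem times mean flowering stems per
#' individual.
#'
#' @param fl mean flowers per flowering stem
#' @param st mean flowering stems per individual
#' @return flowers per individual
#' @export
flowers_per_individual <- function(fl, st) {
  stopifnot(all(fl >= 0), all(st >= 0))
  fl * st
}

#' Fruits per individual
#'
#' Flowers per individual times fruit set (fruits per flower).
#'
#' @param f flowers per individual
#' @param fruit_set fruits per flower, a proportion
#' @return fruits per individual
#' @export
fruits_per_individual <- function(f, fruit_set) {
  if (any(fruit_set < 0 | fruit_set > 1)) {
    stop_endemica("fruit_set must lie in [0, 1]", "endemica_validation_error")
  }
  f * fruit_set
}

#' Fecundity: seeds per individual
#'
#' `S x St`: mean sound seeds per stem times mean flowering stems per
#' individual.
#'
#' @param s mean sound seeds per flowering stem
#' @param st mean flowering stems per individual
#' @return seeds per individual per season
#' @export
fecundity <- function(s, st) {
  stopifnot(all(s >= 0), all(st >= 0))
  s * st
}

#' Relative reproductive success
#'
#' Sound seeds actually produced divided by the maximum potential seed
#' production (ovules): each flower carries `ovules_per_flower` ovules
#' (default 2, one per mericarp of the schizocarp).
#'
#' @param sound_seeds_per_individual seeds per individual
#' @param flowers_per_individual flowers per individual (must be > 0)
#' @param ovules_per_flower ovules per flower (default 2)
#' @return proportion in `[0, 1]`; values above 1 are reported as 1 with a
#'   warning
#' @export
rrs <- function(sound_seeds_per_individual, flowers_per_individual,
                ovules_per_flower = 2) {
  if (any(flowers_per_individual <= 0)) {
    stop_endemica("rrs undefined with zero flowers",
                  "endemica_validation_error")
  }
  out <- sound_seeds_per_individual /
    (flowers_per_individual * ovules_per_flower)
  if (any(out > 1)) {
    warning("RRS above 1 clipped to 1 (more seeds than ovules reported)")
    out <- pmin(out, 1)
  }
  out
}

#' Seed rain
#'
#' Seeds deposited per m^2 per season: fecundity times the number of mature
#' individuals, divided by the subpopulation's local EOO.
#'
#' @param fecundity seeds per individual
#' @param n_mature mature individuals in the subpopulation
#' @param local_eoo_m2 local extent of occurrence in m^2
#' @return seeds per m^2
#' @export
seed_rain <- function(fecundity, n_mature, local_eoo_m2) {
  if (any(local_eoo_m2 <= 0)) {
    stop_endemica("local_eoo_m2 must be positive", "endemica_validation_error")
  }
  fecundity * n_mature / local_eoo_m2
}

#' Annual survival rate of mature individuals
#'
#' Proportion of tagged mature individuals found alive in the following
#' flowering period, with an exact (Clopper-Pearson) 95% binomial interval.
#'
#' @param n_alive_next individuals alive the next season
#' @param n_tagged individuals tagged
#' @return list with `sa`, `ci` (length-2), `n`
#' @export
survival_rate <- function(n_alive_next, n_tagged) {
  if (n_tagged <= 0 || n_alive_next < 0 || n_alive_next > n_tagged) {
    stop_endemica("need 0 <= n_alive_next <= n_tagged, n_tagged > 0",
                  "endemica_validation_error")
  }
  bt <- stats::binom.test(n_alive_next, n_tagged)
  list(sa = n_alive_next / n_tagged,
       ci = as.numeric(bt$conf.int), n = n_tagged)
}

#' Generation length
#'
#' `alpha + 1 / (1 - Sa)`: age at first reproduction plus the expected
#' further lifespan of a mature plant under constant annual survival `Sa`.
#'
#' @param alpha age at first reproduction in years
#' @param sa annual survival rate of mature individuals, in `[0, 1)`
#' @return generation length in years
#' @export
generation_length <- function(alpha, sa) {
  if (any(sa < 0 | sa >= 1)) {
    stop_endemica("generation length undefined for Sa outside [0, 1)",
                  "endemica_validation_error")
  }
  stopifnot(all(alpha >= 0))
  alpha + 1 / (1 - sa)
}

#' Effective population size heuristics
#'
#' Multiplies the census number of mature individuals by standard Ne/Nc
#' ratios (default 0.4 and 0.1). Estimates below 50 are flagged: such
#' populations are considered threatened by inbreeding depression and
#' allele loss.
#'
#' @param nc census count of mature individuals
#' @param ratios Ne/Nc ratios
#' @return data.frame with `ratio`, `ne` (rounded to integer),
#'   `below_50` flag
#' @export
effective_size <- function(nc, ratios = c(0.4, 0.1)) {
  stopifnot(nc >= 0)
  ne <- round(nc * ratios)
  data.frame(ratio = ratios, ne = as.integer(ne), below_50 = ne < 50)
}

#' Seasonal reproductive summary
#'
#' Aggregates per-individual reproductive samples into the per-year summary
#' used in monitoring reports: mean flowering stems (St), flowers per stem
#' (Fl), flowers per individual (F = Fl x St), fruit set, fruits per
#' individual, seeds per stem (S), fecundity (S x St), relative reproductive
#' success, and survival Sa when next-season status is recorded. Means are
#' unweighted arithmetic means over tagged individuals with standard errors
#' sd/sqrt(n).
#'
#' @param samples validated reproduction table
#' @param ovules_per_flower ovules per flower for RRS (default 2)
#' @return data.frame, one row per year
#' @export
repro_summary <- function(samples, ovules_per_flower = 2) {
  years <- sort(unique(samples$year))
  rows <- lapply(years, function(yr) {
    s <- samples[samples$year == yr, , drop = FALSE]
    st <- mean(s$n_flowering_stems)
    fl <- mean(s$flowers_per_stem)
    fset <- mean(s$fruits_per_flower, na.rm = TRUE)
    sps <- mean(s$seeds_per_stem)
    f_ind <- flowers_per_individual(fl, st)
    # per-individual RRS where the individual actually flowered
    flw <- s$flowers_per_stem > 0 & s$n_flowering_stems > 0
    rrs_i <- if (any(flw)) {
      rrs(s$seeds_per_stem[flw] * s$n_flowering_stems[flw],
          s$flowers_per_stem[flw] * s$n_flowering_stems[flw],
          ovules_per_flower)
    } else NA_real_
    sa <- NA_real_
    if (!is.null(s$alive_next_season) && any(!is.na(s$alive_next_season))) {
      alive <- s$alive_next_season[!is.na(s$alive_next_season)]
      sa <- mean(alive)
    }
    out <- data.frame(
      year = yr, n = nrow(s),
      st = st, st_se = se_mean(s$n_flowering_stems),
      fl = fl, fl_se = se_mean(s$flowers_per_stem),
      f = f_ind,
      fruit_set = fset, fruit_set_se = se_mean(s$fruits_per_flower),
      fruits_per_individual = fruits_per_individual(f_ind, fset),
      s = sps, s_se = se_mean(s$seeds_per_stem),
      fecundity = fecundity(sps, st),
      rrs = mean(rrs_i), rrs_se = se_mean(rrs_i),
      sa = sa)
    # construction identities asserted on every summary
    stopifnot(isTRUE(all.equal(out$f, out$fl * out$st)),
              isTRUE(all.equal(out$fecundity, out$s * out$st)))
    out
  })
  do.call(rbind, rows)
}
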