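mon <- read_monitoring(extdata("asperula_monitoring.csv"))
tot <- census_totals(mon)

test_that("census totals reproduce the yearly sums and are additive", {
  expect_equal(tot$n_mature, c(130, 109, 68, 79, 110))
  expect_equal(tot$n_seedlings[tot$year == 2014], 8)
  expect_equal(tot$n_nonreproductive[tot$year == 2014], 21)
  expect_equal(sum(tot$n_seedlings), 45)
  expect_equal(sum(tot$n_dead), 14)

  # permutation-invariant and additive over partitions
  shuffled <- mon[sample(nrow(mon)), ]
  expect_equal(census_totals(shuffled), tot, ignore_attr = TRUE)
  part <- census_totals(mon[mon$subpopulation %in% c("An-Pl", "An-S"), ])
  rest <- census_totals(mon[!mon$subpopulation %in% c("An-Pl", "An-S"), ])
  expect_equal(part$n_mature + rest$n_mature, tot$n_mature)
})

test_that("stage structure excludes the dead and sums to one", {
  ss <- stage_structure(mon, "TOTAL")
  expect_equal(ss$p_mature[1], 130 / 159, tolerance = 1e-12)
  expect_equal(round(ss[1, c("p_mature", "p_nonreproductive",
                             "p_seedlings")], 3),
               data.frame(p_mature = 0.818, p_nonreproductive = 0.132,
                          p_seedlings = 0.050),
               ignore_attr = TRUE)
  expect_equal(ss$p_mature + ss$p_nonreproductive + ss$p_seedlings,
               rep(1, 5), tolerance = 1e-12)
  one <- stage_structure(data.frame(subpopulation = "A", year = 1,
                                    n_mature = 10, n_seedlings = 0,
                                    n_nonreproductive = 0, n_dead = 0,
                                    local_eoo_m2 = 1))
  expect_equal(one$p_mature, 1)
})

test_that("growth ratios are forward multipliers with telescoping identity", {
  r <- growth_ratios(tot$n_mature)
  expect_equal(round(r, 4), c(0.8385, 0.6239, 1.1618, 1.3924))
  expect_equal(growth_ratios(c(7, 7, 7)), c(1, 1))
  # the product of ratios telescopes back to the final census
  expect_equal(130 * prod(r), 110, tolerance = 1e-9)
  expect_equal(130 * exp(4 * mean(log(r))), 110, tolerance = 1e-9)
  expect_error(growth_ratios(c(5, 0, 3)),
               class = "endemica_validation_error")
  expect_error(growth_ratios(5), class = "endemica_validation_error")
})

test_that("reproductive products match the published seasonal table", {
  expect_equal(round(flowers_per_individual(11.71, 18.9), 2), 221.32)
  expect_equal(round(flowers_per_individual(21.55, 9.65), 2), 207.96)
  expect_equal(flowers_per_individual(13, 0), 0)

  expect_equal(round(fruits_per_individual(221.32, 0.29), 2), 64.18)
  expect_equal(round(fruits_per_individual(207.96, 0.34), 2), 70.71)
  expect_equal(fruits_per_individual(100, 0), 0)
  expect_error(fruits_per_individual(100, 1.2),
               class = "endemica_validation_error")

  expect_equal(round(fecundity(7.26, 18.9), 1), 137.2)
  expect_equal(round(fecundity(20.68, 13.9), 1), 287.5)
  expect_equal(fecundity(0, 10), 0)
})

test_that("relative reproductive success is a bounded ovule fraction", {
  expect_equal(rrs(0, 50), 0)
  expect_equal(rrs(2 * 80, 80), 1)
  expect_warning(out <- rrs(300, 100), "clipped")
  expect_equal(out, 1)
  expect_error(rrs(10, 0), class = "endemica_validation_error")
})

test_that("seed rain follows the stated formula and is linear in abundance", {
  expect_equal(seed_rain(137.2, 28, 9100.9), 137.2 * 28 / 9100.9)
  expect_equal(seed_rain(0, 10, 5), 0)
  expect_equal(seed_rain(137.2, 56, 9100.9),
               2 * seed_rain(137.2, 28, 9100.9))
  expect_error(seed_rain(1, 1, 0), class = "endemica_validation_error")
})

test_that("survival rate gives the tagged-cohort proportions with exact CI", {
  expect_equal(survival_rate(17, 20)$sa, 0.85)
  expect_equal(survival_rate(13, 20)$sa, 0.65)
  s <- survival_rate(20, 20)
  expect_equal(s$sa, 1)
  expect_lt(s$ci[1], 1)
  expect_error(survival_rate(21, 20), class = "endemica_validation_error")
})

test_that("generation length follows alpha + 1/(1 - Sa)", {
  expect_equal(generation_length(3, 0.75), 7)
  expect_equal(generation_length(3, 0.8375), 9.1538, tolerance = 1e-4)
  expect_equal(generation_length(0, 0), 1)
  expect_error(generation_length(3, 1), class = "endemica_validation_error")
})

test_that("effective-size heuristics apply the Ne/Nc ratios and the 50 flag", {
  ne <- effective_size(130)
  expect_equal(ne$ne, c(52L, 13L))
  expect_equal(ne$below_50, c(FALSE, TRUE))
  expect_equal(effective_size(0)$ne, c(0L, 0L))
  expect_equal(effective_size(1000)$ne, c(400L, 100L))
})

test_that("seasonal summaries recover generating rates on large samples", {
  spec <- synth_spec(n_years = 1, n_tagged = 10000, seed = 512)
  monit <- generate_monitoring(spec)
  samples <- generate_reproduction(spec, monit)
  rs <- repro_summary(samples)
  # construction identities
  expect_equal(rs$f, rs$fl * rs$st, tolerance = 1e-12)
  expect_equal(rs$fecundity, rs$s * rs$st, tolerance = 1e-12)
  # Monte-Carlo consistency: each summary within 3 SE of its generator value
  expect_lt(abs(rs$st - spec$stems_mu * spec$p_flower), 3 * rs$st_se)
  expect_lt(abs(rs$fruit_set - spec$fruit_set), 3 * rs$fruit_set_se)
  expect_lt(abs(rs$sa - spec$sa), 3 * sqrt(spec$sa * (1 - spec$sa) / 10000))
  # per-ovule seed-set probability is recovered by RRS
  expect_lt(abs(rs$rrs - spec$fruit_set * spec$p_seed), 3 * rs$rrs_se)
})
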