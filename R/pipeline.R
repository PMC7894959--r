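#' Read a run configuration
#'
#' YAML key-value configuration for [run_pipeline()]. Recognised keys:
#' `seed`, `n_permutations`, `out_dir`, input paths under `inputs:`
#' (`monitoring`, `reproduction`, `coordinates`, `genotypes`,
#' `genotype_dialect`, `lnk`), `aoo:` (`cell_km`, `origin`), `pva:`
#' (`horizon_years`, `n_replicates`, `use_survival`), and `assessment:`
#' (`severely_fragmented`, `continuing_decline`, `extreme_fluctuations`,
#' `n_locations`).
#'
#' @param path YAML file path
#' @return configuration list
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$n_permutations)) cfg$n_permutations <- 999L
  if (cfg$n_permutations < 1) {
    stop_endemica("n_permutations must be >= 1", "endemica_validation_error")
  }
  cfg
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null", force = TRUE)
}

#' Run the full assessment pipeline
#'
#' Executes the stages geo -> demography -> popgen -> pva -> assessment on
#' the inputs named in the configuration, writing one structured JSON
#' document per stage plus a plain-text summary into `out_dir`. Stages
#' whose inputs are absent are skipped with a logged warning; any stage
#' failure aborts with the stage name. A fixed seed makes the stochastic
#' stages (permutation tests, bootstrap, PVA) reproducible.
#'
#' @param config configuration list (see [read_config()]) or a YAML path
#' @return named list of per-stage results, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$n_permutations)) config$n_permutations <- 999L
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  log_info("pipeline start, seed %d", seed)
  results <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop_endemica(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)),
                    "endemica_stage_error")
    })
  }

  # ---- geo ----
  geo_res <- NULL
  if (!is.null(config$inputs$coordinates)) {
    geo_res <- run_stage("geo", function() {
      pts <- read_coordinates(config$inputs$coordinates)
      log_info("geo: %d points, %d subpopulations", nrow(pts),
               length(unique(pts$subpopulation)))
      xy <- project_points(pts)
      cell <- config$aoo$cell_km %||% 1
      origin <- unlist(config$aoo$origin %||% c(0, 0))
      log_info("geo: AOO grid cell %.3f km, origin (%.3f, %.3f)",
               cell, origin[1], origin[2])
      a <- aoo(xy, cell_km = cell, origin = origin)
      e <- eoo(xy, aoo_km2 = a$aoo_km2)
      list(eoo_km2 = e$eoo_km2, eoo_km2_adjusted = e$eoo_km2_adjusted,
           degenerate = e$degenerate, aoo_km2 = a$aoo_km2,
           n_cells = a$n_cells,
           cells_by_subpop = as.list(a$cells_by_subpop),
           hull = e$hull)
    })
    write_stage_json(geo_res, file.path(out_dir, "geo.json"))
  } else {
    warning("geo stage skipped: no coordinates input")
  }
  results$geo <- geo_res

  # ---- demography ----
  demo_res <- NULL
  if (!is.null(config$inputs$monitoring)) {
    demo_res <- run_stage("demography", function() {
      mon <- read_monitoring(config$inputs$monitoring)
      log_info("demography: %d monitoring rows", nrow(mon))
      tot <- census_totals(mon)
      out <- list(
        totals = tot,
        stage_structure = stage_structure(mon, "TOTAL"),
        growth_ratios = growth_ratios(tot$n_mature),
        effective_size = effective_size(tot$n_mature[1]),
        fluctuation = flag_extreme_fluctuation(tot$n_mature))
      if (!is.null(config$inputs$reproduction)) {
        rep_tab <- read_reproduction(config$inputs$reproduction)
        out$repro_summary <- repro_summary(rep_tab)
      }
      out
    })
    write_stage_json(demo_res, file.path(out_dir, "demography.json"))
  } else {
    warning("demography stage skipped: no monitoring input")
  }
  results$demography <- demo_res

  # ---- popgen ----
  popgen_res <- NULL
  if (!is.null(config$inputs$genotypes)) {
    popgen_res <- run_stage("popgen", function() {
      dialect <- config$inputs$genotype_dialect %||% "genalex"
      g <- read_genotypes(config$inputs$genotypes, dialect)
      log_info("popgen: %d individuals x %d loci, %d permutations",
               length(g$ids), length(g$loci), config$n_permutations)
      div <- diversity(g)
      af <- allele_frequencies(g)
      pooled_pic <- vapply(seq_along(g$loci), function(l) {
        obs <- c(g$a1[, l], g$a2[, l])
        obs <- obs[!is.na(obs)]
        pic(as.numeric(table(obs)) / length(obs))
      }, numeric(1))
      fs <- f_statistics(g, n_permutations = config$n_permutations,
                         seed = derive_seed(seed, 11))
      ena <- fst_ena(g, n_bootstrap = config$n_bootstrap %||% 1000,
                     seed = derive_seed(seed, 12))
      am <- amova(g, n_permutations = config$n_permutations,
                  seed = derive_seed(seed, 13))
      nei <- nei_unbiased_distance(g)
      pc <- pcoa(nei)
      out <- list(
        diversity = div, pic = setNames(as.list(pooled_pic), g$loci),
        f_statistics = fs[c("per_locus", "mean", "p_fst", "p_fis")],
        nm = gene_flow(max(fs$mean["fst"], 1e-6)),
        fst_ena = ena[c("fst_uncorrected", "fst_corrected",
                        "ci_uncorrected", "ci_corrected")],
        null_alleles = ena$null_estimates,
        amova = am[c("table", "pct_among", "pct_within", "phi_st",
                     "p_value")],
        nei_distance = nei, pcoa_pct_variance = pc$pct_variance)
      if (!is.null(config$inputs$lnk)) {
        lnk <- utils::read.csv(config$inputs$lnk)
        ev <- evanno_delta_k(lnk)
        out$evanno <- ev
      }
      out
    })
    write_stage_json(popgen_res, file.path(out_dir, "popgen.json"))
  } else {
    warning("popgen stage skipped: no genotype input")
  }
  results$popgen <- popgen_res

  # ---- pva ----
  pva_res <- NULL
  if (!is.null(demo_res)) {
    pva_res <- run_stage("pva", function() {
      tot <- demo_res$totals$n_mature
      fg <- fit_growth(tot)
      horizon <- config$pva$horizon_years %||% 50
      nrep <- config$pva$n_replicates %||% 10000
      use_sa <- isTRUE(config$pva$use_survival)
      sa <- if (use_sa && !is.null(demo_res$repro_summary)) {
        mean(demo_res$repro_summary$sa, na.rm = TRUE)
      } else NULL
      log_info("pva: n0 %d, horizon %d, %d replicates", tot[1], horizon,
               nrep)
      cfg <- pva_config(n0 = tot[1], horizon_years = horizon,
                        n_replicates = nrep,
                        growth_log_mean = fg$log_mean,
                        growth_log_sd = fg$log_sd,
                        survival = sa, seed = derive_seed(seed, 21))
      res <- simulate_pva(cfg)
      list(growth_fit = fg[c("arith_mean", "arith_sd", "log_mean",
                             "log_sd")],
           summary = res$summary,
           risk_horizon = extinction_risk(res, horizon)[c("risk", "ci")])
    })
    write_stage_json(pva_res, file.path(out_dir, "pva.json"))
  } else {
    warning("pva stage skipped: demography unavailable")
  }
  results$pva <- pva_res

  # ---- assessment ----
  assess_res <- NULL
  if (!is.null(geo_res) || !is.null(demo_res)) {
    assess_res <- run_stage("assessment", function() {
      acfg <- config$assessment %||% list()
      ep <- NULL
      if (!is.null(pva_res)) {
        ep <- list(p = pva_res$risk_horizon$risk,
                   years = config$pva$horizon_years %||% 50)
      }
      input <- assessment_input(
        eoo_km2 = if (!is.null(geo_res)) geo_res$eoo_km2_adjusted else NA,
        aoo_km2 = if (!is.null(geo_res)) geo_res$aoo_km2 else NA,
        n_locations = acfg$n_locations %||% NA,
        severely_fragmented = isTRUE(acfg$severely_fragmented),
        continuing_decline = unlist(acfg$continuing_decline) %||%
          character(0),
        extreme_fluctuations = unlist(acfg$extreme_fluctuations) %||%
          character(0),
        n_mature = if (!is.null(demo_res))
          utils::tail(demo_res$totals$n_mature, 1) else NA,
        extinction_probability = ep)
      res <- assess(input)
      list(category = res$category, codes = res$codes,
           criteria = res$criteria)
    })
    write_stage_json(assess_res, file.path(out_dir, "assessment.json"))
  }
  results$assessment <- assess_res

  # ---- human-readable summary ----
  lines <- c("endemica pipeline summary",
             sprintf("seed: %d", seed),
             sprintf("R version: %s", as.character(getRversion())))
  if (!is.null(geo_res)) {
    lines <- c(lines, sprintf(
      "geo: EOO %.3f km2 (adjusted %.3f), AOO %.0f km2 in %d cells",
      geo_res$eoo_km2, geo_res$eoo_km2_adjusted, geo_res$aoo_km2,
      geo_res$n_cells))
  }
  if (!is.null(demo_res)) {
    rng <- range(demo_res$totals$n_mature)
    lines <- c(lines, sprintf(
      "demography: mature individuals %d-%d over %d years", rng[1], rng[2],
      nrow(demo_res$totals)))
  }
  if (!is.null(popgen_res)) {
    lines <- c(lines, sprintf(
      "popgen: global FST %.3f (ENA-corrected %.3f), AMOVA among %.1f%%",
      popgen_res$fst_ena$fst_uncorrected, popgen_res$fst_ena$fst_corrected,
      popgen_res$amova$pct_among))
  }
  if (!is.null(pva_res)) {
    lines <- c(lines, sprintf("pva: horizon risk %.3f",
                              pva_res$risk_horizon$risk))
  }
  if (!is.null(assess_res)) {
    lines <- c(lines, sprintf("assessment: %s [%s]", assess_res$category,
                              paste(assess_res$codes, collapse = "; ")))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  log_info("pipeline done: %d stage documents in %s",
           sum(!vapply(results, is.null, logical(1))), out_dir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
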