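#' Synthetic-data specification
#'
#' Parameters of the generator that emulates the statistical structure of
#' all pipeline inputs: a handful of very small cliff subpopulations whose
#' annual fluctuations are driven by a shared environmental multiplier,
#' hierarchical stem -> flower -> fruit -> seed reproduction, and a few SSR
#' loci with moderate differentiation, a strong heterozygote deficit, and
#' locus-specific null alleles. Defaults mirror the monitored system: five
#' subpopulations of 2-46 mature plants, target FST 0.16, inbreeding
#' coefficient 0.46, per-locus null-allele frequencies 0.06-0.25, adult
#' survival 0.84, and subpopulation centres strung along a ~30 km coastal
#' line.
#'
#' @param n_subpops number of subpopulations
#' @param initial_sizes starting mature counts, one per subpopulation
#' @param n_years monitoring years
#' @param mean_growth mean annual growth multiplier
#' @param env_log_sd log-scale sd of the shared annual multiplier
#' @param sa annual survival rate of mature individuals
#' @param seedling_rate,nonrepro_rate expected seedlings / non-reproductive
#'   plants per mature individual per year
#' @param n_tagged tagged individuals per year for reproduction sampling
#' @param stems_mu,stems_size negative-binomial parameters of stems per
#'   individual
#' @param p_flower probability a stem flowers
#' @param flowers_per_stem_mean Poisson mean of flowers per flowering stem
#' @param fruit_set probability a flower sets fruit
#' @param p_seed probability an ovule (2 per fruit) matures into a sound
#'   seed
#' @param local_eoo_m2 local EOO per subpopulation (m^2)
#' @param n_loci number of SSR loci
#' @param n_alleles alleles per locus (recycled)
#' @param fst target among-subpopulation differentiation (Balding-Nichols)
#' @param fis within-subpopulation inbreeding coefficient
#' @param null_rates per-locus null-allele frequencies (recycled)
#' @param allele_base starting fragment size (bp) of the allele ladder
#' @param coast_length_km length of the line along which subpopulation
#'   centres are spaced
#' @param points_per_subpop occurrence points per subpopulation
#' @param jitter_km uniform jitter of points around their centre
#' @param seed master RNG seed
#' @return a `synth_spec` list
#' @export
synth_spec <- function(n_subpops = 5,
                       initial_sizes = c(28, 30, 46, 20, 6),
                       n_years = 5,
                       mean_growth = 1.0,
                       env_log_sd = 0.35,
                       sa = 0.84,
                       seedling_rate = 0.08,
                       nonrepro_rate = 0.20,
                       n_tagged = 20,
                       stems_mu = 21, stems_size = 5,
                       p_flower = 0.67,
                       flowers_per_stem_mean = 19.8,
                       fruit_set = 0.33,
                       p_seed = 0.33,
                       local_eoo_m2 = c(9100, 960, 44640, 14500, 13),
                       n_loci = 3,
                       n_alleles = c(5, 4, 3),
                       fst = 0.16,
                       fis = 0.46,
                       null_rates = c(0.06, 0.20, 0.25),
                       allele_base = 150,
                       coast_length_km = 30,
                       points_per_subpop = 3,
                       jitter_km = 0.2,
                       seed = 1) {
  stopifnot(n_subpops >= 1, length(initial_sizes) == n_subpops,
            all(initial_sizes >= 0), n_years >= 1,
            sa >= 0, sa <= 1, fruit_set >= 0, fruit_set <= 1,
            p_seed >= 0, p_seed <= 1, p_flower >= 0, p_flower <= 1,
            fst > 0, fst < 1, fis >= 0, fis <= 1,
            all(null_rates >= 0), all(null_rates <= 1))
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic monitoring table
#'
#' Each year draws one shared lognormal environmental multiplier applied to
#' every subpopulation (so annual fluctuations are perfectly correlated
#' across subpopulations, as observed in the field system); realised counts
#' come from binomial survival plus Poisson recruitment, and seedling /
#' non-reproductive counts from per-capita Poisson rates.
#'
#' @param spec a [synth_spec()]
#' @return a validated `monitoring_table`
#' @export
generate_monitoring <- function(spec) {
  set.seed(derive_seed(spec$seed, 1))
  subpops <- paste0("SP", seq_len(spec$n_subpops))
  mult <- stats::rlnorm(spec$n_years - 1,
                        log(spec$mean_growth) - spec$env_log_sd^2 / 2,
                        spec$env_log_sd)
  rows <- list()
  N <- spec$initial_sizes
  dead <- integer(spec$n_subpops)
  for (t in seq_len(spec$n_years)) {
    seedl <- stats::rpois(spec$n_subpops, spec$seedling_rate * N)
    nonrep <- stats::rpois(spec$n_subpops, spec$nonrepro_rate * N)
    rows[[t]] <- data.frame(
      subpopulation = subpops, year = 2000 + t,
      n_mature = N, n_seedlings = seedl, n_nonreproductive = nonrep,
      n_dead = dead,
      local_eoo_m2 = rep_len(spec$local_eoo_m2, spec$n_subpops))
    if (t < spec$n_years) {
      s_t <- min(1, spec$sa * mult[t])
      surv <- stats::rbinom(spec$n_subpops, N, s_t)
      rec <- stats::rpois(spec$n_subpops, N * pmax(mult[t] - s_t, 0))
      dead <- N - surv
      N <- surv + rec
    }
  }
  validate_monitoring(do.call(rbind, rows))
}

#' Generate synthetic reproduction samples
#'
#' Per tagged individual and year: stems ~ negative binomial; flowering
#' stems ~ binomial(stems, p_flower); flowers ~ Poisson per flowering stem;
#' fruits ~ binomial(flowers, fruit_set); sound seeds ~ binomial(2 x
#' fruits, p_seed); survival to the next season ~ Bernoulli(Sa).
#'
#' @param spec a [synth_spec()]
#' @param monitoring monitoring table (years taken from it)
#' @return a validated `reproduction_table`
#' @export
generate_reproduction <- function(spec, monitoring) {
  set.seed(derive_seed(spec$seed, 2))
  years <- sort(unique(monitoring$year))
  rows <- list()
  for (yr in years) {
    n <- spec$n_tagged
    stems <- stats::rnbinom(n, mu = spec$stems_mu, size = spec$stems_size)
    flstems <- stats::rbinom(n, stems, spec$p_flower)
    flowers <- stats::rpois(n, flstems * spec$flowers_per_stem_mean)
    fruits <- stats::rbinom(n, flowers, spec$fruit_set)
    seeds <- stats::rbinom(n, 2L * fruits, spec$p_seed)
    rows[[length(rows) + 1]] <- data.frame(
      individual_id = sprintf("Y%d_I%02d", yr, seq_len(n)),
      subpopulation = "SP1", year = yr,
      n_stems = stems, n_flowering_stems = flstems,
      flowers_per_stem = ifelse(flstems > 0, flowers / flstems, 0),
      fruits_per_flower = ifelse(flowers > 0, fruits / flowers, 0),
      sound_seeds_per_fruit = ifelse(fruits > 0, seeds / fruits, 0),
      seeds_per_stem = ifelse(flstems > 0, seeds / flstems, 0),
      alive_next_season = stats::runif(n) < spec$sa)
  }
  validate_reproduction(do.call(rbind, rows))
}

# one Dirichlet draw
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), alpha)
  x / sum(x)
}

#' Generate a synthetic SSR genotype table
#'
#' Ancestral allele frequencies are symmetric-Dirichlet; subpopulation
#' frequencies follow the Balding-Nichols model at the target FST
#' (Dirichlet with concentration `p (1-FST)/FST`). Genotypes are drawn with
#' inbreeding coefficient `fis` (a fraction `fis` of individuals carry two
#' copies of a single allele draw). A null allele segregates at each locus
#' at its specified rate: visible/null genotypes are recorded as visible
#' homozygotes and null/null genotypes as missing.
#'
#' @param spec a [synth_spec()]
#' @param sample_sizes individuals sampled per subpopulation (defaults to
#'   13, 15, 17, 13, 5 recycled to the subpopulation count)
#' @return a `genotype_table`
#' @export
generate_genotypes <- function(spec,
                               sample_sizes = c(13, 15, 17, 13, 5)) {
  set.seed(derive_seed(spec$seed, 3))
  sizes <- rep_len(sample_sizes, spec$n_subpops)
  subpops <- paste0("SP", seq_len(spec$n_subpops))
  n <- sum(sizes)
  pops <- rep(subpops, sizes)
  ids <- sprintf("%s_%02d", pops, unlist(lapply(sizes, seq_len)))
  loci <- paste0("L", seq_len(spec$n_loci))
  k <- rep_len(spec$n_alleles, spec$n_loci)
  r <- rep_len(spec$null_rates, spec$n_loci)
  a1 <- matrix(NA_integer_, n, spec$n_loci)
  a2 <- matrix(NA_integer_, n, spec$n_loci)
  true_freq <- vector("list", spec$n_loci)
  names(true_freq) <- loci
  for (l in seq_len(spec$n_loci)) {
    sizes_bp <- spec$allele_base + 5L * (seq_len(k[l]) - 1L) + 25L * (l - 1L)
    # ancestral visible frequencies: symmetric Dirichlet; the null allele is
    # a segregating variant like any other, so it enters the ancestral pool
    # at rate r and drifts with the rest
    anc_vis <- rdirichlet1(rep(2, k[l]))
    anc <- c(anc_vis * (1 - r[l]), r[l])
    conc <- (1 - spec$fst) / spec$fst
    true_freq[[l]] <- matrix(0, spec$n_subpops, k[l] + 1L,
                             dimnames = list(subpops,
                                             c(sizes_bp, "null")))
    for (pi in seq_along(subpops)) {
      # a single undivided population has no among-population drift: its
      # frequencies ARE the ancestral ones
      p_full <- if (spec$n_subpops == 1) anc
      else if (r[l] > 0) rdirichlet1(anc * conc)
      else c(rdirichlet1(anc_vis * conc), 0)
      true_freq[[l]][pi, ] <- p_full
      sel <- which(pops == subpops[pi])
      for (i in sel) {
        if (stats::runif(1) < spec$fis) {
          al <- sample.int(k[l] + 1L, 1, prob = p_full)
          g1 <- g2 <- al
        } else {
          g1 <- sample.int(k[l] + 1L, 1, prob = p_full)
          g2 <- sample.int(k[l] + 1L, 1, prob = p_full)
        }
        null1 <- g1 > k[l]; null2 <- g2 > k[l]
        if (null1 && null2) next            # missing (stays NA)
        if (null1) g1 <- g2                  # null/visible -> visible hom
        if (null2) g2 <- g1
        a1[i, l] <- sizes_bp[min(g1, g2)]
        a2[i, l] <- sizes_bp[max(g1, g2)]
      }
    }
  }
  out <- genotype_table(ids, pops, loci, a1, a2)
  # true per-subpopulation frequencies (visible alleles + null), for
  # estimator-accuracy checks against the realized differentiation
  attr(out, "true_freq") <- true_freq
  out
}

#' Generate synthetic occurrence coordinates
#'
#' Subpopulation centres are spaced evenly along a line segment (default
#' 30 km, oriented like the coastal cliff system, roughly NNW) and points
#' are jittered uniformly within a small local extent around each centre.
#'
#' @param spec a [synth_spec()]
#' @param base_lon,base_lat anchor of the line's southern end
#' @param bearing_deg line bearing in degrees clockwise from north
#' @return a validated `occurrence_table`
#' @export
generate_coordinates <- function(spec, base_lon = 20.7, base_lat = 37.66,
                                 bearing_deg = 340) {
  set.seed(derive_seed(spec$seed, 4))
  subpops <- paste0("SP", seq_len(spec$n_subpops))
  d <- seq(0, spec$coast_length_km, length.out = spec$n_subpops)
  theta <- bearing_deg * pi / 180
  rows <- list()
  for (i in seq_len(spec$n_subpops)) {
    dx <- d[i] * sin(theta) + stats::runif(spec$points_per_subpop,
                                           -spec$jitter_km, spec$jitter_km)
    dy <- d[i] * cos(theta) + stats::runif(spec$points_per_subpop,
                                           -spec$jitter_km, spec$jitter_km)
    rows[[i]] <- data.frame(
      subpopulation = subpops[i],
      lon = base_lon + dx / (111.32 * cos(base_lat * pi / 180)),
      lat = base_lat + dy / 111.32)
  }
  validate_coordinates(do.call(rbind, rows))
}

#' Generate replicate clustering log-probabilities with a known elbow
#'
#' Emulates the L(K) table of repeated Bayesian clustering runs: the mean
#' log-probability rises steeply up to the true cluster number and nearly
#' plateaus beyond it, with replicate noise. Used to exercise the Evanno
#' delta-K statistic.
#'
#' @param k_true location of the elbow
#' @param k_max largest K
#' @param n_reps replicates per K
#' @param noise_sd replicate sd of L(K)
#' @param seed RNG seed
#' @return data.frame with columns `K`, `rep`, `lnp`
#' @export
generate_lnk <- function(k_true = 3, k_max = 5, n_reps = 20, noise_sd = 2,
                         seed = 1) {
  set.seed(seed)
  ks <- 1:k_max
  mean_l <- ifelse(ks <= k_true,
                   -1000 + 100 * ks,
                   -1000 + 100 * k_true + 5 * (ks - k_true))
  do.call(rbind, lapply(ks, function(k) {
    data.frame(K = k, rep = seq_len(n_reps),
               lnp = stats::rnorm(n_reps, mean_l[k], noise_sd))
  }))
}

#' Write a full synthetic input bundle
#'
#' Generates all four pipeline inputs under one seed and writes them in the
#' documented CSV dialects.
#'
#' @param spec a [synth_spec()]
#' @param dir output directory (created if needed)
#' @return named list of the written file paths, invisibly; the generated
#'   objects are attached as attribute `data`
#' @export
generate_bundle <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mon <- generate_monitoring(spec)
  rep_tab <- generate_reproduction(spec, mon)
  coords <- generate_coordinates(spec)
  geno <- generate_genotypes(spec)
  paths <- list(
    monitoring = file.path(dir, "monitoring.csv"),
    reproduction = file.path(dir, "reproduction.csv"),
    coordinates = file.path(dir, "coordinates.csv"),
    genotypes = file.path(dir, "genotypes_genalex.csv"),
    genotypes_long = file.path(dir, "genotypes_long.csv"))
  utils::write.csv(mon, paths$monitoring, row.names = FALSE, quote = FALSE)
  utils::write.csv(rep_tab, paths$reproduction, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(coords, paths$coordinates, row.names = FALSE,
                   quote = FALSE)
  write_genotypes(geno, paths$genotypes, dialect = "genalex",
                  title = "synthetic SSR bundle")
  write_genotypes(geno, paths$genotypes_long, dialect = "long")
  log_info("synthetic bundle written to %s (seed %d)", dir, spec$seed)
  structure(paths, data = list(monitoring = mon, reproduction = rep_tab,
                               coordinates = coords, genotypes = geno))
}
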