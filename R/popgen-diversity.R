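#' Per-subpopulation allele frequencies
#'
#' Counts allele observations over non-missing diploid calls: each typed
#' individual contributes two allele observations per locus.
#'
#' @param g a `genotype_table`
#' @return list with `freq` (per locus, a pops x alleles frequency matrix;
#'   rows of untyped (pop, locus) cells are all-NA), `n_typed` (pops x loci
#'   matrix of typed individuals), `pops`, `loci`
#' @export
allele_frequencies <- function(g) {
  pops <- sort(unique(g$pops))
  n_typed <- typed_counts(g)
  freq <- lapply(seq_along(g$loci), function(l) {
    alleles <- sort(unique(c(g$a1[, l], g$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    m <- matrix(NA_real_, length(pops), length(alleles),
                dimnames = list(pops, as.character(alleles)))
    for (p in pops) {
      sel <- g$pops == p
      obs <- c(g$a1[sel, l], g$a2[sel, l])
      obs <- obs[!is.na(obs)]
      if (length(obs) > 0) {
        m[p, ] <- tabulate(match(obs, alleles),
                           nbins = length(alleles)) / length(obs)
      }
    }
    m
  })
  names(freq) <- g$loci
  list(freq = freq, n_typed = n_typed, pops = pops, loci = g$loci)
}

# per (pop, locus) summary statistics from one genotype table; the
# workhorse behind diversity() and f_statistics()
per_locus_stats <- function(g) {
  af <- allele_frequencies(g)
  rows <- list()
  for (l in seq_along(g$loci)) {
    fr <- af$freq[[l]]
    for (p in af$pops) {
      n <- af$n_typed[p, l]
      if (n == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          pop = p, locus = g$loci[l], n = 0L, na = NA_integer_,
          ne = NA_real_, ho = NA_real_, he = NA_real_, uhe = NA_real_,
          i = NA_real_, f = NA_real_)
        next
      }
      pvec <- fr[p, ]
      pvec <- pvec[pvec > 0]
      sel <- g$pops == p & !is.na(g$a1[, l])
      het <- mean(g$a1[sel, l] != g$a2[sel, l])
      sumsq <- sum(pvec^2)
      he <- 1 - sumsq
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, locus = g$loci[l], n = n, na = length(pvec),
        ne = 1 / sumsq, ho = het, he = he,
        uhe = he * (2 * n) / (2 * n - 1),
        i = -sum(pvec * log(pvec)),
        f = if (he > 0) 1 - het / he else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Genetic diversity summary
#'
#' Standard codominant-marker diversity statistics per subpopulation and
#' locus: allele count (Na), effective allele number (Ne = 1/sum p^2),
#' observed heterozygosity (Ho), expected heterozygosity (He = 1 - sum p^2),
#' its sample-size-unbiased form (uHe = He * 2N/(2N-1)), Shannon's index
#' (I = -sum p ln p), fixation index (F = 1 - Ho/He, undefined and excluded
#' from means at monomorphic loci), and the percentage of polymorphic loci
#' (P).
#'
#' @param g a `genotype_table`
#' @return list with `per_locus` (one row per pop x locus) and `by_pop`
#'   (across-locus mean and SE per subpopulation, plus N and P)
#' @export
diversity <- function(g) {
  per_locus <- per_locus_stats(g)
  pops <- sort(unique(g$pops))
  by_pop <- do.call(rbind, lapply(pops, function(p) {
    s <- per_locus[per_locus$pop == p & per_locus$n > 0, , drop = FALSE]
    row <- data.frame(pop = p, n = max(s$n),
                      p_polymorphic = 100 * mean(s$na >= 2))
    for (cn in c("na", "ne", "ho", "he", "uhe", "i", "f")) {
      x <- s[[cn]][is.finite(s[[cn]])]
      row[[paste0(cn, "_mean")]] <- mean(x)
      row[[paste0(cn, "_se")]] <- se_mean(x)
    }
    row
  }))
  rownames(by_pop) <- NULL
  list(per_locus = per_locus, by_pop = by_pop)
}

#' Polymorphism information content
#'
#' Botstein's PIC from pooled allele frequencies at one locus:
#' `1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p numeric vector of allele frequencies (will be normalised)
#' @return PIC value
#' @export
pic <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) {
    stop_endemica("pic needs at least one allele", "endemica_validation_error")
  }
  p <- p / sum(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' Observed genotype counts in one subpopulation at one locus are compared
#' with Hardy-Weinberg expectations computed from the sample allele
#' frequencies. Degrees of freedom are `k(k-1)/2` for `k` alleles; the
#' p-value comes from the upper chi-square tail. A warning flag is set when
#' any expected genotype count is below 5 (the asymptotic test is then
#' anti-conservative).
#'
#' @param g a `genotype_table`
#' @param pop subpopulation label
#' @param locus locus name
#' @return list with `chisq`, `df`, `p_value`, `n`, `k_alleles`,
#'   `low_expected` flag, `testable` flag (FALSE for monomorphic loci)
#' @export
hwe_chisq <- function(g, pop, locus) {
  l <- match(locus, g$loci)
  sel <- g$pops == pop & !is.na(g$a1[, l])
  a1 <- g$a1[sel, l]; a2 <- g$a2[sel, l]
  n <- length(a1)
  if (n == 0) {
    stop_endemica("locus untyped in this subpopulation",
                  "endemica_validation_error")
  }
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2) {
    return(list(chisq = NA_real_, df = 0L, p_value = NA_real_, n = n,
                k_alleles = k, low_expected = FALSE, testable = FALSE))
  }
  p <- tabulate(match(c(a1, a2), alleles), nbins = k) / (2 * n)
  # observed and expected counts over all k(k+1)/2 genotype classes
  g1 <- pmin(a1, a2); g2 <- pmax(a1, a2)
  obs_key <- paste(g1, g2)
  chisq <- 0; low <- FALSE
  for (i in seq_len(k)) {
    for (j in i:k) {
      e <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
      o <- sum(obs_key == paste(alleles[i], alleles[j]))
      if (e < 5) low <- TRUE
      if (e > 0) chisq <- chisq + (o - e)^2 / e
    }
  }
  df <- k * (k - 1) / 2
  list(chisq = chisq, df = as.integer(df),
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       n = n, k_alleles = k, low_expected = low, testable = TRUE)
}
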