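#' EM estimation of null-allele frequency
#'
#' Maximum-likelihood estimate of the frequency of a non-amplifying (null)
#' allele at one locus in one subpopulation, under Hardy-Weinberg
#' equilibrium with one null allele. The E-step allocates each observed
#' homozygote between the true-homozygote and visible/null-heterozygote
#' classes (weights `p_i / (p_i + 2 r)`), and counts missing genotypes as
#' null homozygotes; the M-step re-estimates all frequencies from the
#' expected counts. Iterated to `tol` on the max frequency change.
#'
#' @param g a `genotype_table`
#' @param pop subpopulation label
#' @param locus locus name
#' @param tol convergence tolerance (default 1e-8)
#' @param max_iter iteration cap (default 2000)
#' @return list with `r_null`, `visible_freq` (named, conditional on
#'   amplification, i.e. renormalised to sum 1), `iterations`, `converged`,
#'   `boundary` flag (all-missing input)
#' @export
null_allele_em <- function(g, pop, locus, tol = 1e-8, max_iter = 2000) {
  l <- match(locus, g$loci)
  sel <- g$pops == pop
  a1 <- g$a1[sel, l]; a2 <- g$a2[sel, l]
  n_total <- length(a1)
  miss <- is.na(a1)
  n_miss <- sum(miss)
  if (n_miss == n_total) {
    return(list(r_null = 1, visible_freq = numeric(0), iterations = 0L,
                converged = TRUE, boundary = TRUE))
  }
  alleles <- sort(unique(c(a1[!miss], a2[!miss])))
  k <- length(alleles)
  i1 <- match(a1[!miss], alleles); i2 <- match(a2[!miss], alleles)
  hom <- i1 == i2
  n_hom <- tabulate(i1[hom], nbins = k)           # visible homozygotes per allele
  n_het_allele <- tabulate(c(i1[!hom], i2[!hom]), nbins = k)
  # initial values: uniform visible alleles, null frequency from missingness
  r <- max(sqrt(n_miss / n_total), 0.05)
  p <- rep((1 - r) / k, k)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w <- ifelse(p + 2 * r > 0, p / (p + 2 * r), 1)   # P(true hom | observed hom)
    e_hom <- n_hom * w                                # true i/i
    e_null_het <- n_hom * (1 - w)                     # i/null
    p_new <- (2 * e_hom + e_null_het + n_het_allele) / (2 * n_total)
    r_new <- (sum(e_null_het) + 2 * n_miss) / (2 * n_total)
    delta <- max(abs(c(p_new - p, r_new - r)))
    p <- p_new; r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  vf <- if (r < 1) p / sum(p) else p
  names(vf) <- as.character(alleles)
  list(r_null = r, visible_freq = vf, iterations = it,
       converged = converged, boundary = FALSE)
}

#' Null-allele estimates for every (subpopulation, locus) cell
#'
#' @param g a `genotype_table`
#' @param ... passed to [null_allele_em()]
#' @return data.frame with `pop`, `locus`, `r_null`, `converged`, `boundary`
#' @export
null_allele_table <- function(g, ...) {
  pops <- sort(unique(g$pops))
  rows <- expand.grid(pop = pops, locus = g$loci, stringsAsFactors = FALSE)
  est <- Map(function(p, l) null_allele_em(g, p, l, ...), rows$pop, rows$locus)
  rows$r_null <- vapply(est, `[[`, numeric(1), "r_null")
  rows$converged <- vapply(est, `[[`, logical(1), "converged")
  rows$boundary <- vapply(est, `[[`, logical(1), "boundary")
  rows
}

# Weir & Cockerham (1984) theta components for one locus from per-pop
# sample sizes (n), allele frequencies (p, pops x alleles) and per-allele
# observed heterozygote frequencies (h, pops x alleles). Returns the summed
# a and a+b+c over alleles.
wc_components <- function(n, p, h) {
  r <- length(n)
  if (r < 2) return(c(a = 0, abc = 0))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  a_sum <- 0; abc_sum <- 0
  for (al in seq_len(ncol(p))) {
    pbar <- sum(n * p[, al]) / (r * nbar)
    s2 <- sum(n * (p[, al] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h[, al]) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  c(a = a_sum, abc = abc_sum)
}

# raw per-locus WC inputs from a genotype table
wc_locus_raw <- function(g, l) {
  pops <- sort(unique(g$pops))
  typed <- pops[vapply(pops, function(p)
    sum(g$pops == p & !is.na(g$a1[, l])) > 0, logical(1))]
  if (length(typed) < 2) return(NULL)
  alleles <- sort(unique(c(g$a1[, l], g$a2[, l])))
  alleles <- alleles[!is.na(alleles)]
  n <- numeric(length(typed))
  p <- matrix(0, length(typed), length(alleles))
  h <- matrix(0, length(typed), length(alleles))
  for (i in seq_along(typed)) {
    sel <- g$pops == typed[i] & !is.na(g$a1[, l])
    n[i] <- sum(sel)
    a1 <- g$a1[sel, l]; a2 <- g$a2[sel, l]
    obs <- c(a1, a2)
    p[i, ] <- tabulate(match(obs, alleles), nbins = length(alleles)) /
      length(obs)
    het <- a1 != a2
    for (al in seq_along(alleles)) {
      h[i, al] <- mean(het & (a1 == alleles[al] | a2 == alleles[al]))
    }
  }
  list(pops = typed, alleles = alleles, n = n, p = p, h = h)
}

#' Multi-locus Weir-Cockerham FST
#'
#' The theta estimator of Weir & Cockerham (1984) from raw genotype data:
#' per-locus, per-allele variance components a (among populations), b
#' (among individuals within populations) and c (within individuals),
#' summed over alleles and loci before taking the ratio.
#'
#' @param g a `genotype_table`
#' @return theta (NA when undefined)
#' @export
fst_weir_cockerham <- function(g) {
  a <- 0; abc <- 0
  for (l in seq_along(g$loci)) {
    cl <- wc_locus_raw(g, l)
    if (is.null(cl)) next
    w <- wc_components(cl$n, cl$p, cl$h)
    a <- a + w["a"]; abc <- abc + w["abc"]
  }
  if (abc == 0) return(NA_real_)
  unname(a / abc)
}

#' FST with and without the ENA null-allele correction
#'
#' Weir-Cockerham-style FST, reported both uncorrected (raw visible allele
#' counts) and ENA-corrected ("excluding null alleles"): per
#' (subpopulation, locus) cell the null allele is treated as an extra
#' allele whose frequency is estimated by [null_allele_em()]; the visible
#' allele frequencies are replaced by the EM estimates (left unrenormalised,
#' summing to 1 minus the null frequency, so each visible allele's per-pop
#' frequency is estimated free of the null-driven inflation) and the
#' variance components are summed over visible alleles only. Observed
#' heterozygosities are retained in both estimators. Bootstrap confidence
#' intervals resample loci with replacement.
#'
#' @param g a `genotype_table`
#' @param n_bootstrap bootstrap replicates over loci (default 10000)
#' @param seed RNG seed
#' @param conf confidence level (default 0.95)
#' @param pairwise also compute pairwise subpopulation matrices (default
#'   TRUE; disable for replicated simulations where only the global
#'   estimates are needed)
#' @return list with `fst_uncorrected`, `fst_corrected`, their bootstrap
#'   `ci_uncorrected` / `ci_corrected`, per-cell `null_estimates`, and
#'   pairwise matrices `pairwise_uncorrected`, `pairwise_corrected`
#' @export
fst_ena <- function(g, n_bootstrap = 10000, seed = NULL, conf = 0.95,
                    pairwise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(g$loci)
  pops <- sort(unique(g$pops))
  nulls <- null_allele_table(g)

  raw <- lapply(seq_len(L), function(l) wc_locus_raw(g, l))
  # ENA: swap raw per-pop visible frequencies for the EM estimates left on
  # the full-frequency scale (summing to 1 - r_null per pop); observed
  # heterozygosities and sample sizes are kept
  ena_components <- function(gg, raw_l, l) {
    if (is.null(raw_l)) return(NULL)
    p <- raw_l$p
    for (i in seq_along(raw_l$pops)) {
      em <- null_allele_em(gg, raw_l$pops[i], gg$loci[l])
      v <- setNames(rep(0, length(raw_l$alleles)),
                    as.character(raw_l$alleles))
      v[names(em$visible_freq)] <- em$visible_freq * (1 - em$r_null)
      p[i, ] <- v
    }
    list(pops = raw_l$pops, alleles = raw_l$alleles, n = raw_l$n, p = p,
         h = raw_l$h)
  }
  corr <- lapply(seq_len(L), function(l) ena_components(g, raw[[l]], l))

  theta_from <- function(comp_list, locus_idx) {
    a <- 0; abc <- 0
    for (l in locus_idx) {
      cl <- comp_list[[l]]
      if (is.null(cl)) next
      w <- wc_components(cl$n, cl$p, cl$h)
      a <- a + w["a"]; abc <- abc + w["abc"]
    }
    if (abc == 0) return(NA_real_)
    unname(a / abc)
  }

  fst_u <- theta_from(raw, seq_len(L))
  fst_c <- theta_from(corr, seq_len(L))

  if (L < 2) {
    warning("single locus: bootstrap CI over loci is degenerate")
    ci_u <- c(fst_u, fst_u); ci_c <- c(fst_c, fst_c)
  } else {
    boot_u <- numeric(n_bootstrap); boot_c <- numeric(n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(L, L, replace = TRUE)
      boot_u[b] <- theta_from(raw, idx)
      boot_c[b] <- theta_from(corr, idx)
    }
    alpha <- (1 - conf) / 2
    ci_u <- stats::quantile(boot_u, c(alpha, 1 - alpha), na.rm = TRUE,
                            names = FALSE)
    ci_c <- stats::quantile(boot_c, c(alpha, 1 - alpha), na.rm = TRUE,
                            names = FALSE)
  }

  pair_u <- matrix(NA_real_, length(pops), length(pops),
                   dimnames = list(pops, pops))
  pair_c <- pair_u
  diag(pair_u) <- diag(pair_c) <- 0
  if (pairwise) for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      sub <- subset_genotypes(g, g$pops %in% pops[c(i, j)])
      raw_ij <- lapply(seq_len(L), function(l) wc_locus_raw(sub, l))
      pair_u[i, j] <- pair_u[j, i] <- theta_from(raw_ij, seq_len(L))
      corr_ij <- lapply(seq_len(L), function(l)
        ena_components(sub, raw_ij[[l]], l))
      pair_c[i, j] <- pair_c[j, i] <- theta_from(corr_ij, seq_len(L))
    }
  }

  list(fst_uncorrected = fst_u, fst_corrected = fst_c,
       ci_uncorrected = ci_u, ci_corrected = ci_c,
       null_estimates = nulls,
       pairwise_uncorrected = pair_u, pairwise_corrected = pair_c)
}
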