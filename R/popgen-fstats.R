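# Per-locus heterozygosity components in Nei's (1977) decomposition with
# unweighted subpopulation means: Ho = mean observed het across typed pops,
# Hs = mean within-pop expected het, Ht = expected het of the unweighted
# mean allele frequencies.
h_components <- function(g) {
  af <- allele_frequencies(g)
  out <- data.frame(locus = g$loci, ho = NA_real_, hs = NA_real_,
                    ht = NA_real_, n_pops = 0L)
  for (l in seq_along(g$loci)) {
    typed <- af$pops[af$n_typed[, l] > 0]
    if (length(typed) < 2) next
    fr <- af$freq[[l]][typed, , drop = FALSE]
    he_pop <- 1 - rowSums(fr^2)
    ho_pop <- vapply(typed, function(p) {
      sel <- g$pops == p & !is.na(g$a1[, l])
      mean(g$a1[sel, l] != g$a2[sel, l])
    }, numeric(1))
    pbar <- colMeans(fr)
    out$ho[l] <- mean(ho_pop)
    out$hs[l] <- mean(he_pop)
    out$ht[l] <- 1 - sum(pbar^2)
    out$n_pops[l] <- length(typed)
  }
  out
}

# point estimates of FIS/FST/FIT per locus and from across-locus mean
# H components (loci with undefined Ht excluded)
fstat_point <- function(g) {
  h <- h_components(g)
  ok <- is.finite(h$ht) & h$ht > 0
  per_locus <- data.frame(
    locus = h$locus,
    fis = ifelse(ok & h$hs > 0, 1 - h$ho / h$hs, NA_real_),
    fst = ifelse(ok, 1 - h$hs / h$ht, NA_real_),
    fit = ifelse(ok, 1 - h$ho / h$ht, NA_real_),
    ho = h$ho, hs = h$hs, ht = h$ht)
  mh <- colMeans(h[ok, c("ho", "hs", "ht"), drop = FALSE])
  mean_stats <- c(fis = unname(1 - mh["ho"] / mh["hs"]),
                  fst = unname(1 - mh["hs"] / mh["ht"]),
                  fit = unname(1 - mh["ho"] / mh["ht"]))
  list(per_locus = per_locus, mean = mean_stats,
       mean_h = mh, excluded = h$locus[!ok])
}

#' Wright's F-statistics with permutation tests
#'
#' FIS, FST and FIT in the Nei (1977) heterozygosity decomposition with
#' unweighted subpopulation means (the convention of frequency-based
#' codominant analyses): per locus `FIS = 1 - Ho/Hs`, `FST = 1 - Hs/Ht`,
#' `FIT = 1 - Ho/Ht`, so that `(1-FIT) = (1-FIS)(1-FST)` holds exactly.
#' Across-locus means are computed from the mean H components. Significance:
#' FST by permuting individuals among subpopulations, FIS by re-pairing
#' alleles within each subpopulation (breaking heterozygote structure);
#' p-values use (b+1)/(m+1) smoothing.
#'
#' @param g a `genotype_table`
#' @param n_permutations permutation replicates (default 999)
#' @param seed RNG seed for the permutations
#' @return list with `per_locus` data.frame, `mean` named vector,
#'   `mean_h` components, `p_fst`, `p_fis`, `excluded` loci
#' @export
f_statistics <- function(g, n_permutations = 999, seed = NULL) {
  obs <- fstat_point(g)
  if (!is.null(seed)) set.seed(seed)
  b_fst <- 0L
  b_fis <- 0L
  n <- length(g$ids)
  fst_ok <- is.finite(obs$mean["fst"])
  fis_ok <- is.finite(obs$mean["fis"])
  for (b in seq_len(n_permutations)) {
    # FST null: individuals exchangeable among subpopulations
    if (fst_ok) {
      perm <- g
      perm$pops <- g$pops[sample.int(n)]
      if (isTRUE(fstat_point(perm)$mean["fst"] >=
                   obs$mean["fst"] - 1e-12)) {
        b_fst <- b_fst + 1L
      }
    }
    # FIS null: random union of gametes within each subpopulation
    if (fis_ok) {
      perm2 <- g
      for (p in unique(g$pops)) {
        for (l in seq_along(g$loci)) {
          sel <- which(g$pops == p & !is.na(g$a1[, l]))
          if (length(sel) < 2) next
          pool <- sample(c(g$a1[sel, l], g$a2[sel, l]))
          perm2$a1[sel, l] <- pool[seq_along(sel)]
          perm2$a2[sel, l] <- pool[length(sel) + seq_along(sel)]
        }
      }
      if (isTRUE(fstat_point(perm2)$mean["fis"] >=
                   obs$mean["fis"] - 1e-12)) {
        b_fis <- b_fis + 1L
      }
    }
  }
  obs$p_fst <- if (fst_ok) (b_fst + 1) / (n_permutations + 1) else NA_real_
  obs$p_fis <- if (fis_ok) (b_fis + 1) / (n_permutations + 1) else NA_real_
  obs$n_permutations <- n_permutations
  obs
}

#' Nei's (1978) unbiased genetic distance
#'
#' Pairwise distances between subpopulations using bias-corrected
#' within-population gene identities `(2N sum p^2 - 1) / (2N - 1)`,
#' averaged over loci before taking the logarithm:
#' `uD = -ln( mean(Jxy) / sqrt(mean(Jx) mean(Jy)) )`.
#' The unbiased correction can produce tiny negative identities at small N;
#' these are floored at `eps` with a warning. Populations sharing no alleles
#' have infinite distance, reported as `Inf`.
#'
#' @param g a `genotype_table`
#' @param eps floor applied to non-positive mean identities (default 1e-6)
#' @return symmetric matrix of unbiased distances
#' @export
nei_unbiased_distance <- function(g, eps = 1e-6) {
  af <- allele_frequencies(g)
  k <- length(af$pops)
  D <- matrix(0, k, k, dimnames = list(af$pops, af$pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      jx <- jy <- jxy <- numeric(0)
      for (l in seq_along(g$loci)) {
        nx <- af$n_typed[i, l]; ny <- af$n_typed[j, l]
        if (nx == 0 || ny == 0) next
        x <- af$freq[[l]][i, ]; y <- af$freq[[l]][j, ]
        jx <- c(jx, (2 * nx * sum(x^2) - 1) / (2 * nx - 1))
        jy <- c(jy, (2 * ny * sum(y^2) - 1) / (2 * ny - 1))
        jxy <- c(jxy, sum(x * y))
      }
      if (length(jx) == 0) {
        stop_endemica(sprintf("no shared typed locus between %s and %s",
                              af$pops[i], af$pops[j]),
                      "endemica_validation_error")
      }
      mjx <- mean(jx); mjy <- mean(jy); mjxy <- mean(jxy)
      if (mjx <= 0 || mjy <= 0) {
        warning("non-positive mean within-population identity floored")
        mjx <- max(mjx, eps); mjy <- max(mjy, eps)
      }
      D[i, j] <- D[j, i] <- if (mjxy <= 0) Inf else
        -log(mjxy / sqrt(mjx * mjy))
    }
  }
  D
}

#' Gene flow from FST
#'
#' Wright's island-model transform `Nm = (1 - FST) / (4 FST)`: the effective
#' number of migrants per generation consistent with the observed
#' differentiation.
#'
#' @param fst differentiation estimate in `(0, 1]`
#' @return migrants per generation
#' @export
gene_flow <- function(fst) {
  if (any(fst <= 0 | fst > 1)) {
    stop_endemica("gene_flow requires 0 < fst <= 1",
                  "endemica_validation_error")
  }
  (1 - fst) / (4 * fst)
}
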