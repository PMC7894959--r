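# Squared inter-individual genetic distance: per locus the allele-mismatch
# (infinite-allele) metric between diploid genotypes — 0 for an identical
# allele multiset, 1 for one shared allele, 2 for none. Loci missing in
# either individual are skipped and the sum is rescaled to the full locus
# count.
amova_distance <- function(g) {
  n <- length(g$ids)
  L <- length(g$loci)
  D <- matrix(0, n, n)
  typed <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    ok <- !is.na(a1)
    for (i in seq_len(n - 1)) {
      if (!ok[i]) next
      js <- which(ok & seq_len(n) > i)
      if (length(js) == 0) next
      hom_i <- a1[i] == a2[i]
      hom_j <- a1[js] == a2[js]
      # multiset intersection of {a1[i], a2[i]} and {a1[j], a2[j]}:
      # sum over allele values of min(copies in i, copies in j)
      inter <- integer(length(js))
      if (hom_i) {
        inter <- ifelse(hom_j,
                        2L * (a1[js] == a1[i]),
                        (a1[js] == a1[i]) + (a2[js] == a1[i]))
      } else {
        inter <- ifelse(hom_j,
                        (a1[js] == a1[i]) + (a1[js] == a2[i]),
                        (a1[js] == a1[i] | a1[js] == a2[i]) +
                          (a2[js] == a1[i] | a2[js] == a2[i]))
      }
      d <- 2L - inter
      D[i, js] <- D[i, js] + d
      D[js, i] <- D[i, js]
      typed[i, js] <- typed[i, js] + 1L
      typed[js, i] <- typed[i, js]
    }
  }
  scale <- ifelse(typed > 0, L / typed, 0)
  D * scale
}

# sums of squares for a grouping, from a fixed squared-distance matrix
amova_ss <- function(d2, pops) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (p in unique(pops)) {
    sel <- which(pops == p)
    if (length(sel) < 2) next
    sub <- d2[sel, sel, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(sel)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' Analysis of molecular variance (two-level)
#'
#' Partitions genotypic variance among and within subpopulations from
#' squared inter-individual distances (allele-mismatch metric, the
#' codominant default of frequency-based packages). Variance components
#' follow the standard nested ANOVA expectations; Phi_ST is the
#' among-subpopulation fraction; significance comes from permuting
#' individuals among subpopulations with (b+1)/(m+1) smoothing. Negative
#' variance components are truncated to 0 and flagged.
#'
#' @param g a `genotype_table`
#' @param n_permutations label permutations (default 9999)
#' @param seed RNG seed
#' @return list with the AMOVA `table` (df, SS, MS), variance components,
#'   `pct_among` / `pct_within`, `phi_st`, `p_value`, `truncated` flag
#' @export
amova <- function(g, n_permutations = 9999, seed = NULL) {
  # drop subpopulations with fewer than 2 individuals typed at >= 1 locus
  typed_any <- rowSums(!is.na(g$a1)) > 0
  keep_pops <- names(which(table(g$pops[typed_any]) >= 2))
  if (length(keep_pops) < length(unique(g$pops))) {
    warning("subpopulation(s) with < 2 typed individuals excluded from AMOVA")
  }
  if (length(keep_pops) < 2) {
    stop_endemica("AMOVA needs >= 2 subpopulations with >= 2 typed individuals",
                  "endemica_validation_error")
  }
  g <- subset_genotypes(g, typed_any & g$pops %in% keep_pops)
  d2 <- amova_distance(g)
  pops <- g$pops
  n <- length(pops)
  k <- length(unique(pops))
  ss <- amova_ss(d2, pops)
  df_among <- k - 1
  df_within <- n - k
  ms_among <- ss["among"] / df_among
  ms_within <- ss["within"] / df_within
  sizes <- as.numeric(table(pops))
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  var_within <- unname(ms_within)
  var_among <- unname((ms_among - ms_within) / n0)
  truncated <- FALSE
  if (var_among < 0) { var_among <- 0; truncated <- TRUE }
  total <- var_among + var_within
  phi <- if (total > 0) var_among / total else 0

  if (!is.null(seed)) set.seed(seed)
  b <- 0L
  for (i in seq_len(n_permutations)) {
    pp <- pops[sample.int(n)]
    ssp <- amova_ss(d2, pp)
    msa <- ssp["among"] / df_among
    msw <- ssp["within"] / df_within
    va <- max((msa - msw) / n0, 0)
    phi_p <- if (va + msw > 0) va / (va + msw) else 0
    if (phi_p >= phi - 1e-12) b <- b + 1L
  }
  p_value <- (b + 1) / (n_permutations + 1)

  list(
    table = data.frame(
      source = c("among subpopulations", "within subpopulations", "total"),
      df = c(df_among, df_within, n - 1),
      ss = unname(c(ss["among"], ss["within"], ss["total"])),
      ms = c(unname(ms_among), unname(ms_within), NA)),
    var_among = var_among, var_within = var_within,
    pct_among = 100 * phi, pct_within = 100 * (1 - phi),
    phi_st = phi, p_value = p_value, truncated = truncated,
    n_permutations = n_permutations)
}
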