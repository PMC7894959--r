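test_that("allele frequencies count non-missing diploid calls", {
  g <- make_genotypes(list(P = rbind(c(150, 150), c(150, 175))))
  af <- allele_frequencies(g)
  expect_equal(unname(af$freq$L1["P", ]), c(0.75, 0.25))

  g2 <- make_genotypes(list(
    A = rbind(c(150, 150), c(NA, NA)),
    B = rbind(c(NA, NA), c(NA, NA))))
  af2 <- allele_frequencies(g2)
  expect_true(all(is.na(af2$freq$L1["B", ])))
  expect_equal(af2$n_typed["B", "L1"], 0L)
})

test_that("diversity statistics match closed forms in the symmetric case", {
  # 10 individuals, two alleles at 0.5/0.5, everyone heterozygous
  g <- make_genotypes(list(P = matrix(rep(c(150, 175), 10), ncol = 2,
                                      byrow = TRUE)))
  per <- diversity(g)$per_locus
  expect_equal(per$he, 0.5)
  expect_equal(per$uhe, 0.5 * 20 / 19, tolerance = 1e-12)
  expect_equal(per$ho, 1)
  expect_equal(per$ne, 2)
  expect_equal(per$i, log(2), tolerance = 1e-12)
  expect_equal(per$f, -1)
})

test_that("monomorphic loci are degenerate and excluded from F means", {
  g <- make_genotypes(list(P = rbind(c(150, 150, 150, 175),
                                     c(150, 150, 150, 150))))
  per <- diversity(g)$per_locus
  l1 <- per[per$locus == "L1", ]
  expect_equal(l1$na, 1L)
  expect_equal(l1$he, 0)
  expect_equal(l1$i, 0)
  expect_true(is.na(l1$f))
  by_pop <- diversity(g)$by_pop
  expect_equal(by_pop$p_polymorphic, 50)
  expect_false(is.na(by_pop$f_mean))  # mean over the polymorphic locus only
})

test_that("diversity agrees exactly with a brute-force recount", {
  set.seed(77)
  for (rep in 1:5) {
    spec <- synth_spec(seed = 600 + rep)
    g <- generate_genotypes(spec, sample_sizes = c(6, 8, 5, 7, 4))
    per <- diversity(g)$per_locus
    for (row in seq_len(nrow(per))) {
      p <- per$pop[row]; l <- match(per$locus[row], g$loci)
      sel <- g$pops == p
      o <- oracle_diversity_cell(g$a1[sel, l], g$a2[sel, l])
      if (is.null(o)) {
        expect_equal(per$n[row], 0L)
        next
      }
      expect_equal(per$na[row], o$na)
      expect_equal(per$ne[row], o$ne, tolerance = 1e-12)
      expect_equal(per$ho[row], o$ho, tolerance = 1e-12)
      expect_equal(per$uhe[row], o$uhe, tolerance = 1e-12)
      expect_equal(per$i[row], o$i, tolerance = 1e-12)
    }
  }
})

test_that("PIC follows Botstein's formula", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(pic(rep(1 / 3, 3)), 0.5925926, tolerance = 1e-6)
  # PIC never exceeds expected heterozygosity
  set.seed(5)
  for (rep in 1:20) {
    x <- rgamma(4, 1)
    p <- x / sum(x)
    expect_lte(pic(p), 1 - sum(p^2) + 1e-12)
  }
})

test_that("HWE chi-square matches hand computation and has nominal size", {
  hw <- make_genotypes(list(P = matrix(c(rep(c(150, 150), 25),
                                         rep(c(150, 175), 50),
                                         rep(c(175, 175), 25)),
                                       ncol = 2, byrow = TRUE)))
  res <- hwe_chisq(hw, "P", "L1")
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  split2 <- make_genotypes(list(P = matrix(c(rep(c(150, 150), 50),
                                             rep(c(175, 175), 50)),
                                           ncol = 2, byrow = TRUE)))
  res2 <- hwe_chisq(split2, "P", "L1")
  expect_equal(res2$chisq, 100, tolerance = 1e-9)
  expect_equal(res2$df, 1L)

  mono <- make_genotypes(list(P = rbind(c(150, 150), c(150, 150))))
  expect_false(hwe_chisq(mono, "P", "L1")$testable)

  # type-I error close to nominal alpha on simulated HWE populations
  set.seed(911)
  alleles <- c(150L, 175L)
  rejections <- vapply(1:400, function(i) {
    draws <- matrix(sample(alleles, 200, replace = TRUE), ncol = 2)
    g <- make_genotypes(list(P = draws))
    res <- hwe_chisq(g, "P", "L1")
    isTRUE(res$p_value < 0.05)
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("F-statistics honour their partition identity and null cases", {
  # identical HWE subpopulations: FST near zero
  set.seed(12)
  draw <- function(n) matrix(sample(c(150L, 175L), 2 * n, replace = TRUE,
                                    prob = c(0.6, 0.4)), ncol = 2)
  g <- make_genotypes(list(A = draw(200), B = draw(200)))
  fs <- fstat <- f_statistics(g, n_permutations = 199, seed = 4)
  expect_lt(abs(fs$mean["fst"]), 0.01)
  expect_gt(fs$p_fst, 0.05)

  # fixed alternative alleles: complete differentiation
  gf <- make_genotypes(list(A = rbind(c(150, 150), c(150, 150)),
                            B = rbind(c(175, 175), c(175, 175))))
  ff <- f_statistics(gf, n_permutations = 49, seed = 1)
  expect_equal(unname(ff$mean["fst"]), 1)

  # per-locus identity (1-FIT) = (1-FIS)(1-FST)
  spec <- synth_spec(seed = 33)
  gs <- generate_genotypes(spec)
  fss <- f_statistics(gs, n_permutations = 9, seed = 2)
  pl <- fss$per_locus
  expect_equal((1 - pl$fit), (1 - pl$fis) * (1 - pl$fst), tolerance = 1e-9)
  expect_true(all(pl$fst >= 0 & pl$fst <= 1))
})

test_that("F-statistics equal an independently coded direct formula", {
  set.seed(61)
  spec <- synth_spec(seed = 610)
  g <- generate_genotypes(spec, sample_sizes = c(7, 6, 8, 5, 4))
  pl <- f_statistics(g, n_permutations = 9, seed = 1)$per_locus
  for (l in seq_along(g$loci)) {
    pop_calls <- lapply(sort(unique(g$pops)), function(p) {
      sel <- g$pops == p
      list(g$a1[sel, l], g$a2[sel, l])
    })
    o <- oracle_fstats_locus(pop_calls)
    expect_equal(unname(pl$fis[l]), unname(o["fis"]), tolerance = 1e-12)
    expect_equal(unname(pl$fst[l]), unname(o["fst"]), tolerance = 1e-12)
    expect_equal(unname(pl$fit[l]), unname(o["fit"]), tolerance = 1e-12)
  }
})

test_that("Nei's unbiased distance matches its direct formula", {
  # identical large populations: distance ~ 0
  set.seed(8)
  draw <- function(n) matrix(sample(c(150L, 175L, 180L), 2 * n,
                                    replace = TRUE,
                                    prob = c(0.5, 0.3, 0.2)), ncol = 2)
  g0 <- make_genotypes(list(A = draw(400), B = draw(400)))
  expect_lt(abs(nei_unbiased_distance(g0)["A", "B"]), 0.01)

  # disjoint fixed alleles: infinite distance
  gf <- make_genotypes(list(A = rbind(c(150, 150), c(150, 150)),
                            B = rbind(c(175, 175), c(175, 175))))
  expect_equal(nei_unbiased_distance(gf)["A", "B"], Inf)

  # random case against the oracle
  spec <- synth_spec(seed = 55)
  g <- generate_genotypes(spec, sample_sizes = c(9, 11, 6, 8, 5))
  D <- nei_unbiased_distance(g)
  af <- allele_frequencies(g)
  fx <- lapply(af$freq, function(m) {v <- m["SP1", ]; v[v > 0]})
  fy <- lapply(af$freq, function(m) {v <- m["SP2", ]; v[v > 0]})
  o <- oracle_nei(fx, fy, af$n_typed["SP1", ], af$n_typed["SP2", ])
  expect_equal(D["SP1", "SP2"], o, tolerance = 1e-12)
})

test_that("gene flow is Wright's island-model transform", {
  expect_equal(gene_flow(0.2), 1)
  expect_equal(gene_flow(1), 0)
  expect_equal(gene_flow(0.164), 1.274, tolerance = 1e-3)
  expect_error(gene_flow(0), class = "endemica_validation_error")
})

test_that("null-allele EM recovers generating frequencies", {
  # HWE data with no homozygote excess: r-hat near 0
  set.seed(14)
  draw <- matrix(sample(c(150L, 175L), 1000, replace = TRUE), ncol = 2)
  g0 <- make_genotypes(list(P = draw))
  em0 <- null_allele_em(g0, "P", "L1")
  expect_true(em0$converged)
  expect_lt(em0$r_null, 0.05)

  # generating r = 0.25 at n = 500 recovered within 0.05
  spec <- synth_spec(n_subpops = 1, initial_sizes = 500, n_loci = 1,
                     n_alleles = 4, fis = 0, null_rates = 0.25, seed = 99)
  g <- generate_genotypes(spec, sample_sizes = 500)
  em <- null_allele_em(g, "SP1", "L1")
  expect_true(em$converged)
  expect_lt(abs(em$r_null - 0.25), 0.05)

  # fully missing locus sits at the boundary
  gm <- genotype_table(c("a", "b"), c("P", "P"), "L1",
                       matrix(NA_integer_, 2), matrix(NA_integer_, 2))
  emb <- null_allele_em(gm, "P", "L1")
  expect_equal(emb$r_null, 1)
  expect_true(emb$boundary)
})

test_that("ENA correction is a no-op without nulls and collapses under
           permuted labels", {
  spec <- synth_spec(n_alleles = 5, fis = 0, null_rates = 0, seed = 77)
  g <- generate_genotypes(spec, sample_sizes = rep(15, 5))
  fe <- fst_ena(g, n_bootstrap = 50, seed = 3, pairwise = FALSE)
  expect_equal(fe$fst_corrected, fe$fst_uncorrected, tolerance = 0.02)
  expect_lte(fe$ci_uncorrected[1], fe$fst_uncorrected)
  expect_gte(fe$ci_uncorrected[2], fe$fst_uncorrected)

  set.seed(31)
  gp <- g
  gp$pops <- sample(g$pops)
  fp <- fst_ena(gp, n_bootstrap = 10, pairwise = FALSE)
  expect_lt(abs(fp$fst_corrected), 0.05)
})

test_that("the Weir-Cockerham estimator tracks the realized FST", {
  # accuracy against the generator's true drawn frequencies: the estimator
  # error is far smaller than the evolutionary spread of realized FST
  errs <- vapply(1:25, function(i) {
    spec <- synth_spec(n_loci = 10, fis = 0, null_rates = 0,
                       seed = 8200 + i)
    g <- generate_genotypes(spec, sample_sizes = rep(15, 5))
    tf <- attr(g, "true_freq")
    num <- 0; den <- 0
    for (l in seq_along(tf)) {
      P <- tf[[l]][, -ncol(tf[[l]]), drop = FALSE]  # visible alleles
      P <- P / rowSums(P)
      num <- num + sum(apply(P, 2, stats::var))
      den <- den + sum(colMeans(P) * (1 - colMeans(P)))
    }
    fst_weir_cockerham(g) - num / den
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.03), 0.9)
})

test_that("AMOVA components match a hand-computed toy instance", {
  # 3 individuals per pop, 2 pops, 1 locus
  g <- make_genotypes(list(
    A = rbind(c(150, 150), c(150, 175), c(150, 150)),
    B = rbind(c(175, 175), c(175, 175), c(150, 175))))
  # pairwise squared distances (allele mismatch):
  d2 <- matrix(0, 6, 6)
  gl <- rbind(c(150, 150), c(150, 175), c(150, 150),
              c(175, 175), c(175, 175), c(150, 175))
  for (i in 1:5) for (j in (i + 1):6) {
    inter <- sum(pmin(table(factor(gl[i, ], levels = c(150, 175))),
                      table(factor(gl[j, ], levels = c(150, 175)))))
    d2[i, j] <- d2[j, i] <- 2 - inter
  }
  ss_total <- sum(d2[upper.tri(d2)]) / 6
  ss_within <- sum(d2[1:3, 1:3][upper.tri(diag(3))]) / 3 +
    sum(d2[4:6, 4:6][upper.tri(diag(3))]) / 3
  res <- amova(g, n_permutations = 9, seed = 1)
  expect_equal(res$table$ss[3], ss_total, tolerance = 1e-12)
  expect_equal(res$table$ss[2], ss_within, tolerance = 1e-12)
  expect_equal(res$table$ss[1], ss_total - ss_within, tolerance = 1e-12)
  expect_equal(res$table$df[1:2], c(1, 4))
  expect_equal(res$pct_among + res$pct_within, 100, tolerance = 1e-9)
})

test_that("AMOVA finds no structure in cloned subpopulations", {
  block <- rbind(c(150, 150), c(150, 175), c(175, 175), c(150, 175))
  g <- make_genotypes(list(A = block, B = block, C = block))
  res <- amova(g, n_permutations = 199, seed = 6)
  expect_lt(res$pct_among, 1)
  expect_gt(res$p_value, 0.5)
})

test_that("AMOVA on paper-like synthetic differentiation is near one fifth
           among subpopulations", {
  spec <- synth_spec(seed = 424)   # defaults: FST 0.16, FIS 0.46, nulls on
  g <- generate_genotypes(spec)
  res <- amova(g, n_permutations = 99, seed = 7)
  expect_gt(res$pct_among, 21 - 8)
  expect_lt(res$pct_among, 21 + 8)
  expect_lt(res$p_value, 0.05)
})

test_that("PCoA recovers planar configurations and rejects bad input", {
  pts <- cbind(c(0, 3, 3, 0), c(0, 0, 2, 2))
  d <- as.matrix(dist(pts))
  pc <- pcoa(d)
  expect_gte(ncol(pc$coordinates), 2)
  # metric recovery: inter-point distances reproduced exactly
  expect_equal(as.numeric(dist(pc$coordinates[, 1:2])),
               as.numeric(dist(pts)), tolerance = 1e-9)
  # Procrustes residual against the generating configuration ~ 0
  proc <- vegan::procrustes(pts, pc$coordinates[, 1:2])
  expect_lt(proc$ss, 1e-9)

  pc0 <- pcoa(matrix(0, 4, 4))
  expect_true(all(pc0$coordinates == 0))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), class = "endemica_validation_error")
  expect_lte(sum(pc$pct_variance[1:2]), 100 + 1e-9)
})

test_that("Evanno delta-K flags flat profiles and finds constructed elbows", {
  flat <- data.frame(K = rep(1:4, each = 3), rep = rep(1:3, 4),
                     lnp = rep(1:4, each = 3) * -50)
  ev <- evanno_delta_k(flat)
  expect_true(all(ev$summary$sd_zero))
  expect_true(all(is.na(ev$summary$delta_k)))

  lnk <- generate_lnk(k_true = 3, k_max = 5, n_reps = 20, seed = 17)
  ev2 <- evanno_delta_k(lnk)
  expect_equal(ev2$best_k, 3)
  # hand-computed delta-K at the elbow
  L <- reshape(lnk, idvar = "rep", timevar = "K", direction = "wide")
  second <- abs(L$lnp.4 - 2 * L$lnp.3 + L$lnp.2)
  expect_equal(ev2$summary$delta_k[3], mean(second) / sd(L$lnp.3),
               tolerance = 1e-12)

  # scaling all log-probabilities leaves the argmax unchanged
  lnk_scaled <- transform(lnk, lnp = lnp * 3.7)
  expect_equal(evanno_delta_k(lnk_scaled)$best_k, 3)
})
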