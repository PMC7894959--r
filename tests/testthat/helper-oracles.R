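# Independent brute-force oracles used across the suite. These are written
# naively and separately from the package implementations on purpose.

# Convex hull area by edge enumeration: (i, j) is a hull edge iff every
# other point lies on one side of the line through i and j; hull vertices
# are then ordered by angle around the centroid and the shoelace formula
# applied. O(n^3); collinear inputs give area 0.
oracle_hull_area <- function(x, y) {
  n <- length(x)
  pts <- unique(data.frame(x = x, y = y))
  x <- pts$x; y <- pts$y; n <- length(x)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cross <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      cross <- cross[-c(i, j)]
      if (all(cross >= -1e-12) || all(cross <= 1e-12)) {
        on_hull[i] <- on_hull[j] <- TRUE
      }
    }
  }
  hx <- x[on_hull]; hy <- y[on_hull]
  if (length(hx) < 3) return(0)
  ord <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[ord]; hy <- hy[ord]
  k <- length(hx)
  abs(sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)) / 2
}

# Exhaustive AOO oracle: scan every candidate cell of the bounding grid and
# count those containing at least one point.
oracle_aoo_cells <- function(x, y, cell, origin = c(0, 0)) {
  ix <- range(floor((x - origin[1]) / cell))
  iy <- range(floor((y - origin[2]) / cell))
  count <- 0L
  for (cx in ix[1]:ix[2]) {
    for (cy in iy[1]:iy[2]) {
      inside <- x >= origin[1] + cx * cell & x < origin[1] + (cx + 1) * cell &
        y >= origin[2] + cy * cell & y < origin[2] + (cy + 1) * cell
      if (any(inside)) count <- count + 1L
    }
  }
  count
}

# Naive per-(pop, locus) diversity recount straight from genotype vectors.
oracle_diversity_cell <- function(a1, a2) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n == 0) return(NULL)
  alleles <- unique(c(a1, a2))
  p <- vapply(alleles, function(a) sum(a1 == a) + sum(a2 == a),
              numeric(1)) / (2 * n)
  names(p) <- as.character(alleles)
  he <- 1 - sum(p^2)
  list(n = n, na = length(alleles), ne = 1 / sum(p^2),
       ho = sum(a1 != a2) / n, he = he, uhe = he * 2 * n / (2 * n - 1),
       i = -sum(p * log(p)), p = p)
}

# Direct-formula F-statistics for one locus over a list of (a1, a2) pairs
# per subpopulation.
oracle_fstats_locus <- function(pop_calls) {
  cells <- lapply(pop_calls, function(cc) oracle_diversity_cell(cc[[1]],
                                                                cc[[2]]))
  cells <- Filter(Negate(is.null), cells)
  ho <- mean(vapply(cells, `[[`, numeric(1), "ho"))
  hs <- mean(vapply(cells, `[[`, numeric(1), "he"))
  alleles <- unique(unlist(lapply(cells, function(cl) names(cl$p))))
  pmat <- t(vapply(cells, function(cl) {
    v <- setNames(rep(0, length(alleles)), alleles)
    v[names(cl$p)] <- cl$p
    v
  }, numeric(length(alleles))))
  pbar <- colMeans(pmat)
  ht <- 1 - sum(pbar^2)
  c(fis = 1 - ho / hs, fst = 1 - hs / ht, fit = 1 - ho / ht)
}

# Direct Nei (1978) unbiased distance between two pops from per-locus
# frequency vectors and sample sizes.
oracle_nei <- function(freq_x, freq_y, n_x, n_y) {
  jx <- mapply(function(f, n) (2 * n * sum(f^2) - 1) / (2 * n - 1),
               freq_x, n_x)
  jy <- mapply(function(f, n) (2 * n * sum(f^2) - 1) / (2 * n - 1),
               freq_y, n_y)
  jxy <- mapply(function(fx, fy) {
    alleles <- union(names(fx), names(fy))
    vx <- setNames(rep(0, length(alleles)), alleles); vx[names(fx)] <- fx
    vy <- setNames(rep(0, length(alleles)), alleles); vy[names(fy)] <- fy
    sum(vx * vy)
  }, freq_x, freq_y)
  -log(mean(jxy) / sqrt(mean(jx) * mean(jy)))
}

# Galton-Watson extinction recursion for Poisson offspring mean m.
oracle_gw_extinction <- function(m, horizon) {
  q <- numeric(horizon)
  cur <- 0
  for (t in seq_len(horizon)) {
    cur <- exp(m * (cur - 1))
    q[t] <- cur
  }
  q
}

# build a genotype_table from a compact list: one entry per subpopulation,
# each a matrix with two columns per locus (allele pairs), NA = missing
make_genotypes <- function(pop_list, loci = NULL) {
  pops <- rep(names(pop_list), vapply(pop_list, nrow, integer(1)))
  mat <- do.call(rbind, pop_list)
  L <- ncol(mat) / 2
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  a1 <- mat[, seq(1, 2 * L, by = 2), drop = FALSE]
  a2 <- mat[, seq(2, 2 * L, by = 2), drop = FALSE]
  genotype_table(sprintf("i%03d", seq_along(pops)), pops, loci, a1, a2)
}

# path to a bundled monitoring-era fixture
extdata <- function(name) {
  system.file("extdata", name, package = "endemica", mustWork = TRUE)
}
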