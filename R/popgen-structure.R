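#' Principal coordinates analysis
#'
#' Classical metric scaling of a symmetric distance matrix: Gower
#' double-centring of the squared distances followed by eigendecomposition
#' (delegated to [stats::cmdscale()], which implements exactly this). Axes
#' are ordered by decreasing eigenvalue; axes with negative eigenvalues
#' (possible for non-Euclidean genetic distances) are reported but carry no
#' coordinates.
#'
#' @param d symmetric distance matrix with zero diagonal
#' @return list with `coordinates` (rows = objects, columns = retained
#'   axes), `eigenvalues` (all, including any negative ones), and
#'   `pct_variance` per retained axis (share of the positive eigenvalue sum)
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop_endemica("pcoa requires a symmetric distance matrix",
                  "endemica_validation_error")
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop_endemica("pcoa requires a zero diagonal",
                  "endemica_validation_error")
  }
  n <- nrow(d)
  if (all(d == 0)) {
    return(list(coordinates = matrix(0, n, 1,
                                     dimnames = list(rownames(d), "Axis1")),
                eigenvalues = rep(0, n), pct_variance = NA_real_))
  }
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- mds$eig
  pos <- which(eig > 1e-12)
  coords <- mds$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  rownames(coords) <- rownames(d)
  list(coordinates = coords, eigenvalues = eig,
       pct_variance = 100 * eig[pos] / sum(eig[pos]))
}

#' Evanno delta-K from clustering log-probabilities
#'
#' Given replicate log-probabilities L(K) of Bayesian clustering runs for
#' consecutive K, computes the second-difference statistic
#' `deltaK(K) = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K))`, pairing
#' replicates by run index, and reports the K maximising it. deltaK is
#' defined only for interior K and requires a non-zero sd of L(K); zero-sd
#' cells are flagged.
#'
#' @param lnp data.frame with columns `K` (integer), `lnp` (replicate
#'   log-probability), and optionally `rep` (run index; defaults to order
#'   within K)
#' @return list with `summary` (per K: mean, sd, n replicates, delta_k,
#'   sd_zero flag) and `best_k` (argmax of delta_k; NA if none defined)
#' @export
evanno_delta_k <- function(lnp) {
  ks <- sort(unique(lnp$K))
  if (length(ks) < 3 || any(diff(ks) != 1)) {
    stop_endemica("evanno_delta_k needs >= 3 consecutive K values",
                  "endemica_validation_error")
  }
  if (is.null(lnp$rep)) {
    lnp$rep <- stats::ave(seq_len(nrow(lnp)), lnp$K, FUN = seq_along)
  }
  reps <- sort(unique(lnp$rep))
  if (min(table(lnp$K)) < 2) {
    stop_endemica("evanno_delta_k needs >= 2 replicates per K",
                  "endemica_validation_error")
  }
  L <- matrix(NA_real_, length(reps), length(ks),
              dimnames = list(NULL, ks))
  L[cbind(match(lnp$rep, reps), match(lnp$K, ks))] <- lnp$lnp
  mean_l <- colMeans(L)
  sd_l <- apply(L, 2, stats::sd)
  delta <- rep(NA_real_, length(ks))
  for (j in seq_along(ks)[-c(1, length(ks))]) {
    second <- abs(L[, j + 1] - 2 * L[, j] + L[, j - 1])
    if (sd_l[j] > 0) delta[j] <- mean(second, na.rm = TRUE) / sd_l[j]
  }
  summary <- data.frame(K = ks, mean_lnp = mean_l, sd_lnp = sd_l,
                        n_reps = as.integer(table(lnp$K)[as.character(ks)]),
                        delta_k = delta, sd_zero = sd_l == 0)
  best <- if (all(is.na(delta))) NA_integer_ else
    ks[which.max(replace(delta, is.na(delta), -Inf))]
  list(summary = summary, best_k = best)
}
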