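#' Validate a monitoring table
#'
#' A monitoring table holds one row per subpopulation and census year with
#' counts of mature, seedling, non-reproductive and dead individuals plus the
#' local extent of occurrence (the minimum area actually occupied by the
#' subpopulation, in m^2).
#'
#' @param df data.frame with columns `subpopulation`, `year`, `n_mature`,
#'   `n_seedlings`, `n_nonreproductive`, `n_dead`, `local_eoo_m2`
#' @return the validated data.frame, invisibly classed `monitoring_table`
#' @export
validate_monitoring <- function(df) {
  required <- c("subpopulation", "year", "n_mature", "n_seedlings",
                "n_nonreproductive", "n_dead", "local_eoo_m2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_endemica(sprintf("monitoring table is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "endemica_schema_error")
  }
  counts <- c("n_mature", "n_seedlings", "n_nonreproductive", "n_dead")
  for (col in counts) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0) {
      stop_endemica(sprintf("negative or missing %s at row %d", col, bad[1]),
                    "endemica_validation_error")
    }
  }
  bad <- which(!is.finite(df$local_eoo_m2) | df$local_eoo_m2 <= 0)
  if (length(bad) > 0) {
    stop_endemica(sprintf("local_eoo_m2 must be > 0 (row %d)", bad[1]),
                  "endemica_validation_error")
  }
  key <- paste(df$subpopulation, df$year)
  if (anyDuplicated(key)) {
    stop_endemica("duplicate (subpopulation, year) rows in monitoring table",
                  "endemica_validation_error")
  }
  class(df) <- unique(c("monitoring_table", class(df)))
  df
}

#' Validate a reproductive-sample table
#'
#' One row per tagged mature individual per season: stem counts, flowering
#' stems, per-stem flower/fruit/seed measurements and (optionally) whether
#' the plant was found alive in the following flowering period. The fruit is
#' a schizocarp of two one-seeded mericarps, so sound seeds per fruit cannot
#' exceed 2.
#'
#' @param df data.frame with columns `individual_id`, `subpopulation`,
#'   `year`, `n_stems`, `n_flowering_stems`, `flowers_per_stem`,
#'   `fruits_per_flower`, `sound_seeds_per_fruit`, `seeds_per_stem`, and
#'   optionally `alive_next_season`
#' @return the validated data.frame
#' @export
validate_reproduction <- function(df) {
  required <- c("individual_id", "subpopulation", "year", "n_stems",
                "n_flowering_stems", "flowers_per_stem", "fruits_per_flower",
                "sound_seeds_per_fruit", "seeds_per_stem")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_endemica(sprintf("reproduction table is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "endemica_schema_error")
  }
  if (any(df$n_flowering_stems > df$n_stems)) {
    stop_endemica("n_flowering_stems exceeds n_stems",
                  "endemica_validation_error")
  }
  if (any(df$fruits_per_flower < 0 | df$fruits_per_flower > 1, na.rm = TRUE)) {
    stop_endemica("fruits_per_flower must lie in [0, 1]",
                  "endemica_validation_error")
  }
  if (any(df$sound_seeds_per_fruit > 2, na.rm = TRUE)) {
    stop_endemica("sound_seeds_per_fruit cannot exceed 2 (two mericarps)",
                  "endemica_validation_error")
  }
  neg <- c("n_stems", "n_flowering_stems", "flowers_per_stem",
           "sound_seeds_per_fruit", "seeds_per_stem")
  for (col in neg) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop_endemica(sprintf("%s must be non-negative", col),
                    "endemica_validation_error")
    }
  }
  class(df) <- unique(c("reproduction_table", class(df)))
  df
}

#' Validate occurrence coordinates
#'
#' @param df data.frame with columns `subpopulation`, `lon`, `lat` (WGS84
#'   decimal degrees); extra columns are kept
#' @return the validated data.frame
#' @export
validate_coordinates <- function(df) {
  required <- c("subpopulation", "lon", "lat")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_endemica(sprintf("coordinates table is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "endemica_schema_error")
  }
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)) {
    stop_endemica("coordinates outside WGS84 bounds",
                  "endemica_validation_error")
  }
  class(df) <- unique(c("occurrence_table", class(df)))
  df
}

#' Construct a diploid codominant genotype table
#'
#' Alleles are positive integers (fragment size in bp); a missing call is NA
#' in both allele slots. A call with only one missing allele is treated as
#' fully missing: heterozygosity cannot be scored on half a call.
#'
#' @param ids character vector of individual labels
#' @param pops character vector of subpopulation labels, one per individual
#' @param loci character vector of locus names
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes; 0 or
#'   NA marks a missing allele
#' @return an object of class `genotype_table`
#' @export
genotype_table <- function(ids, pops, loci, a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(ids)
  if (length(pops) != n || nrow(a1) != n || nrow(a2) != n ||
      ncol(a1) != length(loci) || ncol(a2) != length(loci)) {
    stop_endemica("genotype table dimensions disagree",
                  "endemica_validation_error")
  }
  a1[!is.na(a1) & a1 == 0L] <- NA_integer_
  a2[!is.na(a2) & a2 == 0L] <- NA_integer_
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_
  a2[half] <- NA_integer_
  if (any(a1 < 0L, na.rm = TRUE) || any(a2 < 0L, na.rm = TRUE)) {
    stop_endemica("allele codes must be positive integers",
                  "endemica_validation_error")
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = as.character(ids), pops = as.character(pops),
                 loci = as.character(loci), a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d subpopulations, %d loci\n",
              length(x$ids), length(unique(x$pops)), length(x$loci)))
  cat(sprintf("missing calls: %d / %d\n",
              sum(is.na(x$a1)), length(x$a1)))
  invisible(x)
}

# number of individuals with a non-missing call, per pop x locus
typed_counts <- function(g) {
  pops <- sort(unique(g$pops))
  out <- matrix(0L, length(pops), length(g$loci),
                dimnames = list(pops, g$loci))
  for (p in pops) {
    sel <- g$pops == p
    out[p, ] <- colSums(!is.na(g$a1[sel, , drop = FALSE]))
  }
  out
}

# subset a genotype table by individual index
subset_genotypes <- function(g, idx) {
  genotype_table(g$ids[idx], g$pops[idx], g$loci,
                 g$a1[idx, , drop = FALSE], g$a2[idx, , drop = FALSE])
}
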