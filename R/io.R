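#' Read a monitoring CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `subpopulation,year,n_mature,n_seedlings,n_nonreproductive,n_dead,local_eoo_m2`.
#' Row order is preserved.
#'
#' @param path file path
#' @return a validated `monitoring_table` data.frame
#' @export
read_monitoring <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_monitoring(df)
}

#' Read a reproductive-sample CSV
#'
#' @param path file path
#' @return a validated `reproduction_table` data.frame
#' @export
read_reproduction <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_reproduction(df)
}

#' Read an occurrence-coordinates CSV
#'
#' @param path file path (columns `subpopulation,lon,lat`, extras kept)
#' @return a validated `occurrence_table` data.frame
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_coordinates(df)
}

#' Read a codominant genotype file
#'
#' Two dialects are supported. `"genalex"` is the GenAlEx codominant layout:
#' row 1 holds `n_loci, n_samples, n_pops, size_1, ..., size_k`; row 2 a
#' title followed by population names; row 3 the header (`sample, pop`, then
#' two columns per locus, the locus name over the first); data rows follow
#' with one allele per column and missing coded 0. `"long"` is one row per
#' (individual, locus): `individual_id,subpopulation,locus,allele1,allele2`,
#' missing coded 0.
#'
#' @param path file path
#' @param dialect `"genalex"` or `"long"`
#' @return a `genotype_table`
#' @export
read_genotypes <- function(path, dialect = c("genalex", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("individual_id", "subpopulation", "locus",
                  "allele1", "allele2")
    if (length(setdiff(required, names(df))) > 0) {
      stop_endemica("long genotype file missing required columns",
                    "endemica_format_error")
    }
    loci <- unique(df$locus)
    ind <- unique(df[, c("individual_id", "subpopulation")])
    n <- nrow(ind)
    a1 <- matrix(NA_integer_, n, length(loci),
                 dimnames = list(ind$individual_id, loci))
    a2 <- a1
    ii <- match(df$individual_id, ind$individual_id)
    jj <- match(df$locus, loci)
    a1[cbind(ii, jj)] <- as.integer(df$allele1)
    a2[cbind(ii, jj)] <- as.integer(df$allele2)
    return(genotype_table(ind$individual_id, ind$subpopulation, loci, a1, a2))
  }
  lines <- readLines(path, warn = FALSE)
  split_row <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  r1 <- split_row(lines[1])
  n_loci <- as.integer(r1[1]); n_samples <- as.integer(r1[2])
  n_pops <- as.integer(r1[3])
  pop_sizes <- as.integer(r1[4:(3 + n_pops)])
  if (sum(pop_sizes) != n_samples) {
    stop_endemica(sprintf(
      "genalex header checksum: pop sizes sum to %d but n_samples is %d",
      sum(pop_sizes), n_samples), "endemica_format_error")
  }
  header <- split_row(lines[3])
  # trailing blank header fields may be dropped by the CSV writer
  allele_cols <- length(header) - 2L
  if (allele_cols < 2L * n_loci - 1L) {
    stop_endemica("genalex header has fewer allele columns than 2 x n_loci",
                  "endemica_format_error")
  }
  loci <- header[seq(3, 1 + 2 * n_loci, by = 2)]
  data_rows <- lines[4:(3 + n_samples)]
  first_fields <- length(split_row(data_rows[1]))
  if ((first_fields - 2L) %% 2L != 0L) {
    stop_endemica("genalex file has an odd number of allele columns",
                  "endemica_format_error")
  }
  ids <- character(n_samples); pops <- character(n_samples)
  a1 <- matrix(NA_integer_, n_samples, n_loci)
  a2 <- matrix(NA_integer_, n_samples, n_loci)
  for (i in seq_len(n_samples)) {
    f <- split_row(data_rows[i])
    ids[i] <- f[1]; pops[i] <- f[2]
    al <- suppressWarnings(as.integer(f[3:(2 + 2 * n_loci)]))
    a1[i, ] <- al[seq(1, 2 * n_loci, by = 2)]
    a2[i, ] <- al[seq(2, 2 * n_loci, by = 2)]
  }
  genotype_table(ids, pops, loci, a1, a2)
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]; missing alleles are written as 0 in both
#' dialects.
#'
#' @param g a `genotype_table`
#' @param path output file path
#' @param dialect `"genalex"` or `"long"`
#' @param title dataset title written into the genalex second row
#' @return `path`, invisibly
#' @export
write_genotypes <- function(g, path, dialect = c("genalex", "long"),
                            title = "endemica export") {
  dialect <- match.arg(dialect)
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  if (dialect == "long") {
    df <- data.frame(
      individual_id = rep(g$ids, times = length(g$loci)),
      subpopulation = rep(g$pops, times = length(g$loci)),
      locus = rep(g$loci, each = length(g$ids)),
      allele1 = as.vector(a1), allele2 = as.vector(a2),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  pops <- unique(g$pops)
  sizes <- as.integer(table(factor(g$pops, levels = pops)))
  r1 <- c(length(g$loci), length(g$ids), length(pops), sizes)
  r2 <- c(title, "", "", pops)
  hdr <- c("sample", "pop", as.vector(rbind(g$loci, "")))
  body <- vapply(seq_along(g$ids), function(i) {
    paste(c(g$ids[i], g$pops[i],
            as.vector(rbind(a1[i, ], a2[i, ]))), collapse = ",")
  }, character(1))
  # order rows so individuals of one population are contiguous (GenAlEx
  # expects blocks matching the size header)
  body <- body[order(match(g$pops, pops))]
  writeLines(c(paste(r1, collapse = ","), paste(r2, collapse = ","),
               paste(hdr, collapse = ","), body), path)
  invisible(path)
}

#' Export genotypes in STRUCTURE's two-row-per-individual format
#'
#' One text row per allele copy: individual label, an integer population
#' index, then one allele per locus; missing coded -9.
#'
#' @param g a `genotype_table`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(g, path) {
  pops <- unique(g$pops)
  pop_idx <- match(g$pops, pops)
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  rows <- character(2L * length(g$ids))
  for (i in seq_along(g$ids)) {
    rows[2 * i - 1] <- paste(c(g$ids[i], pop_idx[i], a1[i, ]), collapse = " ")
    rows[2 * i] <- paste(c(g$ids[i], pop_idx[i], a2[i, ]), collapse = " ")
  }
  writeLines(rows, path)
  invisible(path)
}
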