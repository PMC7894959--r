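#' @keywords internal
"_PACKAGE"

# Simple INFO-level logger used by every pipeline stage. Writes to stderr via
# message() so machine-readable stdout/output files stay clean.
log_info <- function(fmt, ...) {
  message(sprintf(paste0("INFO [endemica] ", fmt), ...))
}

# Stop with a classed condition so callers/tests can distinguish schema,
# validation and format failures.
stop_endemica <- function(msg, class) {
  stop(structure(
    class = c(class, "endemica_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# standard error of the mean; NA for n < 2
se_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Derive a sub-seed from a master seed
#'
#' Stochastic stages each draw from their own stream so that adding or
#' removing one stage does not perturb the others. Sub-seeds are kept below
#' 2^31 - 1.
#'
#' @param seed master integer seed
#' @param offset small integer stage offset
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}
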