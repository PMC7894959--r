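#!/usr/bin/env Rscript
# Red List classification from the assembled facts: published range
# metrics, the census series, and the PVA risk.

library(endemica)
dir.create("results", showWarnings = FALSE)

mon <- read_monitoring(system.file("extdata", "asperula_monitoring.csv",
                                   package = "endemica"))
tot <- census_totals(mon)

fl <- flag_extreme_fluctuation(tot$n_mature)
cat(sprintf("Census max/min ratio %.2f -> order-of-magnitude rule %s\n",
            fl$ratio, if (fl$extreme) "flags extreme fluctuations"
            else "does NOT flag extreme fluctuations"))
cat("The assessment nevertheless carries the fluctuation flags as\n",
    "caller-supplied facts, as in the original evaluation.\n")

input <- assessment_input(
  eoo_km2 = 28.7, aoo_km2 = 8, n_locations = 5,
  severely_fragmented = TRUE,
  continuing_decline = c("i", "ii", "iii", "v"),
  extreme_fluctuations = c("i", "ii", "iv"),
  n_mature = tot$n_mature[1],
  extinction_probability = list(p = 0.478, years = 50))

res <- assess(input)
cat("Overall category:", res$category, "\n")
cat("Triggering codes:", paste(res$codes, collapse = "; "), "\n")
cat("Criterion D alone:", assess_criterion_d(tot$n_mature[1]), "\n")
cat("Criterion E alone:",
    assess_criterion_e(0.478, 50), "\n")

jsonlite::write_json(list(category = res$category, codes = res$codes),
                     "results/assessment.json", auto_unbox = TRUE)
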