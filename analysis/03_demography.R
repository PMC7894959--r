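#!/usr/bin/env Rscript
# Demography of the monitored population: yearly censuses, stage
# structure, growth multipliers, reproductive output and effective-size
# heuristics.

library(endemica)
dir.create("results", showWarnings = FALSE)

mon <- read_monitoring(system.file("extdata", "asperula_monitoring.csv",
                                   package = "endemica"))
tot <- census_totals(mon)
ss <- stage_structure(mon, "TOTAL")
r <- growth_ratios(tot$n_mature)

cat("Mature individuals per year:",
    paste(tot$n_mature, collapse = ", "), "\n")
cat("Seedlings over all years:", sum(tot$n_seedlings),
    "; dead individuals:", sum(tot$n_dead), "\n")
cat(sprintf("Mature-stage share ranges %.1f-%.1f%%\n",
            100 * min(ss$p_mature), 100 * max(ss$p_mature)))
cat("Annual multipliers:", paste(round(r, 3), collapse = ", "), "\n")

rep_tab <- read.csv(system.file("extdata",
                                "asperula_reproduction_summary.csv",
                                package = "endemica"))
rep_tab$f <- flowers_per_individual(rep_tab$fl_flowers_per_stem,
                                    rep_tab$st_flowering_stems)
rep_tab$fruits <- fruits_per_individual(rep_tab$f, rep_tab$fruits_per_flower)
rep_tab$fecundity <- fecundity(rep_tab$s_seeds_per_stem,
                               rep_tab$st_flowering_stems)
cat("Fecundity by year:",
    paste(round(rep_tab$fecundity, 1), collapse = ", "), "\n")

sa_bar <- mean(rep_tab$sa_survival, na.rm = TRUE)
cat(sprintf("Mean adult survival %.3f -> generation length %.2f years\n",
            sa_bar, generation_length(3, sa_bar)))
cat(sprintf("(at Sa = 0.75 the generation length is %.0f years)\n",
            generation_length(3, 0.75)))

ne <- effective_size(tot$n_mature[1])
cat("Effective-size heuristics from the first census:",
    paste(sprintf("%.1fxNc -> %d", ne$ratio, ne$ne), collapse = "; "), "\n")

write.csv(rep_tab, "results/demography_reproduction.csv", row.names = FALSE)
jsonlite::write_json(
  list(totals = tot, stage_structure = ss, growth_ratios = r,
       ne = ne, generation_length = generation_length(3, sa_bar)),
  "results/demography.json", auto_unbox = TRUE, digits = 6, force = TRUE)
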