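#!/usr/bin/env Rscript
# Stage 1 -- simulate the synthetic screening study.
#
# Generates the default study: 50 ground-truth Lemnaceae compounds plus 100
# family decoys in the screening database, three extraction solvents, two
# instruments (TOF "A" without MS/MS, QTOF "B" with MS/MS), triplicate
# injections, blank contaminants and the spiked internal-standard mixture.
# Everything is written as plain text under results/study/.

suppressPackageStartupMessages(library(polarscreen))

cfg <- study_config(seed = 1)
study <- simulate_study(cfg)
dir <- "results/study"
write_study(study, dir)

cat(sprintf("simulated %d truth compounds (+%d decoys), %d sample tables, %d blanks\n",
            nrow(study$db_truth), nrow(study$decoys),
            length(study$tables$samples), length(study$tables$blanks)))
cat(sprintf("feature counts per injection: %s\n",
            paste(range(vapply(study$tables$samples, nrow, 1L)),
                  collapse = "-")))
cat(sprintf("study written to %s\n", dir))
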