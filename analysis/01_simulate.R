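#!/usr/bin/env Rscript
# Generate the synthetic cohort: subject table with MEQ chronotype, the
# ground-truth manifest, and one example session exported to EDF with its
# sidecar annotations (to demonstrate the I/O contract).

source(file.path("analysis", "00_config.R"))

plan <- cohort()

write.csv(plan$subjects, file.path(RESULTS_DIR, "subjects.csv"),
          row.names = FALSE)
jsonlite::write_json(plan$manifest,
                     file.path(RESULTS_DIR, "cohort_manifest.json"),
                     auto_unbox = TRUE, digits = NA)

cell <- realize_cohort_cell(plan, "s01", "sham")
edf <- file.path(RESULTS_DIR, "example_s01_sham.edf")
write_recording(cell$recording, edf)
back <- read_recording(edf)

cat(sprintf("cohort: %d subjects x %d conditions (master seed %d)\n",
            N_SUBJECTS, length(CONDITIONS), MASTER_SEED))
cat(sprintf("chronotype split: %s\n",
            paste(capture.output(print(table(plan$subjects$chronotype))),
                  collapse = " ")))
cat(sprintf("example session: %d planted SO events, %d coupled spindles\n",
            length(cell$truth$so_trough_times),
            length(cell$truth$spindle_phases)))
cat(sprintf("EDF round trip: max abs error %.3g uV over %d samples\n",
            max(abs(back$samples - cell$recording$samples)),
            length(back$samples)))
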