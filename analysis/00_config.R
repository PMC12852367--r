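# Shared settings for the analysis scripts. Source this first.
#
# The cohort mirrors the study design: three within-subject conditions
# (sham, anodal, cathodal so-tDCS) over a blocked nap protocol, with
# planted effects that mirror the qualitative result pattern: an anodal
# shift of the preferred coupling phase toward the SO up-state, an anodal
# spindle-amplitude gain that decreases with morningness (MEQ), and an
# anodal flattening of the aperiodic exponent (E/I shift toward
# excitation).

library(sleeposc)

RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

MASTER_SEED <- 20260925
N_SUBJECTS <- 12  # scaled-down cohort keeping all analyses exercised

COHORT_EFFECTS <- list(
  phase_shift = c(anodal = 15),
  spindle_amp_shift = c(anodal = 3),
  meq_spindle_slope = c(anodal = -0.3),
  exponent_shift = c(anodal = -0.2)
)

BASE_CONFIG <- synth_config(duration = 1100)
PROTOCOL <- stim_protocol(n_blocks = 7)
CONDITIONS <- c("sham", "anodal", "cathodal")

cohort <- function() {
  cohort_plan(N_SUBJECTS, COHORT_EFFECTS, MASTER_SEED, BASE_CONFIG,
              PROTOCOL, CONDITIONS)
}

PIPE_CONFIG <- pipeline_config(
  n_subjects = N_SUBJECTS, effects = COHORT_EFFECTS, seed = MASTER_SEED,
  synth = BASE_CONFIG, protocol = PROTOCOL,
  tfce = tfce_params(n_perm = 1024), conditions = CONDITIONS)
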