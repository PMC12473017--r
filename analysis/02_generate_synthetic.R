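#!/usr/bin/env Rscript
# Step 2: generate the synthetic shake-flask datasets that stand in for the
# measured time courses: triplicate observations at days 0-5 with 5 % CV
# measurement noise per variable, one dataset per strain, fixed root seed.

suppressPackageStartupMessages(library(fermkin))
dir.create("results", showWarnings = FALSE)

seed <- 1L
for (nm in c("native", "BBF001", "BBF002")) {
  cfg <- run_config(scenario = nm, noise = noise_spec(),
                    out_dir = "results", seed = seed)
  f <- run_simulate(cfg)
  obs <- read_time_course(f)
  cat(sprintf("%-7s %d observations (%d times x %d replicates), seed %d\n",
              nm, nrow(obs), length(unique(obs$time_d)),
              length(unique(obs$replicate)), seed))
}
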