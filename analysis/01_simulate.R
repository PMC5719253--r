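#!/usr/bin/env Rscript
# Generate the synthetic study inputs for the downstream analyses:
# two-channel SHG stacks over a maturity gradient, DAB-stained brightfield
# tiles, AFM force curves for a control vs TGF-beta stiffness contrast, and
# a two-factor cohort table. Everything is seeded and written under
# results/sim/.

suppressPackageStartupMessages(library(fibroquant))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results/sim"
dir.create(file.path(out, "shg"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "ihc"), recursive = TRUE, showWarnings = FALSE)

message("SHG stacks: maturities 0.2 / 0.5 / 0.8, 10 fibrils each")
for (m in c(0.2, 0.5, 0.8)) {
  tr <- shg_truth(random_fibril_field(10, c(64, 64, 6), maturity = m,
                                      seed = seed),
                  forward_gain = 20000, backward_gain = 20000,
                  background_level = 800, noise_sd = 300, seed = seed)
  st <- gen_shg_stack(tr, c(64, 64, 6))
  write_shg_tiff(st, file.path(out, "shg", sprintf("stack_m%02.0f.tif", 100 * m)))
}

message("IHC tiles: 3 subjects x LOX/LOXL1/LOXL2")
targets <- c("LOX", "LOXL1", "LOXL2")
for (subj in 1:3) for (target in targets) {
  tr <- random_ihc_truth(c(64, 64), n_blobs = 5,
                         seed = seed * 1000 + subj * 10 + match(target, targets))
  write_ihc_png(gen_ihc_image(tr),
                file.path(out, "ihc", sprintf("s%d_%s.png", subj, target)))
}

message("AFM curves: 35 per area x 3 areas, control (2 kPa) vs TGF-beta (16 kPa)")
curves <- list()
design <- expand.grid(area = 1:3, i = 1:35,
                      treatment = c("control", "TGFb"),
                      stringsAsFactors = FALSE)
design$E <- ifelse(design$treatment == "control", 2, 16)
for (r in seq_len(nrow(design))) {
  id <- sprintf("%s_a%d_c%02d", design$treatment[r], design$area[r], design$i[r])
  curves[[id]] <- gen_force_curve(curve_truth(
    E_true = design$E[r], contact_point = 2, baseline_slope = 0.05,
    noise_rel = 0.05, seed = seed * 10000 + r))
}
write_force_curves(curves, file.path(out, "afm_curves.csv"))
write.csv(design, file.path(out, "afm_design.csv"), row.names = FALSE)

message("Cohort table: default two-factor structure, n = 200")
write.csv(gen_cohort(default_cohort_truth(seed = seed)),
          file.path(out, "cohort.csv"), row.names = FALSE)

yaml::write_yaml(list(seed = seed, generated = as.character(Sys.Date())),
                 file.path(out, "provenance.yaml"))
message("done: ", out)
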