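#!/usr/bin/env Rscript
# Generate the synthetic study cohort: one healthy-volunteer and one
# dilated-cardiomyopathy (DCM) subject with known ground-truth stiffness,
# written under results/subjects/. The volunteer subject is also produced in
# a noisy variant (0.5 mm Gaussian tracking noise) used by the recovery
# study. Meshes are kept at desk scale (a few hundred elements) so the whole
# analysis reruns in minutes.

library(lvstiff)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/subjects"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (grp in c("volunteer", "dcm")) {
  subj <- generate_subject(subject_preset(grp, n_frames = 6), seed = seed,
                           nc = 14, nl = 6, ns = 1)
  write_subject(subj, file.path(out, grp))
  ve <- volumes_and_ef(subj$motion$vol * 1e6)
  message(sprintf(
    "%s (seed %d): EDV %.1f ml, ESV %.1f ml, EF %.2f; gamma* = %.2f, a* = %.0f Pa, a_f* = %.0f Pa, EDP %.1f mmHg",
    grp, seed, ve$edv, ve$esv, ve$ef, subj$truth$gamma, subj$truth$a,
    subj$truth$a_f, subj$truth$edp_mmhg))
}

noisy <- add_displacement_noise(read_subject(file.path(out, "volunteer")),
                                sigma_mm = 0.5, seed = seed + 1000L)
write_subject(noisy, file.path(out, "volunteer_noisy"))
message("wrote noisy volunteer variant (sigma = 0.5 mm)")
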