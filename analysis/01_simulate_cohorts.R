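#!/usr/bin/env Rscript
# Simulate the two synthetic study cohorts and write them as NIfTI studies
# with manifests.
#
# The patient data behind the original analysis are not publicly available,
# so the workflow runs on synthetic three-phase CT cohorts whose lesions
# differ between groups in arterialization heterogeneity: responders carry
# more, finer-grained strongly-arterialized patches. Two labeling schemes
# mirror the clinical groupings: Improved (CR+PR, n=22) vs Un-improved
# (SD+PD, n=23), and Un-worsened (CR+PR+SD, n=31) vs Worsened (PD, n=14).

suppressPackageStartupMessages(library(aeftex))

seed <- 20260924L
out_root <- file.path("results", "cohorts")

for (scheme in c("improved", "unworsened")) {
  spec <- cohort_spec(seed = seed, label_scheme = scheme)
  cohort <- generate_cohort(spec)
  print(cohort)
  dir <- file.path(out_root, scheme)
  manifest <- write_cohort_nifti(cohort, dir)
  cat(sprintf("  wrote %d subjects under %s (manifest: %s)\n",
              length(cohort), dir, manifest))
}

cat("\nEach subject has unenhanced/arterial/portal phase volumes (64 x 64 x 16",
    "voxels at 0.8 x 0.8 x 3 mm) and a lesion mask; labels sit in the",
    "manifest CSVs.\n")
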