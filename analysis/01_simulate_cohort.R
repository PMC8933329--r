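#!/usr/bin/env Rscript
# Simulate the study cohort: a 90-region parcellation, an FA/direction
# phantom with 12 straight bundles, two groups of 30 subjects (no aphasia
# "NA" vs glioma-induced aphasia "GIA"; GIA keeps each left-hemisphere
# bundle with probability 0.6 and draws larger tumors), per-subject
# streamline sets, and stimulation-point tables.  Artifacts go to results/.

suppressPackageStartupMessages(library(vrconn))

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
cfg <- synthetic_config(seed = 1L)
co <- suppressWarnings(make_cohort(cfg))

message(sprintf("Simulated %d subjects over %d regions with %d bundles.",
                nrow(co$cohort), cfg$n_regions, length(co$phantom$bundles)))

write_cohort_csv(co$cohort, "results/cohort/cohort.csv")
pts <- make_stimulation_points(co$cohort, co$parcellation, seed = cfg$seed)
write_points_csv(pts, "results/cohort/stimulation_points.csv")
write_volume(co$phantom$fa, "results/cohort/fa.nii.gz")
write_volume(co$parcellation$volume, "results/cohort/labels.nii.gz")

# one subject's fibers on disk in both tractography formats, as an I/O
# demonstration; the pipeline itself keeps fibers in memory
s1 <- co$subjects[[1L]]
chains <- lapply(s1$fibers, function(f) f$points)
write_streamlines(chains, "results/cohort/S001.tck")
write_streamlines(chains, "results/cohort/S001.trk", reference = co$phantom$fa)
back <- read_streamlines("results/cohort/S001.tck")
stopifnot(length(back) == length(chains))

ch <- co$cohort
message(sprintf("Tumor size: NA %.1f +/- %.1f vs GIA %.1f +/- %.1f cm^3",
                mean(ch$tumor_size[ch$group == "NA"]),
                sd(ch$tumor_size[ch$group == "NA"]),
                mean(ch$tumor_size[ch$group == "GIA"]),
                sd(ch$tumor_size[ch$group == "GIA"])))
message(sprintf("Aphasia levels (GIA): %s",
                paste(sort(unique(ch$aphasia_level[ch$group == "GIA"])),
                      collapse = ", ")))
message("Wrote cohort table, stimulation points, volumes and fibers under results/cohort/")
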