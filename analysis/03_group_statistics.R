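#!/usr/bin/env Rscript
# Group statistics layer: ANCOVA with tumor-size covariate across matrix
# kinds x metrics x threshold blocks (FDR-corrected), pooled rank
# correlation with aphasia level, intragroup mapping proportions, and the
# demographic-style comparisons (t on tumor size, U on mapping counts,
# chi-square on a boosted region).

suppressPackageStartupMessages(library(vrconn))

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
cfg <- synthetic_config(seed = 1L)
res <- suppressWarnings(run_cohort(cfg, out_dir = "results/stats"))
ch <- res$cohort
g <- ch$group

sig <- res$comparison[which(res$comparison$significant), ]
message(sprintf("ANCOVA: %d of %d comparisons significant before FDR:",
                nrow(sig), nrow(res$comparison)))
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %-5s %-2s %-4s  t = %6.2f  p = %.4f  (NA %.3f vs GIA %.3f)",
                  sig$kind[i], sig$metric[i], sig$block[i],
                  abs(sig$statistic[i]), sig$p[i],
                  sig$mean_NA[i], sig$mean_GIA[i]))
}

sigc <- res$correlation[which(res$correlation$significant), ]
message(sprintf("Aphasia correlations: %d of %d significant; strongest:",
                nrow(sigc), nrow(res$correlation)))
top <- sigc[order(sigc$p)[seq_len(min(3, nrow(sigc)))], ]
for (i in seq_len(nrow(top))) {
  message(sprintf("  %-5s %-2s %-4s  R = %+.3f  p = %.2e",
                  top$kind[i], top$metric[i], top$block[i],
                  top$statistic[i], top$p[i]))
}

tt <- independent_t(ch$tumor_size[g == "NA"], ch$tumor_size[g == "GIA"])
message(sprintf("Tumor size t test: t = %.2f, p = %.4f", tt$statistic, tt$p))

npos <- vapply(ch$pos_regions, length, 0L)
nneg <- vapply(ch$neg_regions, length, 0L)
uu <- mann_whitney(npos[g == "NA"], npos[g == "GIA"])
message(sprintf("Positive mapping-region counts: NA %.2f vs GIA %.2f (U = %.0f, p = %.3f)",
                mean(npos[g == "NA"]), mean(npos[g == "GIA"]),
                uu$statistic, uu$p))
message(sprintf("Negative mapping-region counts: NA %.2f vs GIA %.2f",
                mean(nneg[g == "NA"]), mean(nneg[g == "GIA"])))

# chi-square on the region with the largest positive-mapping group contrast
pr <- res$mapping
pos <- pr[pr$polarity == "POS", ]
by_region <- split(pos, pos$region)
contrast <- vapply(by_region, function(d) abs(diff(d$count)), 0)
rid <- names(which.max(contrast))
d <- by_region[[rid]]
tab <- rbind(c(d$count[1L], d$n_group[1L] - d$count[1L]),
             c(d$count[2L], d$n_group[2L] - d$count[2L]))
kk <- chi_square(tab)
message(sprintf("Region %s positively mapped in %d (%s) vs %d (%s): K = %.2f, p = %.3f",
                rid, d$count[1L], d$group[1L], d$count[2L], d$group[2L],
                kk$statistic, kk$p))
message("Wrote group tables under results/stats/")
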