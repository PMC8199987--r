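#!/usr/bin/env Rscript
# Does the fraction of the head that the network actually segments matter for
# attackability? Contrast skull-stripped phantoms (brain fills the labelled
# field of view) against with-skull phantoms (bright shell, brain is a
# smaller proportion) over three seeds, one private/attacker fold each.

suppressPackageStartupMessages(library(segrecon))

out_csv <- "results/skull_condition.csv"
dir.create("results", showWarnings = FALSE)

rows <- list()
for (seed in c(11L, 12L, 13L)) {
  stripped <- single_fold_attack(phantom_params(with_skull = FALSE), seed = seed)
  skulled <- single_fold_attack(phantom_params(with_skull = TRUE), seed = seed)
  rows[[length(rows) + 1L]] <- data.frame(
    seed = seed,
    ssim_skull_stripped = stripped$mean_ssim,
    ssim_with_skull = skulled$mean_ssim)
  message(sprintf("seed %d: skull-stripped %.3f vs with-skull %.3f",
                  seed, stripped$mean_ssim, skulled$mean_ssim))
}
tab <- do.call(rbind, rows)
write.csv(tab, out_csv, row.names = FALSE)
message(sprintf("skull-stripped better in %d of %d seeds; wrote %s",
                sum(tab$ssim_skull_stripped >= tab$ssim_with_skull),
                nrow(tab), out_csv))
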