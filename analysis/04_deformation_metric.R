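#!/usr/bin/env Rscript
# The shape-based reconstruction metric: register each reconstruction to the
# candidate originals (affine + demons) and use the mean displacement norm of
# the non-linear field as a dissimilarity. Registration is costly, so this
# stage scores one fold's reconstructions (4) against all 16 originals using
# the report saved by 02_run_attack_study.R.

suppressPackageStartupMessages(library(segrecon))

report_path <- "results/attack/report.rds"
out_csv <- "results/deformation_ranks.csv"
if (!file.exists(report_path))
  stop("run analysis/02_run_attack_study.R first (missing ", report_path, ")")
report <- readRDS(report_path)

cohort <- read_cohort("results/cohort")
prep <- lapply(cohort$subjects, preprocess_subject, divisor = 4L)
names(prep) <- vapply(prep, `[[`, "", "subject_id")
originals <- lapply(prep, `[[`, "image")
masks <- lapply(prep, brain_mask)

fold <- report$folds[[1]]
rows <- list()
for (arch in names(report$arch)) {
  rec <- report$arch[[arch]]$reconstructions[fold$private_ids]
  m <- matrix(NA_real_, length(rec), length(originals),
              dimnames = list(names(rec), names(originals)))
  for (i in names(rec)) for (j in names(originals)) {
    m[i, j] <- deformation_score(rec[[i]], originals[[j]], mask = masks[[j]])
  }
  # rank within this fold's rows
  for (i in names(rec)) {
    r <- 1L + sum(m[i, setdiff(colnames(m), i)] < m[i, i]) +
      sum(m[i, setdiff(colnames(m), i)] == m[i, i])
    rows[[length(rows) + 1L]] <- data.frame(
      arch = arch, subject_id = i, true_norm_mm = m[i, i],
      best_other_norm_mm = min(m[i, setdiff(colnames(m), i)]), rank = r)
    message(sprintf("[%s] %s: true-pair norm %.2f mm, rank %d of %d",
                    arch, i, m[i, i], r, ncol(m)))
  }
}
write.csv(do.call(rbind, rows), out_csv, row.names = FALSE)
message("wrote ", out_csv)
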