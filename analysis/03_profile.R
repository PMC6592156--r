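#!/usr/bin/env Rscript
# Stage 3: perturbation profiling.
#
# From the corrected abundance matrices: presence calls (detected in >= 2
# of 3 replicates), shared-identity counts between conditions, the
# persistent (exchange-resistant) protein set, per-protein sigmoid fits of
# log10 abundance against condition, critical condition values, and
# response classes — Class I (no change), Class II (transition below
# 30 degrees C / pH 6.8) and Class III (above), each -up or -down.
# Fitted critical values are also compared with the planted ones and, as a
# negative control, correlated with a random per-protein annotation
# (emulating the absence of correlation with global melting points or
# isoelectric points).
#
# Outputs per axis: fits.tsv, shared_counts.tsv, persistent.txt,
# class_counts.tsv.

# run from the repository root: Rscript analysis/03_profile.R
source("analysis/00_config.R")

for (axis in c("temperature", "pH")) {
  out <- axis_dir(axis)
  corrected <- local({
    tab <- read_peptide_table(file.path(out, "peptides_np.tsv"))
    ctl <- read_peptide_table(file.path(out, "peptides_control.tsv"))
    subtract_control(top3(tab), top3(ctl))
  })
  truth <- data.table::fread(file.path(out, "truth.tsv"))

  pres <- presence_calls(corrected, min_replicates = 2)
  shared <- shared_counts(pres)
  pers <- persistent_set(pres)
  writeLines(pers, file.path(out, "persistent.txt"))
  data.table::fwrite(
    data.table::as.data.table(shared$pairwise, keep.rownames = "condition"),
    file.path(out, "shared_counts.tsv"), sep = "\t")

  fits <- fit_profiles(corrected, proteins = pers)
  fits$class_label <- classify(fits$verdict, fits$x_c, fits$direction,
                               class_boundary(axis))
  data.table::fwrite(fits, file.path(out, "fits.tsv"), sep = "\t")
  cc <- table(fits$class_label)
  data.table::fwrite(data.table::as.data.table(cc),
                     file.path(out, "class_counts.tsv"), sep = "\t")

  # planted-truth check and the no-correlation negative control
  m <- merge(as.data.frame(fits), as.data.frame(truth), by = "protein")
  resp <- m[m$responder & m$verdict == "sigmoid", ]
  crit <- setNames(resp$x_c.x, resp$protein)
  set.seed(STUDY_SEED)
  fake_annotation <- setNames(runif(length(crit), 3, 11), names(crit))
  ctrl <- critical_correlation(crit, fake_annotation)

  message(sprintf(
    "[%s] persistent %d (%.0f%% of union); classes: %s", axis,
    length(pers), shared$pct_all,
    paste(names(cc), as.integer(cc), sep = "=", collapse = ", ")))
  message(sprintf(
    "[%s] median |critical value error| = %.2f; r(critical, random annotation) = %.2f (p = %.2f)",
    axis, median(abs(resp$x_c.x - resp$x_c.y)), ctrl$r, ctrl$p))
}
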