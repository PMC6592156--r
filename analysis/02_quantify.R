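#!/usr/bin/env Rscript
# Stage 2: quantify the peptide tables.
#
# Reads the simulated nanoparticle-sample and particle-free-control peptide
# tables, collapses them to protein abundances with Top3 (median of the
# three most abundant peptides; proteins with fewer than 3 quantified
# peptides excluded), and corrects each sample cell by subtracting the
# matched control cell on the linear scale (clamped at zero; a zero is
# non-detection downstream).
#
# Outputs per axis: matrix.tsv (wide corrected abundances) and
# quant_summary.tsv.

# run from the repository root: Rscript analysis/02_quantify.R
source("analysis/00_config.R")

for (axis in c("temperature", "pH")) {
  out <- axis_dir(axis)
  sample_tab <- read_peptide_table(file.path(out, "peptides_np.tsv"))
  control_tab <- read_peptide_table(file.path(out, "peptides_control.tsv"))
  truth <- data.table::fread(file.path(out, "truth.tsv"))

  m_np <- top3(sample_tab, min_peptides = 3)
  m_ctl <- top3(control_tab, min_peptides = 3)
  corrected <- subtract_control(m_np, m_ctl)
  write_abundance_matrix(corrected, file.path(out, "matrix.tsv"))

  summ <- quant_summary(
    identified = list(peptides = length(unique(sample_tab$peptide)),
                      proteins = nrow(truth)),
    table = sample_tab, matrix = m_np)
  data.table::fwrite(data.table::as.data.table(summ),
                     file.path(out, "quant_summary.tsv"), sep = "\t")

  message(sprintf(
    "[%s] quantified %d/%d proteins (%.0f%%); %.0f%% of peptides; median %g peptides/protein",
    axis, summ$n_proteins_quantified, nrow(truth),
    100 * summ$frac_proteins_quantified,
    100 * summ$frac_peptides_quantified, summ$median_peptides_per_protein))
}
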