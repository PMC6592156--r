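#!/usr/bin/env Rscript
# Stage 1: simulate the perturbation experiments.
#
# Generates, for each perturbation axis, a synthetic plasma proteome of 300
# proteins and the corresponding peptide-level LFQ tables: five conditions
# (4/17/30/41/47 degrees C, or pH 4.9/6.1/6.8/7.7/8.9) in triplicate plus
# particle-free controls with 5% carry-over. The persistent corona fraction
# (40% of proteins) is enriched for Kyte-Doolittle hydropathy (+0.5 index
# units), emulating the selective corona the downstream stages should
# detect; 40% of persistent proteins are sigmoid responders with planted
# critical values.
#
# Outputs under results/<axis>/: proteome.fasta, truth.tsv,
# peptides_np.tsv, peptides_control.tsv.

# run from the repository root: Rscript analysis/01_simulate.R
source("analysis/00_config.R")

for (axis in c("temperature", "pH")) {
  out <- axis_dir(axis)
  design <- study_design(axis)
  proteome <- generate_proteome(design)
  experiment <- generate_experiment(design, proteome$truth)

  write_proteome_fasta(proteome$sequences, file.path(out, "proteome.fasta"))
  data.table::fwrite(proteome$truth, file.path(out, "truth.tsv"), sep = "\t")
  write_peptide_table(experiment$sample, file.path(out, "peptides_np.tsv"))
  write_peptide_table(experiment$control,
                      file.path(out, "peptides_control.tsv"))

  tr <- proteome$truth
  message(sprintf(
    "[%s] %d proteins (%d persistent, %d responders, %d exchanged); %d sample peptide rows",
    axis, nrow(tr), sum(tr$persistent), sum(tr$responder),
    sum(!tr$persistent), nrow(experiment$sample)))
}
message("simulation written under results/{temperature,pH}/")
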