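# Shared configuration of the synthetic perturbation study, sourced by the
# numbered analysis stages. One master seed drives everything.

library(coronashift)

STUDY_SEED <- 20190318
N_PERM <- 2999        # lessening-test permutations
Q_THRESHOLD <- 0.005  # enrichment FDR threshold

study_indices <- function() aaindex_properties()

study_design <- function(axis, indices = study_indices()) {
  kd <- indices[["KYTJ820101"]]
  synthetic_design(
    axis = axis, seed = STUDY_SEED + (axis == "pH"),
    enrichment_spec = list(accession = kd$accession, shift = 0.5,
                           values = kd$values))
}

axis_dir <- function(axis) {
  d <- file.path("results", axis)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
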