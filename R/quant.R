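#' Validate a peptide-level abundance table
#'
#' A peptide table is a long table with one row per quantified
#' (peptide, protein, condition, replicate) cell and a positive linear
#' abundance. Absence of a peptide is encoded by a missing row, never by a
#' zero: a zero abundance means "not detected" and is rejected.
#'
#' @param x A data.frame with columns `peptide`, `protein`, `condition`,
#'   `replicate`, `abundance`.
#' @return A validated `peptide_table` (a data.table).
#' @export
peptide_table <- function(x) {
  required <- c("peptide", "protein", "condition", "replicate", "abundance")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("peptide table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dt <- as.data.table(x)[, required, with = FALSE]
  dt[, `:=`(peptide = as.character(peptide), protein = as.character(protein),
            condition = as.numeric(condition),
            replicate = as.integer(replicate),
            abundance = as.numeric(abundance))]
  bad <- which(!is.finite(dt$abundance) | dt$abundance <= 0)
  if (length(bad))
    stop("non-positive abundance at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": absent peptides must be encoded as missing rows, not zeros")
  if (anyNA(dt$replicate) || any(dt$replicate < 1L))
    stop("replicate must be an integer >= 1")
  dup <- duplicated(dt, by = c("peptide", "protein", "condition", "replicate"))
  if (any(dup)) {
    d <- dt[which(dup)[1]]
    stop(sprintf("duplicated key (peptide=%s, protein=%s, condition=%s, replicate=%d)",
                 d$peptide, d$protein, format(d$condition), d$replicate))
  }
  setattr(dt, "class", c("peptide_table", class(dt)))
  dt[]
}

#' Read a peptide table from TSV
#'
#' Expects a UTF-8 TSV with header columns `peptide`, `protein`,
#' `condition`, `replicate`, `abundance`.
#'
#' @param path TSV file path.
#' @return A validated `peptide_table`.
#' @export
read_peptide_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, encoding = "UTF-8",
              colClasses = list(character = c("peptide", "protein")))
  required <- c("peptide", "protein", "condition", "replicate", "abundance")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("peptide table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("condition", "abundance")) {
    v <- dt[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num))
        stop("unparsable numeric in column '", col, "' at row ",
             which(is.na(num))[1])
      dt[[col]] <- num
    }
  }
  peptide_table(dt)
}

#' Top3 protein quantification
#'
#' Collapses a peptide table to protein abundances per
#' (protein, condition, replicate): the protein abundance is the median of
#' its three most abundant peptides (the middle value of the top three).
#' Proteins with fewer than `min_peptides` quantified peptides in a cell
#' are excluded (missing cell).
#'
#' @param table A `peptide_table`.
#' @param min_peptides Minimum quantified peptides required per cell
#'   (default 3).
#' @return An `abundance_matrix`: a long data.table with columns `protein`,
#'   `condition`, `replicate`, `abundance` (linear), `n_peptides`.
#' @export
top3 <- function(table, min_peptides = 3L) {
  if (min_peptides < 1L) stop("min_peptides must be >= 1")
  dt <- as.data.table(table)
  out <- dt[, .(abundance = {
    top <- sort(abundance, decreasing = TRUE)
    top <- top[seq_len(min(3L, length(top)))]
    median(top)
  }, n_peptides = .N), by = .(protein, condition, replicate)]
  out <- out[n_peptides >= min_peptides]
  setorder(out, protein, condition, replicate)
  abundance_matrix(out)
}

abundance_matrix <- function(dt) {
  setattr(dt, "class", unique(c("abundance_matrix", class(dt))))
  dt[]
}

#' Subtract particle-free control abundances
#'
#' Corrects nanoparticle-sample protein abundances for non-specific
#' carry-over by subtracting, on the linear scale, the abundance of the
#' same protein in the matched particle-free control cell; negative
#' results are clamped to 0. A protein (or whole condition) missing from
#' the control is treated as control abundance 0 (corrected equals
#' sample); a cell missing from the sample stays missing; a condition
#' present only in the control indicates mismatched experiments and is an
#' error. Corrected values of 0 are retained in the
#' matrix but count as non-detection downstream (no log10 value, no
#' presence).
#'
#' @param sample,control `abundance_matrix` objects on the same condition
#'   axis, replicates matched by index.
#' @param per_replicate If `TRUE` (default) subtract the matched replicate
#'   cell; if `FALSE` subtract the control's per-condition mean.
#' @return Corrected `abundance_matrix`.
#' @export
subtract_control <- function(sample, control, per_replicate = TRUE) {
  s <- as.data.table(sample)
  c_ <- as.data.table(control)
  if (nrow(c_)) {
    only_c <- setdiff(unique(c_$condition), unique(s$condition))
    if (length(only_c))
      stop("condition sets differ between sample and control; ",
           "control-only condition(s): {", paste(only_c, collapse = ", "),
           "}")
  }
  if (!per_replicate && nrow(c_))
    c_ <- c_[, .(abundance = mean(abundance)),
             by = .(protein, condition)][, replicate := NA_integer_]
  keys <- if (per_replicate) c("protein", "condition", "replicate")
          else c("protein", "condition")
  m <- merge(s, c_[, c(keys, "abundance"), with = FALSE],
             by = keys, all.x = TRUE, suffixes = c("_sample", "_control"))
  m[is.na(abundance_control), abundance_control := 0]
  m[, abundance := pmax(abundance_sample - abundance_control, 0)]
  out <- m[, .(protein, condition, replicate, abundance, n_peptides)]
  setorder(out, protein, condition, replicate)
  abundance_matrix(out)
}

#' Log10 view of an abundance matrix
#'
#' @param matrix An `abundance_matrix`.
#' @return The same table with a `log10_abundance` column, `NA` where the
#'   linear abundance is not strictly positive (non-detection).
#' @export
log10_view <- function(matrix) {
  dt <- copy(as.data.table(matrix))
  dt[, log10_abundance := ifelse(abundance > 0, log10(abundance), NA_real_)]
  abundance_matrix(dt)
}

#' Per-(protein, condition) presence calls
#'
#' A protein is called present at a condition iff it is quantified with a
#' positive corrected abundance in at least `min_replicates` replicates of
#' that condition.
#'
#' @param matrix Corrected `abundance_matrix`.
#' @param min_replicates Minimum detected replicates (default 2).
#' @return data.table with columns `protein`, `condition`, `n_detected`,
#'   `present`.
#' @export
presence_calls <- function(matrix, min_replicates = 2L) {
  dt <- as.data.table(matrix)
  n_rep <- length(unique(dt$replicate))
  if (min_replicates > n_rep)
    stop("min_replicates (", min_replicates, ") exceeds replicate count (",
         n_rep, ")")
  out <- dt[, .(n_detected = sum(abundance > 0)), by = .(protein, condition)]
  out[, present := n_detected >= min_replicates]
  setorder(out, protein, condition)
  out[]
}

#' Quantification summary
#'
#' Fractions of identified peptides and proteins that were quantified, and
#' the median number of quantified peptides per quantified protein.
#' Identified counts come from upstream identification (or from the
#' synthetic ground truth).
#'
#' @param identified `list(peptides =, proteins =)` identified counts.
#' @param table The `peptide_table` that entered quantification.
#' @param matrix The `abundance_matrix` produced by [top3()].
#' @return list with `frac_peptides_quantified`,
#'   `frac_proteins_quantified`, `median_peptides_per_protein`,
#'   `n_proteins_quantified`.
#' @export
quant_summary <- function(identified, table, matrix) {
  if (is.null(identified$peptides) || is.null(identified$proteins) ||
      identified$peptides <= 0 || identified$proteins <= 0)
    stop("identified peptide and protein counts must be positive")
  tab <- as.data.table(table)
  mat <- as.data.table(matrix)
  quant_proteins <- unique(mat$protein)
  pep_per_prot <- tab[protein %in% quant_proteins,
                      .(n = uniqueN(peptide)), by = protein]
  list(
    frac_peptides_quantified =
      uniqueN(tab[, .(peptide, protein)]) / identified$peptides,
    frac_proteins_quantified = length(quant_proteins) / identified$proteins,
    median_peptides_per_protein =
      if (nrow(pep_per_prot)) median(pep_per_prot$n) else NA_real_,
    n_proteins_quantified = length(quant_proteins))
}

#' Write an abundance matrix as wide TSV
#'
#' Protein rows, `condition_replicate` columns; empty cell = missing.
#'
#' @param matrix An `abundance_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(matrix, path) {
  dt <- as.data.table(matrix)
  wide <- dcast(dt, protein ~ condition + replicate, value.var = "abundance",
                sep = "_")
  fwrite(wide, path, sep = "\t")
  invisible(path)
}
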