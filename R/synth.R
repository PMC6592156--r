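#' Design of a synthetic corona perturbation experiment
#'
#' Bundles and validates every knob of the synthetic-data generator: the
#' perturbation axis and its condition series, the size and composition of
#' the simulated plasma proteome, replicate structure, noise, and an
#' optional amino-acid-index enrichment planted into the persistent
#' (exchange-resistant) corona fraction.
#'
#' Default fractions mirror the study conditions the generator emulates:
#' five conditions in triplicate, a few hundred corona proteins of which
#' roughly 40% are persistent, and roughly 40% of those persistent proteins
#' responding to the perturbation with a sigmoid abundance transition.
#'
#' @param axis Perturbation axis, `"temperature"` or `"pH"`.
#' @param condition_values Strictly increasing numeric vector of at least 4
#'   condition values; defaults to [default_conditions()] for the axis.
#' @param n_replicates Number of replicates per condition (default 3).
#' @param n_proteins Number of simulated plasma/corona proteins.
#' @param frac_persistent Fraction of proteins present at every condition.
#' @param frac_responders Fraction *of the persistent set* showing a sigmoid
#'   abundance transition (the rest are Class I, flat).
#' @param noise_sd_log10 Replicate noise standard deviation, log10 units.
#' @param peptides_per_protein Length-3 numeric `(min, mode, max)` of the
#'   triangular distribution of quantified peptides per protein.
#' @param control_carryover Fraction of each sample abundance leaking into
#'   the particle-free control.
#' @param enrichment_spec Optional `list(accession =, shift =, values =)`:
#'   persistent proteins are sampled with residue weights tilted so their
#'   expected per-residue value of the named amino-acid index is shifted by
#'   `shift` index units relative to the background composition. `values`
#'   (named numeric over the 20 residues) may be omitted if the index is
#'   passed to [generate_proteome()] via `indices`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   design.
#' @return A `synthetic_design` object (a validated list).
#' @seealso [generate_proteome()], [generate_experiment()]
#' @export
synthetic_design <- function(axis = c("temperature", "pH"),
                             condition_values = NULL,
                             n_replicates = 3L,
                             n_proteins = 300L,
                             frac_persistent = 0.4,
                             frac_responders = 0.4,
                             noise_sd_log10 = 0.2,
                             peptides_per_protein = c(min = 1, mode = 5, max = 12),
                             control_carryover = 0.05,
                             enrichment_spec = NULL,
                             seed = 1L) {
  axis <- match.arg(axis)
  if (is.null(condition_values)) condition_values <- default_conditions(axis)
  stopifnot(is.numeric(condition_values))
  if (length(condition_values) < 4L || any(diff(condition_values) <= 0))
    stop("condition_values must be strictly increasing with length >= 4")
  if (n_replicates < 1L || n_proteins < 0L)
    stop("n_replicates must be >= 1 and n_proteins >= 0")
  for (f in c(frac_persistent, frac_responders, control_carryover))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (noise_sd_log10 < 0) stop("noise_sd_log10 must be non-negative")
  ppp <- as.numeric(peptides_per_protein)
  if (length(ppp) != 3L || ppp[1] < 1 || ppp[1] > ppp[2] || ppp[2] > ppp[3])
    stop("peptides_per_protein must be (min, mode, max) with 1 <= min <= mode <= max")
  if (!is.null(enrichment_spec)) {
    if (!is.list(enrichment_spec) || is.null(enrichment_spec$accession) ||
        is.null(enrichment_spec$shift))
      stop("enrichment_spec must be a list with elements 'accession' and 'shift'")
  }
  structure(list(
    axis = axis,
    condition_values = as.numeric(condition_values),
    n_replicates = as.integer(n_replicates),
    n_proteins = as.integer(n_proteins),
    frac_persistent = frac_persistent,
    frac_responders = frac_responders,
    noise_sd_log10 = noise_sd_log10,
    peptides_per_protein = setNames(ppp, c("min", "mode", "max")),
    control_carryover = control_carryover,
    enrichment_spec = enrichment_spec,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

# Discrete triangular sampler on min..max with peak at mode.
sample_triangular_int <- function(n, min, mode, max) {
  if (min == max) return(rep(as.integer(min), n))
  k <- seq(min, max)
  w <- ifelse(k <= mode,
              (k - min + 1) / (mode - min + 1),
              (max - k + 1) / (max - mode + 1))
  sample(k, n, replace = TRUE, prob = w)
}

# Exponentially tilt residue frequencies f0 so the expected index value
# shifts by `shift`: w(lambda) ~ f0 * exp(lambda * v). Solves for lambda.
tilt_frequencies <- function(f0, v, shift) {
  if (anyNA(v)) stop("enrichment index must have values for all 20 residues")
  mu0 <- sum(f0 * v)
  target <- mu0 + shift
  if (target >= max(v) || target <= min(v))
    stop("requested enrichment shift is outside the achievable range of the index")
  if (shift == 0) return(f0)
  g <- function(lambda) {
    w <- f0 * exp(lambda * (v - mean(v)))
    w <- w / sum(w)
    sum(w * v) - target
  }
  lo <- -1; hi <- 1
  while (g(lo) > 0) lo <- lo * 2
  while (g(hi) < 0) hi <- hi * 2
  lambda <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  w <- f0 * exp(lambda * (v - mean(v)))
  w / sum(w)
}

#' Generate a synthetic plasma proteome with planted ground truth
#'
#' Simulates `n_proteins` protein sequences over the 20 standard amino
#' acids (lengths uniform on 100--600 residues) and assigns each protein a
#' perturbation-response class: persistent proteins are either flat
#' (Class I) or sigmoid responders with a planted critical condition value,
#' amplitude and direction; the remaining proteins are "exchanged" and will
#' be absent from a random subset of conditions. If the design carries an
#' `enrichment_spec`, the persistent proteins are sampled with tilted
#' residue weights so their mean value of the named amino-acid index is
#' shifted by the requested amount relative to the background composition.
#'
#' @param design A [synthetic_design()].
#' @param indices Optional list of [property_index()] objects used to
#'   resolve `design$enrichment_spec$accession` when the enrichment
#'   specification does not embed the index values itself.
#' @return `list(sequences = <named character>, truth = <data.table>)`.
#'   The truth table has one row per protein: `protein`, `class` (one of
#'   `I`, `II-up`, `II-down`, `III-up`, `III-down`, `exchanged`), `x_c`,
#'   `amplitude`, `slope`, `direction`, `persistent`, `responder`,
#'   `enriched`, `absent_conditions` (comma-joined, empty for persistent).
#' @export
generate_proteome <- function(design, indices = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  n <- design$n_proteins
  empty_truth <- data.table(
    protein = character(), class = character(), x_c = numeric(),
    amplitude = numeric(), slope = numeric(), direction = integer(),
    persistent = logical(), responder = logical(), enriched = logical(),
    absent_conditions = character())
  if (n == 0L) return(list(sequences = setNames(character(), character()),
                           truth = empty_truth))

  ids <- sprintf("SYNP%04d", seq_len(n))
  cv <- design$condition_values
  boundary <- class_boundary(design$axis)

  n_pers <- round(design$frac_persistent * n)
  persistent <- ids %in% sample(ids, n_pers)
  pers_ids <- ids[persistent]
  n_resp <- round(design$frac_responders * n_pers)
  responder <- ids %in% sample(pers_ids, n_resp)

  rng <- diff(range(cv))
  x_c <- ifelse(responder,
                runif(n, min(cv) + 0.05 * rng, max(cv) - 0.05 * rng), NA_real_)
  amplitude <- ifelse(responder, runif(n, 1.0, 2.5), NA_real_)
  smag <- if (design$axis == "temperature") runif(n, 0.25, 0.6) else runif(n, 1.5, 3)
  slope <- ifelse(responder, smag, NA_real_)
  direction <- ifelse(responder, sample(c(-1L, 1L), n, replace = TRUE), 0L)

  cls <- rep("exchanged", n)
  cls[persistent] <- "I"
  side <- ifelse(x_c < boundary, "II", "III")
  updown <- ifelse(direction > 0, "up", "down")
  cls[responder] <- paste0(side[responder], "-", updown[responder])

  absent <- rep("", n)
  for (i in which(!persistent)) {
    k <- sample(1:2, 1)
    absent[i] <- paste(sort(sample(cv, k)), collapse = ",")
  }

  enriched <- rep(FALSE, n)
  f_bg <- AA_BACKGROUND_FREQ[AA_ORDER]
  f_enr <- f_bg
  es <- design$enrichment_spec
  if (!is.null(es)) {
    v <- es$values
    if (is.null(v) && !is.null(indices)) {
      hit <- Filter(function(ix) ix$accession == es$accession, indices)
      if (length(hit)) v <- hit[[1]]$values
    }
    if (is.null(v))
      stop("enrichment index not provided: ", es$accession)
    v <- v[AA_ORDER]
    enriched <- persistent
    f_enr <- tilt_frequencies(f_bg, v, es$shift)
  }

  lens <- sample(100:600, n, replace = TRUE)
  sequences <- vapply(seq_len(n), function(i) {
    f <- if (enriched[i]) f_enr else f_bg
    paste(sample(AA_ORDER, lens[i], replace = TRUE, prob = f), collapse = "")
  }, character(1))
  names(sequences) <- ids

  truth <- data.table(
    protein = ids, class = cls, x_c = x_c, amplitude = amplitude,
    slope = slope, direction = direction, persistent = persistent,
    responder = responder, enriched = enriched, absent_conditions = absent)
  list(sequences = sequences, truth = truth)
}

#' Generate peptide-level abundance tables for a synthetic experiment
#'
#' Produces the nanoparticle-sample and particle-free-control peptide
#' tables for the proteome described by `truth`. Each protein receives a
#' baseline log10 abundance drawn from Normal(6, 1); responders follow the
#' 4-parameter logistic with their planted critical value, amplitude and
#' direction; each peptide carries a fixed ionisation offset drawn from
#' Normal(0, 0.5) plus i.i.d. replicate noise of sd `noise_sd_log10`
#' (all log10 units). Control abundances are `control_carryover` times the
#' realised sample abundance times independent multiplicative noise.
#' Exchanged proteins have no rows (sample or control) at their absent
#' conditions; absence is always encoded as a missing row, never as a zero.
#'
#' @param design The [synthetic_design()] used for `truth`.
#' @param truth Ground-truth table from [generate_proteome()].
#' @return `list(sample = <peptide_table>, control = <peptide_table>)`,
#'   long tables with columns `peptide`, `protein`, `condition`,
#'   `replicate`, `abundance` (linear scale).
#' @export
generate_experiment <- function(design, truth) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed + 1L)
  cv <- design$condition_values
  nrep <- design$n_replicates
  n <- nrow(truth)
  empty <- peptide_table(data.table(
    peptide = character(), protein = character(), condition = numeric(),
    replicate = integer(), abundance = numeric()))
  if (n == 0L) return(list(sample = empty, control = empty))

  ppp <- design$peptides_per_protein
  npep <- sample_triangular_int(n, ppp["min"], ppp["mode"], ppp["max"])
  baseline <- rnorm(n, 6, 1)

  pep <- data.table(
    protein = rep(truth$protein, npep),
    peptide = unlist(lapply(seq_len(n), function(i)
      sprintf("PEP_%s_%02d", truth$protein[i], seq_len(npep[i])))),
    offset = rnorm(sum(npep), 0, 0.5))

  # per-protein mean log10 abundance at each condition
  prof <- truth[, {
    mu <- if (responder[1]) {
      logistic4(cv, b = baseline[.GRP], t = baseline[.GRP] + amplitude,
                xc = x_c, s = -direction * slope)
    } else rep(baseline[.GRP], length(cv))
    .(condition = cv, mu = mu)
  }, by = protein]  # .GRP == truth row index (proteins unique, order kept)

  grid <- pep[prof[, .(protein, condition, mu)], on = "protein",
              allow.cartesian = TRUE]
  grid <- grid[rep(seq_len(.N), each = nrep)]
  grid[, replicate := rep_len(seq_len(nrep), .N)]

  # drop absent (protein, condition) cells of exchanged proteins
  exch <- truth[absent_conditions != ""]
  if (nrow(exch)) {
    ab <- exch[, .(condition = as.numeric(strsplit(absent_conditions, ",")[[1]])),
               by = protein]
    grid <- grid[!ab, on = c("protein", "condition")]
  }

  grid[, noise := rnorm(.N, 0, design$noise_sd_log10)]
  grid[, abundance := 10^(mu + offset + noise)]
  sample_tab <- grid[, .(peptide, protein, condition, replicate, abundance)]
  setorder(sample_tab, protein, peptide, condition, replicate)

  if (design$control_carryover > 0) {
    ctl <- copy(grid)
    ctl[, carry := rnorm(.N, 0, design$noise_sd_log10)]
    ctl[, abundance := design$control_carryover * abundance * 10^carry]
    control_tab <- ctl[, .(peptide, protein, condition, replicate, abundance)]
    setorder(control_tab, protein, peptide, condition, replicate)
  } else {
    control_tab <- sample_tab[0]
  }
  list(sample = peptide_table(sample_tab),
       control = peptide_table(control_tab))
}

#' Write protein sequences as FASTA
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output file; plain FASTA, 60-column wrap.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(sequences), names = names(sequences),
                      file.out = path, nbchar = 60, as.string = TRUE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector (upper-case sequences).
#' @export
read_proteome_fasta <- function(path) {
  x <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          forceDNAtolower = FALSE)
  setNames(toupper(vapply(x, `[[`, character(1), 1)), names(x))
}

#' Write a peptide table as TSV
#'
#' @param table A peptide table (columns `peptide`, `protein`, `condition`,
#'   `replicate`, `abundance`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path) {
  fwrite(as.data.table(table), path, sep = "\t")
  invisible(path)
}
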