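#' Construct an amino-acid property index
#'
#' One entry of the AAindex database: a named scale assigning a numeric
#' value to each of the 20 standard amino acids, plus a category in the
#' six-group scheme used to organise the property tree (composition,
#' physicochemical properties, beta propensity, alpha and turn
#' propensities, hydrophobicity, other).
#'
#' @param accession Index accession (e.g. a 10-character AAindex id).
#' @param description Free-text description of the scale.
#' @param values Named numeric vector over one-letter amino-acid codes;
#'   missing residues are `NA`. At least `min_values` of the 20 residues
#'   must have values.
#' @param category One of the six categories (default `"other"`).
#' @param min_values Minimum number of scored residues (default 15, the
#'   database acceptance rule; lower it only for deliberately degenerate
#'   scales).
#' @return A `property_index` object.
#' @export
property_index <- function(accession, description, values,
                           category = "other", min_values = 15L) {
  v <- rep(NA_real_, 20)
  names(v) <- AA_ORDER
  v[intersect(names(values), AA_ORDER)] <-
    as.numeric(values[intersect(names(values), AA_ORDER)])
  if (sum(!is.na(v)) < min_values)
    stop("index ", accession, " has values for fewer than ", min_values,
         " amino acids")
  structure(list(accession = accession, description = description,
                 values = v, category = category),
            class = "property_index")
}

#' @export
print.property_index <- function(x, ...) {
  cat(sprintf("property_index %s [%s]\n  %s\n", x$accession, x$category,
              x$description))
  invisible(x)
}

PROPERTY_CATEGORIES <- c("composition", "physicochemical properties",
                         "beta propensity", "alpha and turn propensities",
                         "hydrophobicity", "other")

#' Parse an AAindex1 flat-format file
#'
#' Reads entries of the AAindex1 format: `H` accession line, `D`
#' description, and an `I` block whose header row names the residue
#' columns (`A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V`) followed by two
#' rows of 10 values (first row A R N D C Q E G H I, second row
#' L K M F P S T W Y V); `NA` marks a missing value. Entries with fewer
#' than 15 residue values are dropped with a warning.
#'
#' @param path AAindex1 flat file.
#' @param categories Optional accession -> category mapping (named
#'   character vector or two-column data.frame); unmapped entries get the
#'   keyword-based category of [categorize_indices()].
#' @return List of [property_index()] objects.
#' @export
parse_aaindex <- function(path, categories = NULL) {
  lines <- readLines(path, warn = FALSE)
  breaks <- c(0, which(trimws(lines) == "//"))
  out <- list()
  for (e in seq_len(length(breaks) - 1L)) {
    block <- lines[(breaks[e] + 1L):(breaks[e + 1L] - 1L)]
    if (!length(block) || !any(grepl("^H ", block))) next
    acc <- trimws(sub("^H ", "", block[grep("^H ", block)[1]]))
    dpos <- grep("^D ", block)
    desc <- if (length(dpos)) trimws(sub("^D ", "", block[dpos[1]])) else ""
    ipos <- grep("^I ", block)
    if (!length(ipos) || length(block) < ipos[1] + 2L)
      stop("malformed I block in AAindex entry ", acc)
    header <- block[ipos[1]]
    if (!grepl("A/L", header, fixed = TRUE))
      stop("malformed I block in AAindex entry ", acc,
           ": unexpected column header")
    toks <- unlist(strsplit(trimws(block[ipos[1] + 1:2]), "[[:space:]]+"))
    if (length(toks) != 20L)
      stop("malformed I block in AAindex entry ", acc,
           ": expected 20 values, got ", length(toks))
    vals <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
    if (any(is.na(vals) & toks != "NA"))
      stop("malformed I block in AAindex entry ", acc,
           ": unparsable value '", toks[which(is.na(vals) & toks != "NA")[1]], "'")
    # row 1: A R N D C Q E G H I; row 2: L K M F P S T W Y V (== AA_ORDER)
    named <- setNames(vals, AA_ORDER)
    if (sum(!is.na(named)) < 15L) {
      warning("dropping AAindex entry ", acc,
              ": fewer than 15 amino-acid values")
      next
    }
    out[[acc]] <- property_index(acc, desc, named)
  }
  categorize_indices(out, categories)
}

#' Write property indices in AAindex1 flat format
#'
#' @param indices List of [property_index()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(indices, path) {
  fmt <- function(v) paste(sprintf("%8s",
    ifelse(is.na(v), "NA", sprintf("%.3f", v))), collapse = "")
  lines <- unlist(lapply(indices, function(ix) {
    v <- ix$values[AA_ORDER]
    c(paste("H", ix$accession),
      paste("D", ix$description),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      fmt(v[1:10]), fmt(v[11:20]), "//")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Assign the six property categories
#'
#' Uses an explicit accession -> category table where provided; otherwise
#' falls back to keyword matching on the index description. The keyword
#' rules are a heuristic stand-in for a curated annotation and default to
#' `"other"` when no keyword matches.
#'
#' @param indices List of [property_index()] objects.
#' @param categories Named character vector (accession -> category) or a
#'   two-column data.frame `(accession, category)`, e.g. read from TSV.
#' @return The list with `category` fields filled in.
#' @export
categorize_indices <- function(indices, categories = NULL) {
  map <- character()
  if (!is.null(categories)) {
    if (is.data.frame(categories))
      map <- setNames(as.character(categories[[2]]),
                      as.character(categories[[1]]))
    else map <- categories
    bad <- setdiff(unique(map), PROPERTY_CATEGORIES)
    if (length(bad))
      stop("unknown categor(ies): ", paste(bad, collapse = ", "))
  }
  for (i in seq_along(indices)) {
    acc <- indices[[i]]$accession
    indices[[i]]$category <-
      if (acc %in% names(map)) map[[acc]]
      else categorize_description(indices[[i]]$description)
  }
  indices
}

categorize_description <- function(description) {
  d <- tolower(description)
  if (grepl("hydrophob|hydropath|polarity|polar requirement|transfer free energy|partition|solvation|hydration", d))
    "hydrophobicity"
  else if (grepl("beta-sheet|beta-strand|beta structure|beta-structure|beta propensit|beta region|beta-turn", d))
    if (grepl("beta-turn", d)) "alpha and turn propensities" else "beta propensity"
  else if (grepl("alpha-helix|helix|helical|turn|coil|bend|loop", d))
    "alpha and turn propensities"
  else if (grepl("composition|frequency|frequencies|content|occurrence|proportion|number of", d))
    "composition"
  else if (grepl("volume|weight|size|bulk|charge|pk|isoelectric|refractiv|polariz|flexib|accessib|area|energy|entropy|heat|hydration number|mobilit", d))
    "physicochemical properties"
  else "other"
}

#' Load the 544 AAindex v9.1 properties shipped with seqinr
#'
#' Converts the `aaindex` dataset of the seqinr package into
#' [property_index()] objects (canonical residue order, categories filled
#' by [categorize_indices()]). Entries with fewer than 15 residue values
#' are dropped.
#'
#' @param categories Optional accession -> category mapping as in
#'   [parse_aaindex()].
#' @return List of `property_index` objects.
#' @export
aaindex_properties <- function(categories = NULL) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aa <- env$aaindex
  out <- list()
  three_to_one <- setNames(names(AA_THREE), AA_THREE)
  for (e in aa) {
    v <- e$I
    names(v) <- three_to_one[names(v)]
    if (sum(!is.na(v)) < 15L) next
    out[[e$H]] <- property_index(e$H, e$D, v)
  }
  categorize_indices(out, categories)
}

#' Per-protein value of an amino-acid property
#'
#' The arithmetic mean of the per-residue index values over residues that
#' have a value; letters outside the 20 standard amino acids are skipped.
#' Returns `NA` if fewer than half of the sequence's residues are scored.
#'
#' @param sequence Amino-acid sequence (character scalar).
#' @param index A [property_index()].
#' @return Numeric property value (or `NA`).
#' @export
protein_property <- function(sequence, index) {
  if (!nzchar(sequence)) stop("empty sequence")
  ch <- strsplit(toupper(sequence), "")[[1]]
  v <- index$values[ch]
  scored <- sum(!is.na(v))
  if (scored < 0.5 * length(ch)) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Property value matrix for many proteins and indices
#'
#' Vectorised [protein_property()]: computes residue counts once and
#' applies every index by matrix multiplication.
#'
#' @param sequences Named character vector of sequences.
#' @param indices List of [property_index()] objects.
#' @return Numeric matrix, proteins x properties (rownames = protein ids,
#'   colnames = accessions).
#' @export
property_matrix <- function(sequences, indices) {
  if (any(!nzchar(sequences))) stop("empty sequence")
  counts <- t(vapply(strsplit(toupper(sequences), ""),
                     function(ch) tabulate(factor(ch, levels = AA_ORDER),
                                           nbins = 20L),
                     integer(20)))
  len <- nchar(sequences)
  X <- matrix(NA_real_, length(sequences), length(indices),
              dimnames = list(names(sequences),
                              vapply(indices, `[[`, character(1), "accession")))
  for (j in seq_along(indices)) {
    v <- indices[[j]]$values[AA_ORDER]
    has <- !is.na(v)
    num <- counts %*% ifelse(has, v, 0)
    den <- counts %*% has
    val <- as.numeric(num / den)
    val[den < 0.5 * len] <- NA_real_
    X[, j] <- val
  }
  X
}

# P10 and P90 of an already sorted vector, linear-interpolation convention
# (continuous quantiles between order statistics, endpoints at extremes).
.p10p90_sorted <- function(s) {
  n <- length(s)
  h <- 1 + c(0.1, 0.9) * (n - 1)
  lo <- floor(h); g <- h - lo
  s[lo] * (1 - g) + s[pmin(lo + 1, n)] * g
}

#' Dispersion of a property distribution
#'
#' The difference between the 90th and the 10th percentiles (linear
#' interpolation between order statistics).
#'
#' @param values Numeric vector; at least 5 non-missing values.
#' @return Non-negative dispersion `P90 - P10`.
#' @export
dispersion <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 5L) stop("at least 5 non-missing values required")
  q <- .p10p90_sorted(sort(unname(v)))
  q[2] - q[1]
}

# Sort each row of a matrix (vectorised via a single radix order call).
.row_sort <- function(V) {
  matrix(V[order(row(V), V, method = "radix")],
         nrow = nrow(V), byrow = TRUE)
}

# Null dispersions: for each row of the index matrix `idx` (one resampled
# protein subset per row), the P90-P10 dispersion of x[idx[i, ]].
.null_dispersions <- function(x, idx) {
  m <- ncol(idx)
  S <- .row_sort(matrix(x[idx], nrow(idx), m))
  h <- 1 + c(0.1, 0.9) * (m - 1)
  lo <- floor(h); g <- h - lo
  p10 <- S[, lo[1]] * (1 - g[1]) + S[, min(lo[1] + 1, m)] * g[1]
  p90 <- S[, lo[2]] * (1 - g[2]) + S[, min(lo[2] + 1, m)] * g[2]
  p90 - p10
}

# One-sided tail in the observed direction, doubled (two one-sided tests
# with the direction chosen by the data; doubling keeps the p-value valid
# under that selection) and capped at 1. The +1 correction keeps sampled
# p-values strictly positive; exact enumeration needs no correction
# because the observed subset is itself among the enumerated ones.
.perm_pvalue <- function(L_obs, L_null, n_draws, exact) {
  direction <- if (L_obs < 1) "lessened" else "widened"
  extreme <- if (direction == "lessened") sum(L_null <= L_obs)
             else sum(L_null >= L_obs)
  tail <- if (exact) extreme / n_draws else (1 + extreme) / (n_draws + 1)
  list(p = min(1, 2 * tail), direction = direction)
}

#' Dispersion-lessening test for one property
#'
#' Tests whether the persistent corona fraction has a narrower (or wider)
#' property distribution than the plasma background. The statistic is the
#' lessening ratio `L = D_corona / D_plasma` of P90-P10 dispersions. The
#' null is built by drawing `n_perm` uniform random same-size subsets of
#' the background (or bootstrap resamples with `method = "bootstrap"`).
#' Lessening (`L < 1`) and widening (`L > 1`) are tested as two one-sided
#' tails: the reported p-value is the tail in the observed direction,
#' doubled (so it stays valid although the direction is chosen by the
#' data) and capped at 1, with the +1 correction so p is never 0. With
#' `exact = TRUE` all subsets of the background are enumerated instead
#' and the doubled exact tail probability is reported.
#'
#' @param persistent_ids Protein ids of the persistent corona set
#'   (subset of `background_ids`, at least 5).
#' @param background_ids Protein ids of the plasma background.
#' @param values Named numeric property values covering the background.
#' @param n_perm Number of resamples (>= 100).
#' @param seed Integer seed for the resampling stream.
#' @param method `"subset"` (default, permutation of protein labels) or
#'   `"bootstrap"` (with replacement).
#' @param exact Enumerate all `choose(n, m)` subsets (only feasible for
#'   small backgrounds; `n_perm` is ignored).
#' @return list: `D_corona`, `D_plasma`, `L`, `p_perm`, `direction`
#'   (`"lessened"` or `"widened"`), `shift_median`, `shift_mean`,
#'   `n_draws`.
#' @export
lessening_test <- function(persistent_ids, background_ids, values,
                           n_perm = 999L, seed = 1L,
                           method = c("subset", "bootstrap"),
                           exact = FALSE) {
  method <- match.arg(method)
  if (!all(persistent_ids %in% background_ids))
    stop("persistent_ids must be a subset of background_ids")
  m <- length(persistent_ids)
  if (m < 5L) stop("at least 5 persistent proteins required")
  if (!exact && n_perm < 100L) stop("n_perm < 100 gives unstable p-values")
  xb <- values[background_ids]
  xp <- values[persistent_ids]
  D_plasma <- dispersion(xb)
  D_corona <- dispersion(xp)
  if (D_plasma == 0) stop("background dispersion is zero")
  L <- D_corona / D_plasma
  n <- length(background_ids)
  if (exact) {
    if (choose(n, m) > 2e5)
      stop("exact enumeration infeasible: choose(", n, ", ", m, ") subsets")
    idx <- t(combn(n, m))
  } else {
    set.seed(seed)
    idx <- t(vapply(seq_len(n_perm), function(i)
      sample.int(n, m, replace = method == "bootstrap"), integer(m)))
  }
  L_null <- .null_dispersions(xb, idx) / D_plasma
  pv <- .perm_pvalue(L, L_null, nrow(idx), exact)
  list(D_corona = D_corona, D_plasma = D_plasma, L = L,
       p_perm = pv$p, direction = pv$direction,
       shift_median = median(xp) - median(xb),
       shift_mean = mean(xp) - mean(xb),
       n_draws = nrow(idx))
}

#' Dispersion-lessening scan over many properties
#'
#' Runs the lessening test for every column of a property value matrix,
#' sharing one stream of resampled protein subsets across all properties
#' (the null resamples proteins, so the same subsets apply to every
#' property), and applies Benjamini-Hochberg correction across properties.
#'
#' @param X Property value matrix from [property_matrix()] (proteins x
#'   properties; rownames = protein ids).
#' @param persistent_ids Persistent protein ids (subset of rownames).
#' @param n_perm Number of resampled subsets (>= 100).
#' @param seed Integer seed.
#' @param indices Optional list of [property_index()] objects used to
#'   annotate results with description and category.
#' @param method `"subset"` or `"bootstrap"` as in [lessening_test()].
#' @return data.table with one row per property: `accession`,
#'   `description`, `category`, `D_corona`, `D_plasma`, `L`, `p_perm`,
#'   `q`, `direction`, `shift_median`, `shift_mean`.
#' @export
lessening_scan <- function(X, persistent_ids, n_perm = 999L, seed = 1L,
                           indices = NULL,
                           method = c("subset", "bootstrap")) {
  method <- match.arg(method)
  if (!all(persistent_ids %in% rownames(X)))
    stop("persistent_ids must be a subset of rownames(X)")
  m <- length(persistent_ids)
  if (m < 5L) stop("at least 5 persistent proteins required")
  if (n_perm < 100L) stop("n_perm < 100 gives unstable p-values")
  drop <- colSums(is.na(X)) > 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " propert(ies) with missing values")
    X <- X[, !drop, drop = FALSE]
  }
  n <- nrow(X)
  pers_rows <- match(persistent_ids, rownames(X))
  set.seed(seed)
  idx <- t(vapply(seq_len(n_perm), function(i)
    sample.int(n, m, replace = method == "bootstrap"), integer(m)))

  res <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    D_plasma <- dispersion(x)
    D_corona <- dispersion(x[pers_rows])
    if (D_plasma == 0)
      return(data.table(accession = colnames(X)[j], D_corona = D_corona,
                        D_plasma = D_plasma, L = NA_real_,
                        p_perm = NA_real_, direction = NA_character_,
                        shift_median = NA_real_, shift_mean = NA_real_))
    L <- D_corona / D_plasma
    L_null <- .null_dispersions(x, idx) / D_plasma
    pv <- .perm_pvalue(L, L_null, n_perm, exact = FALSE)
    data.table(accession = colnames(X)[j], D_corona = D_corona,
               D_plasma = D_plasma, L = L, p_perm = pv$p,
               direction = pv$direction,
               shift_median = median(x[pers_rows]) - median(x),
               shift_mean = mean(x[pers_rows]) - mean(x))
  })
  out <- rbindlist(res)
  out[, q := NA_real_]
  ok <- !is.na(out$p_perm)
  out$q[ok] <- bh_adjust(out$p_perm[ok])
  if (!is.null(indices)) {
    ann <- data.table(
      accession = vapply(indices, `[[`, character(1), "accession"),
      description = vapply(indices, `[[`, character(1), "description"),
      category = vapply(indices, `[[`, character(1), "category"))
    out <- ann[out, on = "accession"]
  } else {
    out[, `:=`(description = NA_character_, category = NA_character_)]
  }
  setcolorder(out, c("accession", "description", "category", "D_corona",
                     "D_plasma", "L", "p_perm", "q", "direction",
                     "shift_median", "shift_mean"))
  out[]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment; input p-values must lie in [0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted q-values (same order as input).
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Filter a lessening scan to significant properties
#'
#' @param results Output of [lessening_scan()].
#' @param q_threshold FDR threshold (default 0.005); a threshold of 1 or
#'   more disables filtering and retains every tested property.
#' @return Rows with `q < q_threshold`, sorted by `q`.
#' @export
enrichment_table <- function(results, q_threshold = 0.005) {
  dt <- as.data.table(results)
  out <- if (q_threshold >= 1) dt[!is.na(q)] else dt[!is.na(q) & q < q_threshold]
  setorder(out, q)
  out[]
}
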