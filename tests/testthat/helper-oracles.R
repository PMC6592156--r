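# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use plain loops / base R so they share no code
# path with the implementation they check.

aaindex_fixture_path <- function() {
  system.file("extdata", "aaindex_synthetic.txt", package = "coronashift")
}

fixture_indices <- function() parse_aaindex(aaindex_fixture_path())

kd_values <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

logistic4_ref <- function(x, b, t, xc, s) b + (t - b) / (1 + exp(s * (x - xc)))

# Brute-force Top3 + control subtraction: loops over every key, sorts,
# takes the middle of the top three, clamps at zero.
oracle_top3_subtract <- function(sample_df, control_df, min_peptides = 3) {
  keys <- unique(sample_df[, c("protein", "condition", "replicate")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    rows <- sample_df$protein == k$protein &
      sample_df$condition == k$condition & sample_df$replicate == k$replicate
    ab <- sample_df$abundance[rows]
    if (length(ab) < min_peptides) next
    top <- sort(ab, decreasing = TRUE)[seq_len(min(3, length(ab)))]
    mid <- if (length(top) == 3) top[2] else if (length(top) == 2)
      (top[1] + top[2]) / 2 else top[1]
    crows <- control_df$protein == k$protein &
      control_df$condition == k$condition & control_df$replicate == k$replicate
    cab <- control_df$abundance[crows]
    cval <- if (length(cab) >= min_peptides) {
      ctop <- sort(cab, decreasing = TRUE)[seq_len(min(3, length(cab)))]
      if (length(ctop) == 3) ctop[2] else if (length(ctop) == 2)
        (ctop[1] + ctop[2]) / 2 else ctop[1]
    } else 0
    out[[i]] <- data.frame(protein = k$protein, condition = k$condition,
                           replicate = k$replicate,
                           abundance = max(mid - cval, 0))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(protein = character(), condition = numeric(),
                      replicate = integer(), abundance = numeric()))
  res[order(res$protein, res$condition, res$replicate), ]
}

random_peptide_table <- function(n_proteins = 6, conditions = c(1, 2, 3, 4),
                                 n_reps = 2, max_peptides = 6) {
  rows <- list()
  for (p in sprintf("PR%02d", seq_len(n_proteins))) {
    npep <- sample(1:max_peptides, 1)
    peps <- sprintf("%s_pep%d", p, seq_len(npep))
    for (cc in conditions) for (r in seq_len(n_reps)) {
      present <- runif(npep) < 0.85
      if (!any(present)) next
      rows[[length(rows) + 1]] <- data.frame(
        peptide = peps[present], protein = p, condition = cc, replicate = r,
        abundance = 10^runif(sum(present), 3, 8))
    }
  }
  do.call(rbind, rows)
}

# Sort-and-interpolate percentile oracle (linear interpolation between
# order statistics), written independently of dispersion().
oracle_p90_minus_p10 <- function(v) {
  v <- sort(unname(v[is.finite(v)]))
  n <- length(v)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    f <- h - floor(h)
    v[floor(h)] + f * (v[min(floor(h) + 1, n)] - v[floor(h)])
  }
  interp(0.9) - interp(0.1)
}

# Exhaustive minimum spanning tree weight by enumerating all subsets of
# n - 1 edges and keeping the cheapest acyclic connected one.
oracle_mst_weight <- function(w) {
  n <- nrow(w)
  pairs <- t(combn(n, 2))
  wts <- w[pairs]
  best <- Inf
  for (cols in asplit(combn(nrow(pairs), n - 1), 2)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in cols) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(wts[cols]))
  }
  best
}

# Dense grid-search minimiser for the 4-parameter logistic, used as an
# independent check of the nonlinear least-squares fit.
oracle_grid_fit <- function(x, y, xc_grid, s_grid) {
  best <- list(rss = Inf)
  b_grid <- seq(min(y), max(y), length.out = 12)
  for (xc in xc_grid) for (s in s_grid)
    for (b in b_grid) for (tt in b_grid[b_grid >= b]) {
      r <- y - logistic4_ref(x, b, tt, xc, s)
      rss <- sum(r * r)
      if (rss < best$rss) best <- list(b = b, t = tt, xc = xc, s = s, rss = rss)
    }
  best
}
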