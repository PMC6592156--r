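make_table <- function(...) {
  peptide_table(data.frame(...))
}

test_that("peptide table IO validates structure and conventions", {
  df <- data.frame(peptide = c("a", "b", "c"), protein = "P1",
                   condition = 1, replicate = 1L, abundance = c(10, 8, 6))
  tf <- tempfile(fileext = ".tsv")
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- read_peptide_table(tf)
  expect_equal(nrow(tab), 3)

  # missing column named in the error
  tf2 <- tempfile(fileext = ".tsv")
  write.table(df[, -5], tf2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_peptide_table(tf2), "abundance")

  # duplicated key cited
  dup <- rbind(df, df[1, ])
  expect_error(peptide_table(dup), "duplicated key.*peptide=a")

  # zero abundance violates the zero-means-absent convention
  z <- df; z$abundance[2] <- 0
  expect_error(peptide_table(z), "missing rows, not zeros")

  # unparsable numeric reported with its row
  bad <- df; bad$abundance <- as.character(bad$abundance)
  bad$abundance[3] <- "oops"
  tf3 <- tempfile(fileext = ".tsv")
  write.table(bad, tf3, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_peptide_table(tf3), "row 3")
})

test_that("Top3 takes the middle of the three most abundant peptides", {
  tab <- make_table(peptide = c("a", "b", "c", "d"), protein = "P1",
                    condition = 1, replicate = 1L,
                    abundance = c(10, 8, 6, 1))
  expect_equal(top3(tab)$abundance, 8)

  # fewer than min_peptides quantified peptides -> excluded
  two <- make_table(peptide = c("a", "b"), protein = "P1", condition = 1,
                    replicate = 1L, abundance = c(5, 5))
  expect_equal(nrow(top3(two, min_peptides = 3)), 0)
  expect_error(top3(two, min_peptides = 0), "min_peptides")

  # tie-rich case, invariant over all input orders
  ab <- c(7, 7, 7, 2, 1)
  perms <- rbind(c(1:5), c(5:1), c(3, 1, 4, 2, 5), c(2, 4, 1, 5, 3))
  for (i in seq_len(nrow(perms))) {
    tab <- make_table(peptide = letters[perms[i, ]], protein = "P1",
                      condition = 1, replicate = 1L,
                      abundance = ab[perms[i, ]])
    expect_equal(top3(tab)$abundance, 7)
  }
})

test_that("Top3 is scale-equivariant and order-invariant", {
  set.seed(4)
  df <- random_peptide_table()
  tab <- peptide_table(df)
  m1 <- as.data.frame(top3(tab))
  df2 <- df; df2$abundance <- df2$abundance * 3.7
  m2 <- as.data.frame(top3(peptide_table(df2)))
  expect_equal(m2$abundance, m1$abundance * 3.7)
  m3 <- as.data.frame(top3(peptide_table(df[sample(nrow(df)), ])))
  expect_equal(m3, m1)
})

test_that("control subtraction clamps, defaults missing controls to zero", {
  s <- make_table(peptide = c("a", "b", "c", "d", "e", "f"),
                  protein = rep(c("P1", "P2"), each = 3),
                  condition = 1, replicate = 1L,
                  abundance = c(100, 100, 100, 20, 20, 20))
  ctl <- make_table(peptide = c("a", "b", "c", "d", "e", "f"),
                    protein = rep(c("P1", "P2"), each = 3),
                    condition = 1, replicate = 1L,
                    abundance = c(30, 30, 30, 30, 30, 30))
  out <- as.data.frame(subtract_control(top3(s), top3(ctl)))
  expect_equal(out$abundance[out$protein == "P1"], 70)
  expect_equal(out$abundance[out$protein == "P2"], 0)  # clamped negative
  # a clamped zero is non-detection downstream
  pres <- presence_calls(subtract_control(top3(s), top3(ctl)),
                         min_replicates = 1)
  expect_false(pres$present[pres$protein == "P2"])

  # control missing for a protein: corrected equals sample exactly
  out2 <- as.data.frame(subtract_control(top3(s), top3(ctl)[protein == "none"]))
  expect_equal(out2$abundance, as.data.frame(top3(s))$abundance)

  # asymmetric condition sets are rejected with the offending conditions
  s2 <- make_table(peptide = c("a", "b", "c"), protein = "P1", condition = 2,
                   replicate = 1L, abundance = c(1, 2, 3))
  expect_error(subtract_control(top3(s2), top3(ctl)), "condition sets differ")
})

test_that("subtraction is non-negative and idempotent for all-zero control", {
  set.seed(8)
  tab <- peptide_table(random_peptide_table())
  m <- top3(tab)
  empty_ctl <- m[0]
  once <- subtract_control(m, empty_ctl)
  expect_true(all(once$abundance >= 0))
  twice <- subtract_control(once, empty_ctl)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("presence calls implement the >= min_replicates rule exactly", {
  mk <- function(pattern) {
    # pattern: logical length 3, detected replicate or not
    m <- data.table::data.table(protein = "P1", condition = 1,
                                replicate = 1:3,
                                abundance = ifelse(pattern, 5, 0),
                                n_peptides = 3L)
    coronashift:::abundance_matrix(m)
  }
  # exhaustive truth over all 2^3 patterns
  for (bits in 0:7) {
    pattern <- as.logical(bitwAnd(bits, c(1, 2, 4)))
    pres <- presence_calls(mk(pattern), min_replicates = 2)
    expect_equal(pres$present, sum(pattern) >= 2, info = paste(pattern, collapse = ""))
  }
  expect_error(presence_calls(mk(c(TRUE, TRUE, TRUE)), min_replicates = 4),
               "exceeds replicate count")
})

test_that("quantification summary fractions and medians are recomputed", {
  set.seed(12)
  df <- random_peptide_table(n_proteins = 10, max_peptides = 8)
  tab <- peptide_table(df)
  mat <- top3(tab)
  s <- quant_summary(list(peptides = 200, proteins = 15), tab, mat)
  # independent recount
  key <- unique(df[, c("peptide", "protein")])
  expect_equal(s$frac_peptides_quantified, nrow(key) / 200)
  quantified <- unique(as.data.frame(mat)$protein)
  expect_equal(s$frac_proteins_quantified, length(quantified) / 15)
  counts <- sapply(quantified, function(p)
    length(unique(df$peptide[df$protein == p])))
  expect_equal(s$median_peptides_per_protein, median(counts))

  s87 <- quant_summary(list(peptides = 100, proteins = 100),
                       tab[1:87][, peptide := sprintf("q%02d", 1:87)], mat)
  expect_equal(s87$frac_peptides_quantified, 0.87)
  expect_error(quant_summary(list(peptides = 0, proteins = 5), tab, mat),
               "positive")
})

test_that("replicate-mean log10 abundance is bounded by per-replicate extremes", {
  set.seed(19)
  tab <- peptide_table(random_peptide_table())
  m <- as.data.frame(log10_view(top3(tab)))
  agg <- aggregate(log10_abundance ~ protein + condition, m, mean)
  rng <- aggregate(log10_abundance ~ protein + condition, m, range)
  expect_true(all(agg$log10_abundance >= rng$log10_abundance[, 1] - 1e-12 &
                  agg$log10_abundance <= rng$log10_abundance[, 2] + 1e-12))
})
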