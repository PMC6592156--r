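test_that("the packaged AAindex fixture parses bit-exactly", {
  idx <- fixture_indices()
  expect_length(idx, 30)
  accs <- vapply(idx, `[[`, character(1), "accession")
  expect_equal(anyDuplicated(accs), 0)
  expect_equal(idx[["KYTJ820101"]]$values, kd_values)
  expect_equal(idx[["KYTJ820101"]]$category, "hydrophobicity")
  # the fixture deliberately contains one 18/20-value entry
  expect_equal(sum(is.na(idx[["SYNIDX0013"]]$values)), 2)
})

test_that("sparse and malformed AAindex entries are handled", {
  v <- kd_values; v[1:6] <- NA
  tf <- tempfile(fileext = ".txt")
  writeLines(c("H SPARSE0001", "D mostly missing index",
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               paste(ifelse(is.na(v[1:10]), "NA", v[1:10]), collapse = "   "),
               paste(ifelse(is.na(v[11:20]), "NA", v[11:20]), collapse = "   "),
               "//"), tf)
  expect_warning(idx <- parse_aaindex(tf), "SPARSE0001")
  expect_length(idx, 0)

  writeLines(c("H BROKEN0001", "D broken block",
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               "1 2 3", "4 5 6", "//"), tf)
  expect_error(parse_aaindex(tf), "BROKEN0001")
})

test_that("explicit category tables override the keyword heuristic", {
  idx <- fixture_indices()
  tab <- data.frame(accession = "KYTJ820101", category = "other")
  idx2 <- categorize_indices(idx, tab)
  expect_equal(idx2[["KYTJ820101"]]$category, "other")
  expect_error(categorize_indices(idx, data.frame(accession = "X",
                                                  category = "bogus")),
               "unknown categor")
})

test_that("per-protein property values are residue means", {
  kd <- property_index("KYTJ820101", "hydropathy", kd_values)
  expect_equal(protein_property("AAAA", kd), 1.8)
  vv <- setNames(rep(0, 20), names(kd_values))
  vv["A"] <- 1; vv["R"] <- 3
  two <- property_index("TEST000001", "toy", vv)
  expect_equal(protein_property("AR", two), 2)
  expect_error(protein_property("", kd), "empty")

  set.seed(6)
  seqs <- vapply(1:5, function(i)
    paste(sample(names(kd_values), 50, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("P%d", 1:5)
  X <- property_matrix(seqs, list(kd))
  for (i in 1:5) {
    ch <- strsplit(seqs[i], "")[[1]]
    expect_equal(unname(X[i, 1]), sum(kd_values[ch]) / length(ch))
  }
})

test_that("properties with sparse indices go missing below 50% coverage", {
  sparse <- property_index("SPRS000001", "sparse",
                           c(kd_values[1:15], setNames(rep(NA, 5),
                                                       names(kd_values)[16:20])))
  covered <- paste(rep(names(kd_values)[1:15], 4), collapse = "")
  uncovered <- paste(rep(names(kd_values)[16:20], 12), collapse = "")
  expect_false(is.na(protein_property(covered, sparse)))
  expect_true(is.na(protein_property(uncovered, sparse)))
})

test_that("dispersion equals the percentile oracle", {
  expect_equal(dispersion(0:10), 8)         # P10 = 1, P90 = 9
  expect_equal(dispersion(rep(3.3, 9)), 0)  # constant list
  expect_error(dispersion(c(1, 2, 3, 4)), "at least 5")
  set.seed(15)
  for (i in 1:100) {
    v <- rnorm(sample(5:40, 1), sd = runif(1, 0.1, 10))
    expect_equal(dispersion(v), oracle_p90_minus_p10(v))
    expect_equal(dispersion(v),
                 unname(diff(quantile(v, c(0.1, 0.9), type = 7))))
  }
})

test_that("degenerate persistent set equal to the background gives L = 1, p = 1", {
  set.seed(30)
  vals <- setNames(rnorm(12), sprintf("P%02d", 1:12))
  r <- lessening_test(names(vals), names(vals), vals, n_perm = 200, seed = 1)
  expect_equal(r$L, 1)
  expect_equal(r$p_perm, 1)
})

test_that("exact subset enumeration matches the permutation limit", {
  set.seed(44)
  vals <- setNames(c(rnorm(5, 0, 0.3), rnorm(3, 0, 3)), sprintf("P%d", 1:8))
  pers <- sprintf("P%d", 1:5)
  # independent enumeration of all choose(8, 5) = 56 subsets
  D_pl <- oracle_p90_minus_p10(vals)
  L_obs <- oracle_p90_minus_p10(vals[pers]) / D_pl
  subs <- combn(8, 5)
  L_null <- apply(subs, 2, function(ix) oracle_p90_minus_p10(vals[ix]) / D_pl)
  tail_exact <- if (L_obs < 1) mean(L_null <= L_obs) else mean(L_null >= L_obs)
  p_exact <- min(1, 2 * tail_exact)  # doubled observed-direction tail

  r <- lessening_test(pers, names(vals), vals, exact = TRUE)
  expect_equal(r$n_draws, 56)
  expect_equal(r$p_perm, p_exact)
  expect_equal(r$L, L_obs)

  # the sampled permutation estimate converges to the exact tail
  r2 <- lessening_test(pers, names(vals), vals, n_perm = 20000, seed = 2)
  expect_lt(abs(r2$p_perm - p_exact), 0.03)
})

test_that("the lessening ratio is shift- and scale-equivariant", {
  set.seed(52)
  vals <- setNames(rnorm(40), sprintf("P%02d", 1:40))
  pers <- sample(names(vals), 10)
  base <- lessening_test(pers, names(vals), vals, n_perm = 300, seed = 9)
  shifted <- lessening_test(pers, names(vals), vals + 100, n_perm = 300, seed = 9)
  scaled <- lessening_test(pers, names(vals), vals * 7, n_perm = 300, seed = 9)
  expect_equal(shifted$L, base$L)
  expect_equal(shifted$p_perm, base$p_perm)
  expect_equal(scaled$L, base$L)
  expect_equal(scaled$p_perm, base$p_perm)
  expect_equal(scaled$D_plasma, base$D_plasma * 7)
})

test_that("null permutation p-values are stochastically >= uniform", {
  set.seed(61)
  pvals <- replicate(150, {
    vals <- setNames(rnorm(40), sprintf("P%02d", 1:40))
    pers <- sample(names(vals), 8)
    lessening_test(pers, names(vals), vals, n_perm = 999,
                   seed = sample.int(1e6, 1))$p_perm
  })
  ks <- suppressWarnings(ks.test(pvals, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment validates input and matches the step-up form", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # closed-form step-up on a fixed list
  p <- c(0.003, 0.04, 0.2, 0.015, 0.9)
  o <- order(p)
  stepup <- pmin(1, rev(cummin(rev(p[o] * length(p) / seq_along(p)))))
  expect_equal(bh_adjust(p)[o], stepup)
})

test_that("a planted narrowed band flags the hydropathy index as lessened", {
  idx <- fixture_indices()
  d <- synthetic_design(n_proteins = 200, seed = 77)
  pr <- generate_proteome(d)
  X <- property_matrix(pr$sequences, idx)
  kd <- X[, "KYTJ820101"]
  band <- names(kd)[kd > quantile(kd, 0.35) & kd < quantile(kd, 0.65)]
  pers <- sample(band, 25)
  scan <- lessening_scan(X, pers, n_perm = 19999, seed = 5, indices = idx)
  row <- scan[scan$accession == "KYTJ820101", ]
  expect_lt(row$L, 1)
  expect_equal(row$direction, "lessened")
  expect_lt(row$q, 0.005)
  # hydrophobicity-category indices dominate the significant lessened rows
  sig <- enrichment_table(scan, 0.005)
  lessened <- sig[sig$direction == "lessened", ]
  expect_gt(mean(lessened$category == "hydrophobicity"), 0.3)
  # threshold 1 retains everything tested
  expect_equal(nrow(enrichment_table(scan, 1)), nrow(scan))
  # no result under an impossible threshold
  expect_equal(nrow(enrichment_table(scan, 1e-12)), 0)
})

test_that("scan results agree with single-property tests", {
  set.seed(99)
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("P%02d", 1:50), paste0("IX", 1:4)))
  pers <- sample(rownames(X), 10)
  scan <- lessening_scan(X, pers, n_perm = 499, seed = 7)
  for (j in 1:4) {
    single <- lessening_test(pers, rownames(X), X[, j], n_perm = 499, seed = 7)
    expect_equal(scan$L[j], single$L)
    expect_equal(scan$D_corona[j], single$D_corona)
    expect_equal(scan$p_perm[j], single$p_perm)
  }
  expect_true(all(scan$q >= scan$p_perm))
})
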