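#' Fit a 4-parameter logistic abundance-condition curve
#'
#' Fits `A(x) = b + (t - b) / (1 + exp(s * (x - x_c)))` to all replicate
#' log10 abundances of one protein by nonlinear least squares
#' (Levenberg-Marquardt), multi-started over a grid of midpoints and both
#' slope signs. The fitted midpoint `x_c` is the critical condition value:
#' the pH or temperature midway between the attached and the detached
#' states. A sigmoid verdict requires both a fitted end-to-end abundance
#' change across the observed condition range of at least
#' `amplitude_threshold` log10 units and an F-test of the sigmoid against
#' the flat (constant-mean) model rejecting at level `alpha`. The midpoint
#' is constrained to at most one condition step beyond the observed range;
#' a fit whose midpoint nevertheless falls outside that window is demoted
#' to flat (the transition is not observed, only extrapolated).
#'
#' @param x Numeric vector of condition values, one per observation
#'   (replicate points are repeated); at least 4 distinct conditions.
#' @param y Log10 abundances, same length as `x`.
#' @param amplitude_threshold Minimum fitted end-to-end change (log10
#'   units) for a sigmoid verdict (default 0.5).
#' @param alpha F-test level for sigmoid vs flat (default 0.05).
#' @param xc_grid_points Number of multi-start midpoints across the
#'   condition range (default 9).
#' @return A `sigmoid_fit` list: `b`, `t` (plateaus, with `t >= b`), `x_c`,
#'   `s`, `rss`, `rss_flat`, `f_p` (F-test p), `verdict` (`"sigmoid"` or
#'   `"flat"`), `direction` (+1 increasing with condition, -1 decreasing,
#'   0 flat), `demoted` (sigmoid rejected for out-of-range midpoint),
#'   `converged`, `n`.
#' @export
fit_sigmoid <- function(x, y, amplitude_threshold = 0.5, alpha = 0.05,
                        xc_grid_points = 9L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  ux <- sort(unique(x))
  if (length(ux) < 4L)
    stop("at least 4 distinct conditions are required (got ", length(ux), ")")
  n <- length(y)
  rss_flat <- sum((y - mean(y))^2)

  res <- list(b = mean(y), t = mean(y), x_c = NA_real_, s = NA_real_,
              rss = rss_flat, rss_flat = rss_flat, f_p = NA_real_,
              verdict = "flat", direction = 0L, demoted = FALSE,
              converged = TRUE, n = n)
  class(res) <- "sigmoid_fit"
  if (rss_flat < .Machine$double.eps * n) return(res)  # constant profile

  step_lo <- ux[2] - ux[1]
  step_hi <- ux[length(ux)] - ux[length(ux) - 1]
  b0 <- as.numeric(quantile(y, 0.1))
  t0 <- as.numeric(quantile(y, 0.9))
  s_scale <- 2 / mean(diff(ux))
  starts <- expand.grid(
    xc = seq(min(ux), max(ux), length.out = xc_grid_points),
    s = c(-1, 1) %o% c(0.5, 1) * s_scale)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(b = b0, t = t0, xc = starts$xc[i], s = starts$s[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + (t - b) / (1 + exp(s * (x - xc))),
                        start = st,
                        # midpoints are only meaningful inside the window
                        # observable from the design points
                        lower = c(-Inf, -Inf, min(ux) - step_lo, -Inf),
                        upper = c(Inf, Inf, max(ux) + step_hi, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- c(as.list(stats::coef(fit)), list(rss = rss))
  }
  if (is.null(best)) {
    # fall back to direct RSS minimisation from the central start
    obj <- function(p) {
      r <- y - logistic4(x, p[1], p[2], p[3], p[4])
      sum(r * r)
    }
    o <- optim(c(b0, t0, mean(range(ux)), s_scale), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    best <- list(b = o$par[1], t = o$par[2], xc = o$par[3], s = o$par[4],
                 rss = o$value)
    res$converged <- o$convergence == 0
  }

  # canonical orientation: t >= b (identical curve under (b,t,s)->(t,b,-s))
  if (best$t < best$b) {
    tmp <- best$b; best$b <- best$t; best$t <- tmp; best$s <- -best$s
  }
  res$b <- best$b; res$t <- best$t; res$x_c <- best$xc; res$s <- best$s
  res$rss <- best$rss

  df2 <- n - 4L
  if (df2 > 0L && res$rss > 0) {
    f_stat <- ((rss_flat - res$rss) / 3) / (res$rss / df2)
    res$f_p <- pf(f_stat, 3, df2, lower.tail = FALSE)
  } else if (df2 > 0L) {
    res$f_p <- 0  # perfect sigmoid fit of a non-constant profile
  }

  # the "change in abundance" that must be substantial is the fitted change
  # across the observed condition range, not the (possibly extrapolated)
  # plateau separation t - b
  amp_observed <- abs(logistic4(max(ux), res$b, res$t, res$x_c, res$s) -
                      logistic4(min(ux), res$b, res$t, res$x_c, res$s))
  amplitude_ok <- amp_observed >= amplitude_threshold
  ftest_ok <- !is.na(res$f_p) && res$f_p < alpha
  if (amplitude_ok && ftest_ok) {
    if (res$x_c < min(ux) - step_lo || res$x_c > max(ux) + step_hi) {
      res$demoted <- TRUE  # transition outside the observable range
    } else {
      res$verdict <- "sigmoid"
      res$direction <- if (res$s < 0) 1L else -1L
    }
  }
  res
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid_fit: verdict=%s direction=%+d\n", x$verdict, x$direction))
  cat(sprintf("  b=%.3f t=%.3f x_c=%.3f s=%.3f rss=%.4g (flat %.4g) p=%.3g\n",
              x$b, x$t, x$x_c, x$s, x$rss, x$rss_flat,
              if (is.na(x$f_p)) NA else x$f_p))
  invisible(x)
}

#' Fit sigmoid profiles for every protein in an abundance matrix
#'
#' Applies [fit_sigmoid()] to the log10 corrected abundances of each
#' protein with data at `min_conditions` or more distinct conditions, using
#' all replicate points.
#'
#' @param matrix Corrected `abundance_matrix`.
#' @param proteins Optional subset of protein ids (default: all).
#' @param min_conditions Minimum distinct conditions with data (default 4).
#' @inheritParams fit_sigmoid
#' @return data.table with one row per fitted protein: parameters, RSS,
#'   `f_p`, `verdict`, `direction`, `demoted`.
#' @export
fit_profiles <- function(matrix, proteins = NULL, min_conditions = 4L,
                         amplitude_threshold = 0.5, alpha = 0.05) {
  dt <- as.data.table(log10_view(matrix))
  dt <- dt[!is.na(log10_abundance)]
  if (!is.null(proteins)) dt <- dt[protein %in% proteins]
  fits <- dt[, {
    if (uniqueN(condition) >= min_conditions) {
      f <- fit_sigmoid(condition, log10_abundance,
                       amplitude_threshold = amplitude_threshold,
                       alpha = alpha)
      .(b = f$b, t = f$t, x_c = f$x_c, s = f$s, rss = f$rss,
        rss_flat = f$rss_flat, f_p = f$f_p, verdict = f$verdict,
        direction = f$direction, demoted = f$demoted)
    } else NULL
  }, by = protein]
  setorder(fits, protein)
  fits[]
}

#' Assign a perturbation-response class to a fitted protein
#'
#' Persistent corona proteins fall into Class I (no abundance change),
#' Class II (sigmoid transition below the axis boundary: 30 degrees C or
#' pH 6.8) or Class III (transition above it), each with an `-up`/`-down`
#' suffix for the direction of abundance change with increasing condition.
#' A midpoint exactly on the boundary is assigned Class III (the boundary
#' is itself a design point; Class II is the strictly-below side).
#'
#' @param verdict `"sigmoid"` or `"flat"` (vectorised).
#' @param x_c Fitted critical condition values.
#' @param direction +1/-1 abundance direction.
#' @param boundary Class II/III boundary; see [class_boundary()].
#' @return Character vector of class labels (`"I"`, `"II-up"`, `"II-down"`,
#'   `"III-up"`, `"III-down"`).
#' @export
classify <- function(verdict, x_c, direction, boundary) {
  side <- ifelse(x_c < boundary, "II", "III")
  updown <- ifelse(direction > 0, "up", "down")
  ifelse(verdict == "sigmoid", paste0(side, "-", updown), "I")
}

#' Pairwise shared protein identities across conditions
#'
#' Counts, for every pair of conditions, the proteins present at both, plus
#' the number present at all conditions and its percentage of the union.
#'
#' @param presence Presence calls from [presence_calls()].
#' @return list with `pairwise` (symmetric condition x condition count
#'   matrix whose diagonal is the per-condition presence count), `n_all`,
#'   `n_union`, `pct_all` (percentage of the union present everywhere).
#' @export
shared_counts <- function(presence) {
  dt <- as.data.table(presence)
  dt[, protein := as.character(protein)]
  conds <- sort(unique(dt$condition))
  if (length(conds) < 2L) stop("presence calls for >= 2 conditions required")
  sets <- lapply(conds, function(cc) dt[condition == cc & present, protein])
  names(sets) <- as.character(conds)
  k <- length(conds)
  m <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  all_set <- Reduce(intersect, sets)
  union_set <- Reduce(union, sets)
  list(pairwise = m,
       n_all = length(all_set),
       n_union = length(union_set),
       pct_all = if (length(union_set)) 100 * length(all_set) / length(union_set)
                 else NA_real_)
}

#' Persistent (exchange-resistant) protein set
#'
#' @param presence Presence calls from [presence_calls()].
#' @return Sorted character vector of proteins present at every condition.
#' @export
persistent_set <- function(presence) {
  dt <- as.data.table(presence)
  dt[, protein := as.character(protein)]
  n_cond <- uniqueN(dt$condition)
  ids <- dt[present == TRUE, .(n = .N), by = protein][n == n_cond, protein]
  sort(ids)
}

#' Correlate critical condition values with a protein annotation
#'
#' Used to ask whether fitted critical temperatures track published
#' melting points, or critical pH values track isoelectric points.
#'
#' @param criticals Named numeric vector of per-protein critical values.
#' @param annotations Named numeric vector of the annotation (same ids).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p` (two-sided), `n` (pairs used).
#' @export
critical_correlation <- function(criticals, annotations,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- intersect(names(criticals), names(annotations))
  a <- criticals[ids]; b <- annotations[ids]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("at least 3 complete pairs are required")
  ct <- suppressWarnings(cor.test(a[ok], b[ok], method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
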