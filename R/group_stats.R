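#' Welch's unequal-variance two-sample t-test
#'
#' Computes t = (mean_a − mean_b) / sqrt(s²_a/n_a + s²_b/n_b), the
#' Welch–Satterthwaite degrees of freedom, and the two-sided p-value from
#' the t distribution. Implemented from the closed form (not a wrapper) so
#' the test suite can check it against an independent reference.
#'
#' @param sample_a,sample_b numeric vectors, each with at least 2 finite
#'   values.
#' @return list with `t_stat`, `dof`, `p_raw`.
#' @export
welch_t <- function(sample_a, sample_b) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (length(a) < 2 || length(b) < 2)
    ct_stop("ct_insufficient_data",
            "welch_t needs >= 2 finite values per sample")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se2 <- va + vb
  if (se2 <= 0) {
    # identical constant samples: no evidence of difference
    return(list(t_stat = 0, dof = length(a) + length(b) - 2, p_raw = 1))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  dof <- se2^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t_stat = t_stat, dof = dof,
       p_raw = 2 * stats::pt(-abs(t_stat), dof))
}

#' Holm–Šídák step-down adjustment
#'
#' Sorts the m raw p-values ascending, adjusts the i-th smallest as
#' 1 − (1 − p)^(m − i + 1), enforces monotonicity with a running maximum,
#' caps at 1, and maps the adjusted values back to the input order.
#'
#' @param p_values raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
holm_sidak <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    ct_stop("ct_domain_error", "p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Per-bin comparison of replicate profiles between two conditions
#'
#' The replicate unit is the plate: each condition contributes one profile
#' value per bin per plate, and each bin is compared with a Welch t-test on
#' those per-plate values. Holm–Šídák correction is applied across all
#' tested bins of the comparison (one profile comparison = one family).
#' Bins with fewer than 2 finite replicate values in either condition are
#' flagged untested and excluded from the correction family.
#'
#' @param profiles_a,profiles_b lists of `ct_profile` objects (≥ 2 each),
#'   all on an identical bin grid.
#' @param alpha significance level for the `significant` flag (adjusted
#'   p < alpha); default 0.05.
#' @return an object of class `ct_bin_comparison`: data.frame with
#'   `bin_left`, `bin_right`, `mean_a`, `mean_b`, `t_stat`, `dof`, `p_raw`,
#'   `p_adj`, `significant`, `tested`.
#' @export
compare_profiles <- function(profiles_a, profiles_b, alpha = 0.05) {
  stopifnot(is.list(profiles_a), length(profiles_a) >= 1,
            is.list(profiles_b), length(profiles_b) >= 1)
  as_matrix <- function(profiles, grid) {
    for (p in profiles) {
      stopifnot(inherits(p, "ct_profile"))
      if (nrow(p) != nrow(grid) ||
          any(abs(p$bin_left - grid$bin_left) > 1e-9))
        ct_stop("ct_grid_error", "profiles are not on a common bin grid")
    }
    do.call(cbind, lapply(profiles, `[[`, "value"))
  }
  grid <- profiles_a[[1]][c("bin_left", "bin_right")]
  A <- as_matrix(profiles_a, grid)
  B <- as_matrix(profiles_b, grid)
  nb <- nrow(grid)
  res <- data.frame(bin_left = grid$bin_left, bin_right = grid$bin_right,
                    mean_a = rowMeans(A, na.rm = TRUE),
                    mean_b = rowMeans(B, na.rm = TRUE),
                    t_stat = NA_real_, dof = NA_real_, p_raw = NA_real_,
                    p_adj = NA_real_, significant = FALSE, tested = FALSE)
  for (i in seq_len(nb)) {
    a <- A[i, ][is.finite(A[i, ])]
    b <- B[i, ][is.finite(B[i, ])]
    if (length(a) >= 2 && length(b) >= 2) {
      w <- welch_t(a, b)
      res$t_stat[i] <- w$t_stat
      res$dof[i] <- w$dof
      res$p_raw[i] <- w$p_raw
      res$tested[i] <- TRUE
    }
  }
  if (any(res$tested)) {
    res$p_adj[res$tested] <- holm_sidak(res$p_raw[res$tested])
    res$significant <- res$tested & !is.na(res$p_adj) & res$p_adj < alpha
  }
  attr(res, "alpha") <- alpha
  class(res) <- c("ct_bin_comparison", "data.frame")
  res
}

#' Write a per-bin comparison table as CSV
#' @param comparison a `ct_bin_comparison`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
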