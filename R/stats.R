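# Segmentation validation (Dice similarity) and two-group comparisons:
# Mann-Whitney U with rank-based effect size r for the composition metrics,
# pooled-variance Student's t for the Dice scores.

#' Dice similarity coefficient
#'
#' `DSC(A, G) = 2|A intersect G| / (|A| + |G|)` between an algorithm mask `A`
#' and a ground-truth mask `G`. Defined as 1.0 (with a message) when both
#' masks are empty: both raters agree there is no tissue.
#'
#' @param A,G Binary masks on the same grid.
#' @return Value in `[0, 1]`.
#' @export
dice <- function(A, G) {
  assert_same_dim(A, G, "masks")
  A <- as_mask(A); G <- as_mask(G)
  denom <- sum(A) + sum(G)
  if (denom == 0L) {
    message("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(A & G) / denom
}

#' Mann-Whitney U test with rank-based effect size
#'
#' U statistic with midrank tie handling. The two-sided p-value is computed
#' by exhaustive permutation enumeration when either group has fewer than 8
#' values (and the enumeration is tractable), and by the tie-corrected normal
#' approximation otherwise. The standardized statistic Z underlying the
#' effect size `r = |Z| / sqrt(n1 + n2)` is always taken from the
#' tie-corrected normal approximation, since r is defined through Z.
#'
#' @param group1,group2 Numeric vectors (each non-empty).
#' @return An object of class `group_comparison` with fields `statistic`
#'   (U of group 1), `p_value`, `Z`, `effect_size_r`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(group1, group2) {
  if (length(group1) < 1L || length(group2) < 1L)
    stopf("both groups must be non-empty")
  n1 <- length(group1); n2 <- length(group2); N <- n1 + n2
  pooled <- c(group1, group2)
  rk <- rank(pooled)  # midranks
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  # tie-corrected normal approximation (no continuity correction; Z also
  # feeds the effect size)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  Z <- if (sigma2 > 0) (U1 - mu) / sqrt(sigma2) else 0

  exact_feasible <- choose(N, n1) <= 5e5
  if ((n1 < 8L || n2 < 8L) && exact_feasible) {
    combs <- utils::combn(N, n1)
    base <- n1 * (n1 + 1) / 2
    Uperm <- colSums(matrix(rk[combs], nrow = n1)) - base
    p <- mean(abs(Uperm - mu) >= abs(U1 - mu) - 1e-9)
    method <- "exact permutation enumeration"
  } else {
    if (n1 < 8L || n2 < 8L)
      warnf("exact enumeration infeasible for n1=%d, n2=%d; using normal approximation",
            n1, n2)
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(Z)) else 1
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = U1, p_value = min(p, 1), Z = Z,
                 effect_size_r = abs(Z) / sqrt(N),
                 n1 = n1, n2 = n2, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), p = %.4g, r = %.3f [%s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$effect_size_r, x$method))
  invisible(x)
}

#' Rank-based effect size r
#'
#' `r = |Z| / sqrt(n1 + n2)`, bounded in `[0, 1]`, where Z is the
#' standardized Mann-Whitney statistic.
#'
#' @param comparison A `group_comparison` from [mann_whitney()].
#' @return Effect size in `[0, 1]`.
#' @export
effect_size_r <- function(comparison) {
  if (!inherits(comparison, "group_comparison"))
    stopf("'comparison' must come from mann_whitney()")
  abs(comparison$Z) / sqrt(comparison$n1 + comparison$n2)
}

#' Compare Dice scores between groups (Student's t)
#'
#' For each region x tissue cell of a Dice report, screens both groups for
#' normality (Shapiro-Wilk, recorded; a warning is emitted when either group
#' deviates at p <= 0.05) and applies a two-sided pooled-variance Student's
#' t-test, mirroring a per-region segmentation-performance table.
#'
#' @param report Data frame with columns `subject`, `group`, `region`,
#'   `tissue`, `dsc`.
#' @return Data frame with one row per region x tissue: group means, t, df,
#'   p-value and the Shapiro-Wilk p-values.
#' @export
compare_dsc_groups <- function(report) {
  needed <- c("group", "region", "tissue", "dsc")
  if (!all(needed %in% names(report)))
    stopf("report must have columns %s", paste(needed, collapse = ", "))
  if (any(report$dsc < 0 | report$dsc > 1)) stopf("dsc values must lie in [0, 1]")
  groups <- sort(unique(report$group))
  if (length(groups) != 2L) stopf("exactly two groups required")
  cells <- unique(report[, c("region", "tissue")])
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- report$region == cells$region[i] & report$tissue == cells$tissue[i]
    x <- report$dsc[sel & report$group == groups[1]]
    y <- report$dsc[sel & report$group == groups[2]]
    if (length(x) < 2L || length(y) < 2L)
      stopf("each group needs >= 2 subjects per region/tissue")
    sw <- function(v) if (length(unique(v)) > 2L && length(v) >= 3L)
      stats::shapiro.test(v)$p.value else NA_real_
    swx <- sw(x); swy <- sw(y)
    if (!is.na(swx) && swx <= 0.05 || !is.na(swy) && swy <= 0.05)
      warnf("%s/%s: Dice scores deviate from normality (Shapiro-Wilk p <= 0.05)",
            cells$region[i], cells$tissue[i])
    tt <- if (stats::var(x) + stats::var(y) == 0) {
      list(statistic = 0, parameter = length(x) + length(y) - 2, p.value = 1)
    } else {
      stats::t.test(x, y, var.equal = TRUE)
    }
    data.frame(region = cells$region[i], tissue = cells$tissue[i],
               mean_1 = mean(x), mean_2 = mean(y),
               n1 = length(x), n2 = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               shapiro_p_1 = swx, shapiro_p_2 = swy)
  }))
}

#' Dice report for a segmented phantom
#'
#' Computes SAT and muscle Dice coefficients against phantom ground truth on
#' the representative calf (decade-3 middle) and thigh (decade-7 middle)
#' slices.
#'
#' @param masks_list Output of [segment_volume()].
#' @param truth A `phantom_truth`.
#' @return Data frame with columns `region`, `tissue`, `slice`, `dsc`.
#' @export
phantom_dsc_report <- function(masks_list, truth) {
  nz <- length(masks_list)
  slices <- c(calf = decade_middle_slice(nz, 3L), thigh = decade_middle_slice(nz, 7L))
  do.call(rbind, lapply(names(slices), function(region) {
    z <- slices[[region]]
    m <- masks_list[[z]]
    data.frame(region = region, tissue = c("sat", "muscle"), slice = z,
               dsc = c(dice(m$sat, truth$sat[, , z]),
                       dice(m$muscle_final, truth$muscle[, , z])))
  }))
}
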