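# Nonparametric statistics: Kruskal-Wallis with small-sample permutation
# critical values, and Wilcoxon signed-rank with Bonferroni correction.

# Tie-corrected Kruskal-Wallis H from pooled values and a group factor;
# fast kernel used inside the permutation loop (the reported statistic
# comes from stats::kruskal.test, which this kernel matches).
kw_h <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  rs <- tapply(r, g, sum)
  ns <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h / corr else 0
}

#' Kruskal-Wallis test with the joint H / H-critical decision rule
#'
#' Rank-based comparison of two or more independent groups. The tie-corrected
#' H statistic and the chi-square p-value come from [stats::kruskal.test()].
#' When every group is small (all sizes at or below `exact_max_n`), the null
#' distribution of H is additionally obtained by permutation of the group
#' labels (full enumeration for two groups when feasible, otherwise seeded
#' Monte Carlo), giving a small-sample p-value and the critical value of H at
#' the requested alpha. Significance requires both `p < alpha` and
#' `H > H_critical`.
#'
#' @param groups List of numeric vectors, one per group (>= 2 nonempty
#'   groups).
#' @param alpha Significance level for the critical value (default 0.05).
#' @param exact_max_n Largest group size for which the permutation path is
#'   used; larger samples use the chi-square approximation for both p and
#'   H-critical.
#' @param n_perm Monte Carlo permutations when enumeration is infeasible.
#' @param seed Seed for the Monte Carlo permutations.
#' @return Object of class `stat_result`: `statistic` (H), `p_value` (the
#'   p-value used for the decision), `p_chisq`, `critical_value`,
#'   `n_per_group`, `significant`, `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # 3.857
#' @export
kruskal_wallis <- function(groups, alpha = 0.05, exact_max_n = 8,
                           n_perm = 20000, seed = 1) {
  if (length(groups) < 2 || any(vapply(groups, length, integer(1)) == 0)) {
    stop("need >= 2 nonempty groups", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  ns <- vapply(groups, length, integer(1))
  g <- factor(rep(seq_along(groups), ns))
  n <- length(x)
  df <- length(groups) - 1

  if (length(unique(x)) == 1) {
    out <- list(method = "kruskal_wallis (degenerate: constant data)",
                statistic = 0, p_value = 1, p_chisq = 1,
                critical_value = stats::qchisq(1 - alpha, df),
                n_per_group = ns, alpha = alpha, significant = FALSE)
    class(out) <- "stat_result"
    return(out)
  }

  kt <- stats::kruskal.test(x, g)
  h_obs <- unname(kt$statistic)
  p_chisq <- kt$p.value

  small <- all(ns <= exact_max_n)
  if (small) {
    enum <- length(groups) == 2 && choose(n, ns[1]) <= 100000
    if (enum) {
      combos <- utils::combn(n, ns[1])
      h_null <- apply(combos, 2, function(idx) {
        gi <- integer(n)
        gi[idx] <- 1L
        kw_h(x, factor(gi))
      })
      method <- "kruskal_wallis (exact permutation)"
    } else {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
      set.seed(derive_seed(seed, 13, n, length(groups)))
      h_null <- vapply(seq_len(n_perm), function(i) {
        kw_h(x, g[sample.int(n)])
      }, numeric(1))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      method <- "kruskal_wallis (Monte Carlo permutation)"
    }
    eps <- 1e-10
    p_value <- if (enum) mean(h_null >= h_obs - eps) else
      (1 + sum(h_null >= h_obs - eps)) / (1 + length(h_null))
    # smallest achievable H whose upper-tail probability is <= alpha
    hs <- sort(unique(round(h_null, 10)))
    tail_p <- vapply(hs, function(h) mean(h_null >= h - eps), numeric(1))
    ok <- which(tail_p <= alpha)
    critical <- if (length(ok)) hs[min(ok)] else Inf
  } else {
    p_value <- p_chisq
    critical <- stats::qchisq(1 - alpha, df)
    method <- "kruskal_wallis (chi-square approximation)"
  }

  out <- list(method = method, statistic = h_obs, p_value = p_value,
              p_chisq = p_chisq, critical_value = unname(critical),
              n_per_group = ns, alpha = alpha,
              significant = p_value < alpha && h_obs > critical)
  class(out) <- "stat_result"
  out
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Two-sided signed-rank test on the paired differences (zero differences
#' dropped, tied ranks mid-ranked, exact p for small samples without ties),
#' with the Bonferroni-adjusted p-value `min(1, m * p)` for a family of `m`
#' tests. When every difference is zero the statistic is undefined; the
#' result is flagged degenerate and reported as not significant.
#'
#' @param paired_a,paired_b Equal-length paired samples.
#' @param m Bonferroni family size (>= 1, default 6).
#' @param alpha Significance level applied to the adjusted p.
#' @return Object of class `stat_result` with `statistic` (V), `p_value`
#'   (raw), `p_adjusted`, `n` (pairs used after dropping zeros),
#'   `significant`, `degenerate`.
#' @export
wilcoxon_bonferroni <- function(paired_a, paired_b, m = 6, alpha = 0.05) {
  if (length(paired_a) != length(paired_b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (m < 1) stop("family size m must be >= 1", call. = FALSE)
  d <- as.numeric(paired_a) - as.numeric(paired_b)
  nz <- d[d != 0]
  if (length(nz) == 0) {
    out <- list(method = "wilcoxon_signed_rank (degenerate: all zero)",
                statistic = NA_real_, p_value = 1, p_adjusted = 1,
                n = 0L, m = m, alpha = alpha, significant = FALSE,
                degenerate = TRUE)
    class(out) <- "stat_result"
    return(out)
  }
  wt <- suppressWarnings(stats::wilcox.test(paired_a, paired_b,
                                            paired = TRUE,
                                            alternative = "two.sided"))
  p <- wt$p.value
  out <- list(method = "wilcoxon_signed_rank (two-sided, Bonferroni)",
              statistic = unname(wt$statistic), p_value = p,
              p_adjusted = min(1, m * p), n = length(nz), m = m,
              alpha = alpha, significant = min(1, m * p) < alpha,
              degenerate = FALSE)
  class(out) <- "stat_result"
  out
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic:", format(x$statistic, digits = 4),
      " p:", format(x$p_value, digits = 4))
  if (!is.null(x$p_adjusted)) {
    cat("  adjusted p:", format(x$p_adjusted, digits = 4),
        "(m =", x$m, ")")
  }
  if (!is.null(x$critical_value)) {
    cat("  critical:", format(x$critical_value, digits = 4))
  }
  cat("\n  significant:", x$significant, "\n")
  invisible(x)
}
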