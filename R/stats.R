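# Group-comparison report: normality-gated test selection per measure
# (Lilliefors/Kolmogorov-Smirnov normality; ANOVA with Welch fallback or
# Kruskal-Wallis / Mann-Whitney), Bonferroni-corrected pairwise tests.

#' Group-comparison statistics for a cohort table
#'
#' For every requested measure: each group's distribution is checked for
#' normality with the Lilliefors-corrected Kolmogorov-Smirnov test (exact
#' Shapiro-Wilk for very small groups).  Normal measures are compared
#' with one-way ANOVA (the Welch variant when a Bartlett test rejects
#' equal variances) and Bonferroni-corrected pairwise t tests; non-normal
#' measures with the Kruskal-Wallis H test (three or more groups) or the
#' Mann-Whitney U test (two groups), with Bonferroni-corrected pairwise
#' Wilcoxon tests.  Significance level 0.05 throughout; p values are
#' reported to three decimals.
#'
#' @param cohort Subject-level tibble.
#' @param measures Character vector of measure columns to compare.
#' @param group Name of the grouping column (default `"group"`).
#' @param alpha Significance level used for the normality and variance
#'   gates.
#' @return A tibble with one row per measure: per-group `mean_*` and
#'   `sd_*` columns, the test used, its statistic and p value, and one
#'   Bonferroni-adjusted p value column per group pair.  Measures with a
#'   group of fewer than 2 observations are skipped with a warning.
#' @examples
#' coh <- dplyr::bind_rows(gen_scores("control", n = 20, seed = 1),
#'                         gen_scores("dp140_neg", n = 20, seed = 2))
#' stats_report(coh, c("dsf", "dsb"))
#' @export
stats_report <- function(cohort, measures, group = "group", alpha = 0.05) {
  stopifnot(group %in% names(cohort))
  g <- factor(cohort[[group]])
  if (nlevels(g) < 2) stop("at least 2 groups are required", call. = FALSE)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)

  rows <- purrr::map(measures, function(m) {
    if (!m %in% names(cohort)) {
      warning("measure not found, skipped: ", m, call. = FALSE)
      return(NULL)
    }
    x <- cohort[[m]]
    keep <- !is.na(x)
    xs <- split(x[keep], g[keep])
    if (any(vapply(xs, length, integer(1)) < 2)) {
      warning("group with < 2 observations, measure skipped: ", m,
              call. = FALSE)
      return(NULL)
    }
    normal <- all(vapply(xs, function(v) {
      if (stats::sd(v) == 0) return(FALSE) # degenerate: no normality claim
      p <- if (length(v) >= 5) nortest::lillie.test(v)$p.value
           else stats::shapiro.test(v)$p.value
      p > alpha
    }, logical(1)))

    desc <- purrr::imap(xs, function(v, nm) {
      stats::setNames(c(mean(v), stats::sd(v)),
                      paste0(c("mean_", "sd_"), nm))
    })
    desc <- unlist(unname(desc))

    if (normal) {
      var_equal <- tryCatch(stats::bartlett.test(x[keep], g[keep])$p.value >= alpha,
                            error = function(e) TRUE)
      if (nlevels(droplevels(g[keep])) > 2) {
        om <- stats::oneway.test(x[keep] ~ g[keep], var.equal = var_equal)
        test <- if (var_equal) "anova" else "welch_anova"
      } else {
        om <- stats::t.test(x[keep] ~ g[keep], var.equal = var_equal)
        test <- if (var_equal) "t" else "welch_t"
      }
      pw <- stats::pairwise.t.test(x[keep], g[keep],
                                   p.adjust.method = "bonferroni",
                                   pool.sd = var_equal)$p.value
    } else {
      if (nlevels(droplevels(g[keep])) > 2) {
        om <- stats::kruskal.test(x[keep], g[keep])
        test <- "kruskal_wallis"
      } else {
        om <- stats::wilcox.test(x[keep] ~ g[keep], exact = FALSE)
        test <- "mann_whitney"
      }
      pw <- stats::pairwise.wilcox.test(x[keep], g[keep],
                                        p.adjust.method = "bonferroni",
                                        exact = FALSE)$p.value
    }
    look <- function(r, c) {
      if (r %in% rownames(pw) && c %in% colnames(pw)) pw[r, c] else NA_real_
    }
    pair_p <- vapply(pairs, function(pr) {
      v <- c(look(pr[2], pr[1]), look(pr[1], pr[2]))
      v <- v[!is.na(v)]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    names(pair_p) <- vapply(pairs, function(pr) {
      paste0("p_", pr[1], "_vs_", pr[2])
    }, character(1))

    dplyr::bind_cols(
      tibble::tibble(measure = m),
      tibble::as_tibble(as.list(desc)),
      tibble::tibble(test = test,
                     statistic = unname(om$statistic),
                     p_value = round(om$p.value, 3)),
      tibble::as_tibble(as.list(round(pair_p, 3)))
    )
  })
  dplyr::bind_rows(rows)
}
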