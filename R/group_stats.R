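#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (a thin, validating
#' wrapper around `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    qs_stop("p-values must lie in [0, 1]", "quartersleep_format_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Age-adjusted per-feature group screening
#'
#' For every feature, fits the linear model `feature ~ age + group` and
#' tests the group term (F test with age entered first, i.e. ANOVA
#' controlling for age), adjusts the p-values across features by
#' Benjamini-Hochberg, and computes Tukey pairwise comparisons of the
#' age-adjusted group means (via estimated marginal means).  This
#' screening is deliberately independent of the classification framework.
#'
#' Features that are constant (or missing in all but one group) have an
#' undefined F statistic; they are flagged `excluded` and do not enter the
#' FDR family.
#'
#' @param table A feature table as built by [cohort_feature_table()], with
#'   `group` and `age` columns.
#' @param features Feature columns to test (default: all feature columns).
#' @param tukey Compute Tukey pairwise contrasts (default `TRUE`).
#' @param alpha Significance level recorded in the output (default 0.05).
#' @return List of class `"qs_group_stats"` with `stats` (data frame:
#'   `feature`, `F`, `p`, `p_adj`, `significant`, `excluded`) and `tukey`
#'   (long data frame of pairwise contrasts: `feature`, `contrast`,
#'   `estimate`, `lower`, `upper`, `p_tukey`).
#' @export
ancova_by_feature <- function(table, features = feature_cols(table),
                              tukey = TRUE, alpha = 0.05) {
  stopifnot(all(c("group", "age") %in% names(table)))
  grp <- factor(table$group)
  if (nlevels(grp) < 2 || any(table(grp) < 2)) {
    qs_stop("need at least 2 groups with at least 2 subjects each",
            "quartersleep_format_error")
  }
  age <- table$age
  stats_rows <- vector("list", length(features))
  tukey_rows <- list()
  for (i in seq_along(features)) {
    f <- features[i]
    y <- table[[f]]
    ok <- !is.na(y)
    excluded <- length(unique(y[ok])) < 2 ||
      length(unique(grp[ok])) < nlevels(grp)
    Fv <- pv <- NA_real_
    if (!excluded) {
      d <- data.frame(y = y[ok], age = age[ok], group = droplevels(grp[ok]))
      fit <- stats::lm(y ~ age + group, data = d)
      an <- stats::anova(fit)
      Fv <- an["group", "F value"]
      pv <- an["group", "Pr(>F)"]
      if (is.na(Fv)) excluded <- TRUE
      if (tukey && !excluded) {
        emm <- emmeans::emmeans(fit, "group")
        prs <- summary(emmeans::contrast(emm, "pairwise", adjust = "tukey"),
                       infer = TRUE)
        tukey_rows[[length(tukey_rows) + 1L]] <- data.frame(
          feature = f, contrast = as.character(prs$contrast),
          estimate = prs$estimate, lower = prs$lower.CL,
          upper = prs$upper.CL, p_tukey = prs$p.value)
      }
    }
    stats_rows[[i]] <- data.frame(feature = f, F = Fv, p = pv,
                                  excluded = excluded)
  }
  st <- do.call(rbind, stats_rows)
  st$p_adj <- NA_real_
  st$p_adj[!st$excluded] <- bh_adjust(st$p[!st$excluded])
  st$significant <- !is.na(st$p_adj) & st$p_adj < alpha
  structure(list(stats = st[, c("feature", "F", "p", "p_adj",
                                "significant", "excluded")],
                 tukey = if (length(tukey_rows)) do.call(rbind, tukey_rows)
                         else NULL,
                 alpha = alpha),
            class = "qs_group_stats")
}

#' @export
print.qs_group_stats <- function(x, ...) {
  n_sig <- sum(x$stats$significant, na.rm = TRUE)
  cat(sprintf("<qs_group_stats> %d features tested, %d FDR-significant at alpha = %g\n",
              sum(!x$stats$excluded), n_sig, x$alpha))
  invisible(x)
}
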