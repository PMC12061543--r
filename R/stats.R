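GROUP_PAIRS <- list(c("control", "NoDR"), c("control", "mild"),
                    c("NoDR", "mild"))

significance_tier <- function(p) {
  if (is.na(p)) NA_character_
  else if (p < 0.001) "p<0.001"
  else if (p < 0.017) "p<0.017"
  else if (p < 0.05) "p<0.05"
  else "none"
}

#' Pairwise Mann-Whitney U comparisons of CFZ biomarkers
#'
#' For every biomarker x region x group pair, runs a two-sided
#' Mann-Whitney U (Wilcoxon rank-sum) test between the two groups.
#' Significance tiers follow the usual three-group convention: p<0.05
#' (uncorrected), p<0.017 (Bonferroni 0.05/3 for the three pairwise
#' comparisons) and p<0.001. The exact null distribution is used for
#' small tie-free samples (both groups <= 8 observations); otherwise the
#' normal approximation with continuity correction. Missing feature
#' values are dropped per comparison.
#'
#' @param table feature table as produced by [cohort_feature_table()] /
#'   read back from [write_feature_table()] output.
#' @param features biomarker columns to compare.
#' @param exact_max use the exact U distribution when both group sizes
#'   are at most this (and there are no ties).
#' @return A `data.frame` with one row per comparison: `feature`,
#'   `region`, `group1`, `group2`, `n1`, `n2`, `U`, `p`, `tier`, and
#'   per-group `median1/2`, `mean1/2`, `iqr1/2`.
#' @export
mann_whitney_pairwise <- function(table, features = FEATURE_COLUMNS,
                                  exact_max = 8) {
  out <- NULL
  for (rg in unique(table$region)) {
    sub <- table[table$region == rg, , drop = FALSE]
    for (ft in features) {
      for (pair in GROUP_PAIRS) {
        x <- sub[[ft]][sub$group == pair[1]]
        y <- sub[[ft]][sub$group == pair[2]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) {
          warning(sprintf("skipping %s/%s %s vs %s: fewer than 2 observations",
                          ft, rg, pair[1], pair[2]), call. = FALSE)
          next
        }
        use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
          !anyDuplicated(c(x, y))
        ht <- suppressWarnings(
          wilcox.test(x, y, exact = use_exact, correct = TRUE))
        out <- rbind(out, data.frame(
          feature = ft, region = rg, group1 = pair[1], group2 = pair[2],
          n1 = length(x), n2 = length(y),
          U = unname(ht$statistic), p = ht$p.value,
          tier = significance_tier(ht$p.value),
          median1 = median(x), median2 = median(y),
          mean1 = mean(x), mean2 = mean(y),
          iqr1 = unname(diff(quantile(x, c(0.25, 0.75)))),
          iqr2 = unname(diff(quantile(y, c(0.25, 0.75)))),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(feature = character(0), region = character(0),
                      group1 = character(0), group2 = character(0),
                      n1 = integer(0), n2 = integer(0), U = numeric(0),
                      p = numeric(0), tier = character(0),
                      median1 = numeric(0), median2 = numeric(0),
                      mean1 = numeric(0), mean2 = numeric(0),
                      iqr1 = numeric(0), iqr2 = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cohort covariate balance checks
#'
#' Chi-squared homogeneity tests across groups for categorical
#' covariates, and Shapiro-Wilk normality (per group) plus one-way ANOVA
#' for continuous covariates. Shapiro-Wilk is skipped with a warning for
#' groups of fewer than 3 observations.
#'
#' @param metadata data.frame with a `group` column and covariate
#'   columns.
#' @param categorical,continuous names of covariate columns; columns
#'   absent from `metadata` are reported as missing rather than failing.
#' @return `list(categorical, continuous, shapiro, missing)` of result
#'   data.frames.
#' @export
cohort_checks <- function(metadata, categorical = "sex", continuous = "age") {
  missing_cols <- setdiff(c(categorical, continuous), names(metadata))
  categorical <- intersect(categorical, names(metadata))
  continuous <- intersect(continuous, names(metadata))
  cat_res <- NULL
  for (cv in categorical) {
    tab <- table(metadata$group, metadata[[cv]])
    ht <- suppressWarnings(chisq.test(tab))
    cat_res <- rbind(cat_res, data.frame(
      covariate = cv, statistic = unname(ht$statistic),
      df = unname(ht$parameter), p = ht$p.value, stringsAsFactors = FALSE))
  }
  cont_res <- NULL; sw_res <- NULL
  for (cv in continuous) {
    fit <- aov(metadata[[cv]] ~ factor(metadata$group))
    an <- summary(fit)[[1]]
    cont_res <- rbind(cont_res, data.frame(
      covariate = cv, F = an[["F value"]][1], df1 = an[["Df"]][1],
      df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1], stringsAsFactors = FALSE))
    for (grp in unique(metadata$group)) {
      v <- metadata[[cv]][metadata$group == grp]
      v <- v[!is.na(v)]
      if (length(v) < 3) {
        warning(sprintf("Shapiro-Wilk skipped for %s in group %s (n < 3)",
                        cv, grp), call. = FALSE)
        sw_res <- rbind(sw_res, data.frame(covariate = cv, group = grp,
                                           W = NA_real_, p = NA_real_,
                                           n = length(v),
                                           stringsAsFactors = FALSE))
      } else {
        ht <- shapiro.test(v)
        sw_res <- rbind(sw_res, data.frame(covariate = cv, group = grp,
                                           W = unname(ht$statistic),
                                           p = ht$p.value, n = length(v),
                                           stringsAsFactors = FALSE))
      }
    }
  }
  list(categorical = cat_res, continuous = cont_res, shapiro = sw_res,
       missing = missing_cols)
}

#' Per-group distribution summaries for boxplot-style reporting
#'
#' Median, mean and interquartile range (Q3 - Q1, linear-interpolation
#' type-7 quantiles) of every biomarker per group and region.
#'
#' @param table feature table (see [mann_whitney_pairwise()]).
#' @param features biomarker columns to summarise.
#' @return A `data.frame` with columns `feature`, `region`, `group`,
#'   `n`, `median`, `mean`, `iqr`, `q1`, `q3`.
#' @export
boxplot_summaries <- function(table, features = FEATURE_COLUMNS) {
  out <- NULL
  for (rg in unique(table$region)) {
    sub <- table[table$region == rg, , drop = FALSE]
    for (ft in features) {
      for (grp in unique(sub$group)) {
        v <- sub[[ft]][sub$group == grp]
        v <- v[!is.na(v)]
        qs <- if (length(v)) quantile(v, c(0.25, 0.5, 0.75), type = 7)
              else rep(NA_real_, 3)
        out <- rbind(out, data.frame(
          feature = ft, region = rg, group = grp, n = length(v),
          median = unname(qs[2]), mean = if (length(v)) mean(v) else NA_real_,
          iqr = unname(qs[3] - qs[1]), q1 = unname(qs[1]), q3 = unname(qs[3]),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
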