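fake_table <- function(values_by_group, feature = "Mt", region = "whole") {
  do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    df <- data.frame(subject_id = sprintf("%s%02d", g, seq_along(v)),
                     laterality = "OD", group = g, region = region,
                     stringsAsFactors = FALSE)
    for (ft in c("Ra", "Rv", "Rt", "Na", "Nv", "Nt", "Ma", "Mv", "Mt"))
      df[[ft]] <- NA_real_
    df[[feature]] <- v
    df
  }))
}

test_that("identical groups give p = 1 and tier none", {
  tab <- fake_table(list(control = c(1, 2, 3), NoDR = c(1, 2, 3)))
  res <- mann_whitney_pairwise(tab, features = "Mt")
  row <- res[res$group1 == "control" & res$group2 == "NoDR", ]
  expect_equal(row$p, 1)
  expect_equal(row$tier, "none")
})

test_that("complete separation gives the exact enumeration tail", {
  tab <- fake_table(list(control = c(1, 2, 3), mild = c(101, 102, 103)))
  res <- mann_whitney_pairwise(tab, features = "Mt")
  row <- res[res$group2 == "mild", ]
  expect_true(row$U %in% c(0, 9))
  expect_equal(row$p, 2 / choose(6, 3) * 1, tolerance = 1e-12)  # 0.1
  expect_equal(row$tier, "none")
})

test_that("U and exact p agree with full enumeration for small groups", {
  set.seed(8)
  for (rep in 1:10) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    x <- round(runif(m), 6); y <- round(runif(n) + 0.2, 6)
    tab <- fake_table(list(control = x, NoDR = y))
    res <- mann_whitney_pairwise(tab, features = "Mt")
    row <- res[res$group2 == "NoDR", ]
    ora <- oracle_u_exact(x, y)
    expect_equal(row$U, ora$U)
    expect_equal(row$p, ora$p, tolerance = 1e-12)
  }
})

test_that("significance tiers are nested and monotone in p", {
  tiers <- vapply(c(0.2, 0.04, 0.016, 0.0009), cfzquant:::significance_tier, "")
  expect_equal(tiers, c("none", "p<0.05", "p<0.017", "p<0.001"))
  # nesting: a p below a tighter threshold is below all looser ones
  expect_true(0.0009 < 0.017 && 0.0009 < 0.05)
})

test_that("missing values are dropped and tiny groups skipped with warning", {
  tab <- fake_table(list(control = c(1, 2, NA, 4), NoDR = c(5, 6, 7, NA)))
  res <- mann_whitney_pairwise(tab, features = "Mt")
  row <- res[res$group2 == "NoDR", ]
  expect_equal(row$n1, 3); expect_equal(row$n2, 3)
  tab1 <- fake_table(list(control = c(1, 2, 3), NoDR = 5))
  expect_warning(res1 <- mann_whitney_pairwise(tab1, features = "Mt"),
                 "fewer than 2")
  expect_equal(nrow(res1), 0)
})

test_that("covariate checks run chi-squared, ANOVA and Shapiro-Wilk", {
  md <- data.frame(
    group = rep(c("control", "NoDR", "mild"), each = 20),
    sex = rep(rep(c("M", "F"), each = 10), 3),
    age = c(rnorm(20, 50, 5), rnorm(20, 50, 5), rnorm(20, 60, 5)))
  set.seed(2)
  md$age <- c(50 + rnorm(20), 50 + rnorm(20), 60 + rnorm(20))
  res <- cohort_checks(md)
  # identical sex split in every group: chi-squared p == 1
  expect_equal(res$categorical$p, 1, tolerance = 1e-9)
  # +10 year shift: ANOVA p tiny, F matches the closed form
  expect_lt(res$continuous$p, 1e-6)
  grand <- mean(md$age)
  gm <- tapply(md$age, md$group, mean)
  ssb <- sum(20 * (gm - grand)^2)
  ssw <- sum((md$age - gm[md$group])^2)
  f_manual <- (ssb / 2) / (ssw / 57)
  expect_equal(res$continuous$F, f_manual, tolerance = 1e-9)
  expect_equal(nrow(res$shapiro), 3)

  # n < 3 group: Shapiro-Wilk skipped with warning
  md_small <- data.frame(group = c("control", "control", "mild"),
                         age = c(50, 51, 60))
  expect_warning(res2 <- cohort_checks(md_small, categorical = character(0)),
                 "skipped")
  expect_true(any(is.na(res2$shapiro$W)))
  # absent columns are reported, not fatal
  res3 <- suppressWarnings(cohort_checks(md_small, categorical = "sex"))
  expect_equal(res3$missing, "sex")
})

test_that("boxplot summaries use type-7 quantiles", {
  tab <- fake_table(list(control = c(1, 2, 3, 4, 5)))
  s <- boxplot_summaries(tab, features = "Mt")
  expect_equal(s$median, 3); expect_equal(s$mean, 3); expect_equal(s$iqr, 2)
  tab2 <- fake_table(list(control = rep(7, 6)))
  expect_equal(boxplot_summaries(tab2, features = "Mt")$iqr, 0)
  set.seed(31)
  v <- runif(23)
  tab3 <- fake_table(list(control = v))
  s3 <- boxplot_summaries(tab3, features = "Mt")
  sv <- sort(v)
  q_manual <- function(p) {
    h <- (length(sv) - 1) * p
    lo <- floor(h)
    sv[lo + 1] + (h - lo) * (sv[pmin(lo + 2, length(sv))] - sv[lo + 1])
  }
  expect_equal(s3$median, q_manual(0.5), tolerance = 1e-12)
  expect_equal(s3$iqr, q_manual(0.75) - q_manual(0.25), tolerance = 1e-12)
})
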