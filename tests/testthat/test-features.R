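test_that("class areas are exact pixel counts", {
  blank <- label_map(matrix(0L, 16, 16))
  expect_equal(class_area(blank, 1), 0)
  expect_equal(class_area(label_map(matrix(3L, 64, 64)), 3), 4096)
  expect_error(class_area(blank, 7), "0:4")
  m <- random_label_map(20, 20, seed = 2)
  for (k in 0:4) {
    count <- 0
    for (v in as.integer(unclass(m))) if (v == k) count <- count + 1
    expect_equal(class_area(m, k), count)
  }
})

test_that("CFZ ratios follow the area quotients with NA for empty denominators", {
  build <- function(a1, a2, a3, a4) {
    m <- matrix(0L, 32, 32)
    v <- c(rep(1L, a1), rep(2L, a2), rep(3L, a3), rep(4L, a4))
    m[seq_along(v)] <- v
    label_map(m)
  }
  r <- cfz_ratios(build(10, 8, 5, 4))
  expect_equal(unname(r["Ra"]), 0.5)
  r2 <- cfz_ratios(build(100, 50, 30, 20))
  expect_equal(unname(r2["Rt"]), 1 / 3)
  expect_equal(unname(r2["Ra"]), 0.3)
  expect_equal(unname(r2["Rv"]), 0.4)
  # vessels but no CFZ: true zeros
  expect_equal(unname(cfz_ratios(build(10, 10, 0, 0))), c(0, 0, 0))
  # empty denominator is missing, not zero
  r3 <- cfz_ratios(build(0, 10, 5, 4))
  expect_true(is.na(r3["Ra"]))
  expect_false(is.na(r3["Rv"]))
})

test_that("components of two pixels or fewer are excluded", {
  m <- matrix(0L, 12, 24)
  m[2, 2] <- 3L                 # size 1
  m[4, 2:3] <- 3L               # size 2
  m[6, 2:4] <- 3L               # size 3
  m[8, 2:5] <- 3L               # size 4
  lm <- label_map(m)
  cs <- cfz_components(lm, "paCFZ")
  expect_equal(sort(cs$areas), c(3L, 4L))
  cm <- cfz_counts_and_means(lm)
  expect_equal(unname(cm["Na"]), 2)
  expect_equal(unname(cm["Ma"]), 3.5)
  # all-speck map yields zero counts and missing means
  specks <- matrix(0L, 10, 10)
  specks[1, 1] <- 3L; specks[5, 5:6] <- 4L
  cm0 <- cfz_counts_and_means(label_map(specks))
  expect_equal(unname(cm0[c("Na", "Nv", "Nt")]), c(0, 0, 0))
  expect_true(all(is.na(cm0[c("Ma", "Mv", "Mt")])))
})

test_that("total-CFZ components use the union mask", {
  m <- matrix(0L, 20, 20)
  m[2, 2:5] <- 3L               # paCFZ, 4 px
  m[6, 2:7] <- 3L               # paCFZ, 6 px
  m[12, 2:11] <- 4L             # pvCFZ, 10 px
  cm <- cfz_counts_and_means(label_map(m))
  expect_equal(unname(cm[c("Na", "Nv", "Nt")]), c(2, 1, 3))
  expect_equal(unname(cm["Ma"]), 5)
  expect_equal(unname(cm["Mt"]), 20 / 3)
  # touching periarterial and perivenous components merge in the union
  m2 <- matrix(0L, 10, 10)
  m2[4, 2:4] <- 3L; m2[4, 5:7] <- 4L
  cm2 <- cfz_counts_and_means(label_map(m2))
  expect_equal(unname(cm2[c("Na", "Nv", "Nt")]), c(1, 1, 1))
  expect_equal(unname(cm2["Mt"]), 6)
})

test_that("all nine biomarkers match the enumeration + flood-fill oracle", {
  for (seed in 1:40) {
    m <- random_label_map(64, 64, seed)
    got <- cfz_features(m)
    expect_equal(got, oracle_features(m), tolerance = 1e-12)
  }
})

test_that("nasal/temporal hemifields follow laterality and configuration", {
  expect_equal(hemifield_columns(10, "OD")$nasal, 6:10)
  expect_equal(hemifield_columns(10, "OS")$nasal, 1:5)
  expect_equal(hemifield_columns(10, "OD", "left")$nasal, 1:5)
  # odd width: left half gets floor(width/2) columns
  hc <- hemifield_columns(11, "OS")
  expect_equal(hc$nasal, 1:5)
  expect_equal(hc$temporal, 6:11)
})

test_that("regional features crop, re-label and swap with laterality", {
  m <- matrix(0L, 24, 24)
  m[3, 1:24] <- 1L; m[20, 1:24] <- 2L      # vessels span both halves
  m[5, 2:6] <- 3L; m[17, 3:8] <- 4L        # CFZ only in the left half
  lm <- label_map(m)
  md_od <- eye_metadata("s1", "OD", "control")
  rf <- regional_features(lm, md_od, nasal_side_for_OD = "left")
  nasal <- rf[rf$region == "nasal", ]
  temporal <- rf[rf$region == "temporal", ]
  expect_gt(nasal$Nt, 0)
  expect_equal(temporal$Nt, 0)
  expect_equal(temporal$Ra, 0)

  # symmetric map: nasal and temporal agree
  sym <- matrix(0L, 16, 16)
  sym[2, ] <- 1L; sym[14, ] <- 2L
  sym[4, c(2:5, 12:15)] <- 3L; sym[12, c(2:5, 12:15)] <- 4L
  rs <- regional_features(label_map(sym), md_od)
  feats <- c("Ra", "Rv", "Rt", "Na", "Nv", "Nt", "Ma", "Mv", "Mt")
  expect_equal(rs[rs$region == "nasal", feats],
               rs[rs$region == "temporal", feats], ignore_attr = TRUE)

  # OD vs OS swaps the hemifield feature sets
  md_os <- eye_metadata("s1", "OS", "control")
  r_od <- regional_features(lm, md_od)
  r_os <- regional_features(lm, md_os)
  expect_equal(r_od[r_od$region == "nasal", feats],
               r_os[r_os$region == "temporal", feats], ignore_attr = TRUE)
  expect_equal(r_od[r_od$region == "temporal", feats],
               r_os[r_os$region == "nasal", feats], ignore_attr = TRUE)
})

test_that("hemifield class areas sum to the whole-image areas", {
  for (seed in 11:15) {
    m <- random_label_map(30, 31, seed)
    md <- eye_metadata("x", "OD", "NoDR")
    halves <- hemifield_columns(31, "OD")
    for (k in 0:4) {
      whole <- class_area(m, k)
      nas <- sum(unclass(m)[, halves$nasal] == k)
      tem <- sum(unclass(m)[, halves$temporal] == k)
      expect_equal(nas + tem, whole)
    }
  }
})

test_that("adding CFZ pixels never decreases the total CFZ ratio", {
  set.seed(99)
  m <- random_label_map(32, 32, seed = 99)
  rt <- cfz_ratios(m)["Rt"]
  for (rep in 1:25) {
    bg <- which(unclass(m) == 0L)
    if (!length(bg)) break
    m[sample(bg, 1)] <- sample(3:4, 1)
    m <- label_map(unclass(m))
    rt_new <- cfz_ratios(m)["Rt"]
    expect_gte(rt_new, rt)
    rt <- rt_new
  }
})
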