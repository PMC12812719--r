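test_that("classification follows the ADA cutoffs", {
  cases <- list(
    list(99, 139, 5.6, FALSE, "NGT"),
    list(100, 120, 5.4, FALSE, "PREDM"),
    list(110, 210, 6.0, FALSE, "DM"),
    list(90, 120, 5.3, TRUE, "DM"),
    list(NA, NA, NA, FALSE, "UNKNOWN"))
  for (cs in cases) {
    expect_equal(classify_visit(cs[[1]], cs[[2]], cs[[3]], cs[[4]]), cs[[5]])
  }
  # absent criteria are simply not consulted: FPG alone can make NGT
  expect_equal(classify_visit(95, NA, NA, FALSE), "NGT")
  expect_equal(classify_visit(NA, NA, 6.0, FALSE), "PREDM")
  expect_error(classify_visit(-1, 120, 5.0, FALSE), "negative")
})

test_that("boundary values land exactly on the higher category", {
  expect_equal(classify_visit(100, 120, 5.3, FALSE), "PREDM")
  expect_equal(classify_visit(126, 120, 5.3, FALSE), "DM")
  expect_equal(classify_visit(90, 140, 5.3, FALSE), "PREDM")
  expect_equal(classify_visit(90, 200, 5.3, FALSE), "DM")
  expect_equal(classify_visit(90, 120, 5.7, FALSE), "PREDM")
  expect_equal(classify_visit(90, 120, 6.5, FALSE), "DM")
  # just below each cutoff stays in the lower category
  expect_equal(classify_visit(99.99, 139.99, 5.69, FALSE), "NGT")
  expect_equal(classify_visit(125.99, 199.99, 6.49, FALSE), "PREDM")
})

test_that("classification is monotone in every input", {
  set.seed(42)
  n <- 2000
  fpg <- runif(n, 60, 180)
  pg2h <- runif(n, 70, 260)
  hba1c <- runif(n, 4, 8)
  base <- status_severity(classify_visit(fpg, pg2h, hba1c, FALSE))
  for (bump in list(c(5, 0, 0), c(0, 10, 0), c(0, 0, 0.4))) {
    bumped <- status_severity(classify_visit(fpg + bump[1], pg2h + bump[2],
                                             hba1c + bump[3], FALSE))
    expect_true(all(bumped >= base))
  }
  # medication never lowers severity
  med <- status_severity(classify_visit(fpg, pg2h, hba1c, TRUE))
  expect_true(all(med >= base))
})

test_that("eligibility filter applies rules in order with one reason each", {
  co <- toy_cohort()
  # A: NGT baseline, full OGTT, has visit 5 -> retained
  # B: NGT baseline, visit 5 present -> retained
  # C: NGT baseline but we flip it to PREDM via g0
  co$g0[co$id == "C" & co$visit_index == 0] <- 105
  flt <- filter_eligible(co)
  expect_setequal(unique(flt$cohort$id), c("A", "B"))
  expect_equal(flt$exclusions$reason[flt$exclusions$id == "C"],
               "baseline not NGT")

  co2 <- toy_cohort()
  co2$hba1c[co2$id == "B" & co2$visit_index == 0] <- NA
  flt2 <- filter_eligible(co2)
  expect_equal(flt2$exclusions$reason[flt2$exclusions$id == "B"],
               "baseline OGTT incomplete")

  co3 <- toy_cohort()
  co3 <- as_cohort(co3[!(co3$id == "B" & co3$visit_index == 5), ])
  flt3 <- filter_eligible(co3)
  expect_equal(flt3$exclusions$reason[flt3$exclusions$id == "B"],
               "no year-10 OGTT")

  co4 <- toy_cohort()
  co4$on_medication[co4$id == "A" & co4$visit_index == 0] <- TRUE
  flt4 <- filter_eligible(co4)
  # medication makes the baseline classify DM, so rule (a) fires first
  expect_equal(flt4$exclusions$reason[flt4$exclusions$id == "A"],
               "baseline not NGT")
})

test_that("progression rules give ever-worst vs final-visit labels", {
  mk <- function(statuses) {
    # build a cohort whose classified statuses follow the given sequence
    fpg <- c(NGT = 90, PREDM = 110, DM = 130)[statuses]
    as_cohort(data.frame(id = "X", visit_index = 0:5, g0 = fpg,
                         hba1c = 5.0))
  }
  expect_equal(
    assign_progression(mk(rep("NGT", 6)))$progression, "NON_P")
  relapse <- mk(c("NGT", "PREDM", "NGT", "NGT", "NGT", "NGT"))
  expect_equal(assign_progression(relapse, "ever-worst")$progression,
               "PREDM_P")
  expect_equal(assign_progression(relapse, "final-visit")$progression,
               "NON_P")
  worsening <- mk(c("NGT", "NGT", "PREDM", "DM", "DM", "DM"))
  expect_equal(assign_progression(worsening, "ever-worst")$progression,
               "T2D_P")
  expect_equal(assign_progression(worsening, "final-visit")$progression,
               "T2D_P")
})

test_that("ever-worst severity dominates final-visit severity", {
  set.seed(7)
  sev_rank <- c(NON_P = 1, PREDM_P = 2, T2D_P = 3)
  for (rep in 1:50) {
    statuses <- sample(c("NGT", "PREDM", "DM"), 6, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1))
    statuses[1] <- "NGT"
    fpg <- c(NGT = 90, PREDM = 110, DM = 130)[statuses]
    co <- as_cohort(data.frame(id = "X", visit_index = 0:5, g0 = fpg,
                               hba1c = 5.0))
    ever <- assign_progression(co, "ever-worst")$progression
    final <- assign_progression(co, "final-visit")$progression
    expect_gte(sev_rank[ever], sev_rank[final])
  }
})

test_that("UNKNOWN visits are skipped, all-unknown errors", {
  co <- as_cohort(data.frame(id = "X", visit_index = 0:5,
                             g0 = c(90, NA, NA, 110, NA, NA),
                             hba1c = c(5.0, NA, NA, NA, NA, NA)))
  expect_equal(assign_progression(co)$progression, "PREDM_P")
  co_none <- as_cohort(data.frame(id = "X", visit_index = 0:1,
                                  g0 = c(90, NA), hba1c = c(5.0, NA)))
  expect_error(assign_progression(co_none), "no evaluable")
})
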