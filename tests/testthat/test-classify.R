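ix_from_ac <- function(ac_left, ac_right, ac_srt) {
  m <- make_patient_measurements(
    cortisol = c(ivc_low = 1, lt_adv = 1, rt_adv = 1, s_rt_adv = 1),
    aldosterone = c(ivc_low = 1, lt_adv = ac_left, rt_adv = ac_right,
                    s_rt_adv = ac_srt))
  compute_index_set(m, "post_acth")
}

test_that("threshold objects enforce their ordering constraints", {
  thr <- avs_thresholds()
  expect_equal(thr$si_success, 5)
  expect_equal(thr$li_uapa, 4)
  expect_error(avs_thresholds(mli_rt = 3, mli_lt = 2), class = "avs_invalid_parameter")
  expect_error(avs_thresholds(si_success = 0.5), class = "avs_invalid_parameter")
})

test_that("catheterization success is inclusive at the selectivity cutoff", {
  expect_true(catheterization_success(5.0))
  expect_false(catheterization_success(4.99))
  expect_false(catheterization_success(1.0))
  expect_error(catheterization_success(-1), class = "avs_invalid_measurement")
})

test_that("conventional rule lateralizes at the inclusive LI cutoff", {
  expect_identical(subtype_conventional(ix_from_ac(4, 1, 1))$label, "lt_APA")
  expect_identical(subtype_conventional(ix_from_ac(1, 3.99, 1))$label, "IHA")
  expect_identical(subtype_conventional(ix_from_ac(1, 23.3, 1))$label, "rt_APA")
  expect_identical(subtype_conventional(ix_from_ac(2, 2, 1))$label, "IHA") # tie
  expect_identical(subtype_conventional(ix_from_ac(4, 1, 1))$rule, "conventional")
})

test_that("modified rule partitions the positive axis with inclusive boundaries", {
  expect_identical(subtype_modified(0.37)$label, "rt_APA")
  expect_identical(subtype_modified(1.52)$label, "IHA")
  expect_identical(subtype_modified(3.46)$label, "lt_APA")
  expect_identical(subtype_modified(0.7)$label, "rt_APA")  # boundary to abnormal class
  expect_identical(subtype_modified(2.2)$label, "lt_APA")
  grid <- c(10^seq(-3, 3, length.out = 60), 0.7, 2.2,
            0.7 + 1e-12, 2.2 - 1e-12)
  for (v in grid) {
    lab <- subtype_modified(v)$label
    expect_true(lab %in% avs_subtypes())
    expect_identical(lab, if (v <= 0.7) "rt_APA" else if (v >= 2.2) "lt_APA" else "IHA")
  }
  expect_error(subtype_modified(0), class = "avs_invalid_measurement")
})

test_that("adjudication dispatches on right-vein selectivity only", {
  ix <- ix_from_ac(10, 1, 20) # LI 10 left; modified 0.5
  conv <- adjudicate(ix, TRUE)
  expect_identical(conv$label, "lt_APA")
  expect_identical(conv$rule, "conventional")
  fall <- adjudicate(ix, FALSE)
  expect_identical(fall$label, subtype_modified(ix$modified_li)$label)
  expect_identical(fall$label, "rt_APA")
  expect_identical(fall$rule, "fallback")

  # perturbation: the unused index must not matter
  ix_m <- ix; ix_m$modified_li <- 99
  expect_identical(adjudicate(ix_m, TRUE)$label, conv$label)
  ix_c <- ix; ix_c$conventional_li <- 1; ix_c$dominant_side <- "tie"
  expect_identical(adjudicate(ix_c, FALSE)$label, fall$label)
})

test_that("forced right-selectivity failure makes fallback equal the modified rule", {
  set.seed(45)
  for (i in 1:20) {
    ac <- runif(3, 0.05, 20)
    ix <- ix_from_ac(ac[1], ac[2], ac[3])
    call <- adjudicate(ix, FALSE)
    expect_identical(call$label, subtype_modified(ix$modified_li)$label)
    expect_identical(call$rule, "fallback")
  }
})

test_that("cohort filter reproduces the study's exclusion cascade", {
  roster <- make_roster()
  expect_equal(nrow(roster), 58)
  res <- cohort_filter(roster)
  expect_equal(nrow(res$included), 44)
  expect_equal(unname(res$tally),
               c(9, 2, 2, 0, 1))
  expect_identical(names(res$tally), exclusion_reasons())
})

test_that("cohort filter edge cases and conservation", {
  empty <- cohort_filter(make_roster(0, 0, 0, 0, 0, 0))
  expect_equal(nrow(empty$included), 0)
  expect_true(all(empty$tally == 0))
  clean <- cohort_filter(make_roster(10, 0, 0, 0, 0, 0))
  expect_equal(nrow(clean$included), 10)

  set.seed(46)
  for (i in 1:10) {
    n <- 30
    meta <- data.frame(
      patient_id = seq_len(n),
      rt_sampling_complete = runif(n) > 0.2,
      surgery_done_if_uapa = runif(n) > 0.2,
      postop_arr = ifelse(runif(n) > 0.5, runif(n, 50, 400), NA_real_),
      postop_bp_normal = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
      followup_available = runif(n) > 0.1
    )
    res <- cohort_filter(meta)
    expect_equal(nrow(res$included) + sum(res$tally), n)
  }
})

test_that("a record failing several checks is counted under the first reason", {
  meta <- make_roster(1, 0, 0, 0, 0, 0)
  meta$rt_sampling_complete <- FALSE
  meta$followup_available <- FALSE
  res <- cohort_filter(meta)
  expect_equal(unname(res$tally[["rt_sampling_incomplete"]]), 1)
  expect_equal(unname(res$tally[["followup_unavailable"]]), 0)
})

test_that("missing eligibility flags raise an incomplete-metadata error", {
  meta <- make_roster(3, 0, 0, 0, 0, 0)
  expect_error(cohort_filter(meta[, setdiff(names(meta), "followup_available")]),
               class = "avs_incomplete_metadata")
  meta$rt_sampling_complete[2] <- NA
  expect_error(cohort_filter(meta), class = "avs_incomplete_metadata")
})
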