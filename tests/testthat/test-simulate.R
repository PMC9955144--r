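test_that("lognormal moment matching round-trips", {
  std <- lognormal_from_moments(exp(0.5), sqrt((exp(1) - 1) * exp(1)))
  expect_equal(std$mu, 0, tolerance = 1e-12)
  expect_equal(std$sigma, 1, tolerance = 1e-12)

  p <- lognormal_from_moments(0.37, 0.38)
  expect_equal(unname(lognormal_moments(p)), c(0.37, 0.38), tolerance = 1e-12)

  set.seed(55)
  for (i in 1:25) {
    m <- runif(1, 0.01, 100); s <- runif(1, 0.01, 100)
    expect_equal(unname(lognormal_moments(lognormal_from_moments(m, s))),
                 c(m, s), tolerance = 1e-10)
  }
  expect_error(lognormal_from_moments(-1, 1), class = "avs_invalid_parameter")
})

test_that("moment matching recovers log-scale parameters from samples", {
  set.seed(56)
  x <- rlnorm(1e5, meanlog = 0.5, sdlog = 0.6)
  fit <- lognormal_from_moments(mean(x), sd(x))
  expect_lt(abs(fit$mu - 0.5) / 0.5, 0.02)
  expect_lt(abs(fit$sigma - 0.6) / 0.6, 0.02)
})

test_that("noise-free patient equals the closed-form dilution algebra", {
  p <- mechanistic_params(noise_cv = 0)
  pat <- simulate_patient("rt_APA", p)
  m <- pat$measurements
  pre <- m[m$phase == "pre_acth", ]
  at <- function(s, w) pre[[w]][pre$site == s]
  expect_equal(at("ivc_low", "cortisol"), p$peripheral_cortisol)
  expect_equal(at("lt_adv", "cortisol"),
               p$peripheral_cortisol + p$cortisol_flux_per_gland / p$adv_flow)
  expect_equal(at("s_rt_adv", "aldosterone"),
               p$peripheral_aldo + (p$units_normal + p$units_apa) / p$ivc_flow)
  # selectivity index equals the flux/flow expression
  ix <- compute_index_set(m, "pre_acth")
  expect_equal(ix$si_left,
               (p$peripheral_cortisol + p$cortisol_flux_per_gland / p$adv_flow) /
                 p$peripheral_cortisol)
  # post-ACTH rows carry the multiplied fluxes
  post <- m[m$phase == "post_acth", ]
  expect_equal(post$aldosterone[post$site == "s_rt_adv"],
               p$peripheral_aldo +
                 (p$units_normal + p$units_apa) * p$acth_aldo_multiplier / p$ivc_flow)
})

test_that("with no background the substitute site sees eleven toy units", {
  p <- mechanistic_params(noise_cv = 0, peripheral_aldo = 0,
                          peripheral_cortisol = 1e-12)
  m <- simulate_patient("rt_APA", p)$measurements
  pre <- m[m$phase == "pre_acth", ]
  expect_equal(pre$aldosterone[pre$site == "s_rt_adv"] * p$ivc_flow, 11)
  expect_equal(pre$aldosterone[pre$site == "lt_adv"] * p$adv_flow, 1)
  expect_error(simulate_patient("bilateral", p), class = "avs_invalid_input")
})

test_that("identical seeds give identical patients; different seeds differ", {
  p <- mechanistic_params(noise_cv = 0.3)
  a <- simulate_patient("IHA", p, seed = 99)
  b <- simulate_patient("IHA", p, seed = 99)
  expect_identical(a, b)
  c <- simulate_patient("IHA", p, seed = 100)
  expect_false(identical(a$measurements$cortisol, c$measurements$cortisol))
})

test_that("indices are invariant under an overall hormone-unit rescaling", {
  p <- mechanistic_params(noise_cv = 0)
  k <- 7.3
  p2 <- mechanistic_params(
    units_normal = p$units_normal * k, units_apa = p$units_apa * k,
    cortisol_flux_per_gland = p$cortisol_flux_per_gland * k,
    adv_flow = p$adv_flow, ivc_flow = p$ivc_flow,
    peripheral_aldo = p$peripheral_aldo * k,
    peripheral_cortisol = p$peripheral_cortisol * k,
    noise_cv = 0)
  for (cls in avs_subtypes()) {
    ix1 <- compute_index_set(simulate_patient(cls, p)$measurements)
    ix2 <- compute_index_set(simulate_patient(cls, p2)$measurements)
    for (f in c("si_left", "si_right", "conventional_li", "modified_li")) {
      expect_equal(ix1[[f]], ix2[[f]], tolerance = 1e-12)
    }
  }
})

test_that("vectorized modified-LI draws match the closed-form moments", {
  p <- mechanistic_params(noise_cv = 0.4)
  pred <- predict_mli_moments(p)
  for (cls in avs_subtypes()) {
    x <- simulate_modified_li(cls, 50000, p, seed = 57)
    pr <- pred[pred$class == cls, ]
    expect_equal(mean(x), pr$mean, tolerance = 0.05)
    expect_equal(sd(x), pr$sd, tolerance = 0.1)
  }
  # zero noise: every draw equals the deterministic value
  p0 <- mechanistic_params(noise_cv = 0)
  x0 <- simulate_modified_li("lt_APA", 10, p0)
  v0 <- predict_mli_moments(p0)
  expect_true(all(abs(x0 - v0$mean[v0$class == "lt_APA"]) < 1e-12))
})

test_that("distributional cohorts hit their calibration moments", {
  n <- c(4000, 6000, 12000)
  co <- draw_cohort(cohort_spec(n[1], n[2], n[3], mode = "distributional",
                                seed = 58))
  mom <- default_cohort_moments()$modified_li
  for (i in seq_along(avs_subtypes())) {
    cls <- avs_subtypes()[i]
    x <- co$modified_li[co$class == cls]
    tgt <- mom[mom$class == cls, ]
    se <- tgt$sd / sqrt(length(x))
    expect_lt(abs(mean(x) - tgt$mean), 3 * se + 0.02 * tgt$mean)
  }
})

test_that("cohort generation edge cases and determinism", {
  empty <- draw_cohort(cohort_spec(0, 0, 0, mode = "distributional", seed = 1))
  expect_equal(nrow(empty), 0)

  bad_cal <- list(modified_li = default_cohort_moments()$modified_li[1:2, ])
  expect_error(draw_cohort(cohort_spec(1, 1, 1, mode = "distributional", seed = 1),
                           bad_cal),
               class = "avs_invalid_parameter")

  a <- draw_cohort(cohort_spec(3, 3, 3, seed = 7))
  b <- draw_cohort(cohort_spec(3, 3, 3, seed = 7))
  expect_identical(a, b)
})

test_that("a mechanistic cohort runs end-to-end into a confusion table", {
  co <- draw_cohort(cohort_spec(8, 12, 24, seed = 59))
  expect_equal(nrow(co$meta), 44)
  expect_equal(nrow(co$measurements), 44 * 4 * 2)
  rep <- run_pipeline(co)
  conf <- table(true = rep$per_patient$class, called = rep$per_patient$call)
  expect_equal(sum(conf), 44)
  expect_setequal(rownames(conf), avs_subtypes())
})
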