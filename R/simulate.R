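#' Lognormal parameters from arithmetic moments
#'
#' Moment matching on the natural scale: given a target arithmetic mean and
#' standard deviation, returns the log-scale location and spread of the
#' lognormal with those moments, via `sigma^2 = log(1 + (sd/mean)^2)` and
#' `mu = log(mean) - sigma^2/2`. The round trip through
#' [lognormal_moments()] reproduces the inputs to machine tolerance.
#'
#' @param mean Target arithmetic mean, positive.
#' @param sd Target arithmetic standard deviation, positive.
#' @return An object of class `lognormal_params`: list with `mu`, `sigma`.
#' @examples
#' lognormal_from_moments(0.37, 0.38)
#' @export
lognormal_from_moments <- function(mean, sd) {
  check_positive(mean, "mean", class = "avs_invalid_parameter")
  check_positive(sd, "sd", class = "avs_invalid_parameter")
  stopifnot(length(mean) == 1L, length(sd) == 1L)
  s2 <- log1p((sd / mean)^2)
  structure(list(mu = log(mean) - s2 / 2, sigma = sqrt(s2)),
            class = "lognormal_params")
}

#' Arithmetic moments of a lognormal
#'
#' Inverse of [lognormal_from_moments()].
#'
#' @param params A `lognormal_params` object (or list with `mu`, `sigma`).
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
lognormal_moments <- function(params) {
  m <- exp(params$mu + params$sigma^2 / 2)
  c(mean = m, sd = m * sqrt(expm1(params$sigma^2)))
}

#' Parameters of the mechanistic secretion/dilution model
#'
#' The simulator extends the unit-secretion thought experiment behind the
#' modified lateralized index into a steady-state secretion and dilution
#' model. Each adrenal gland secretes aldosterone at a rate of
#' `units_normal` units (or `units_apa` when it harbours a producing lesion)
#' and cortisol at `cortisol_flux_per_gland`. An adrenal-vein sample carries
#' its own gland's fluxes diluted by `adv_flow` plus the peripheral
#' background; the substitute right adrenal-vein sample carries BOTH glands'
#' fluxes diluted by `ivc_flow` (the left adrenal vein drains into the IVC
#' via the renal vein below that sampling point, so its output is already
#' mixed in); the lowest-IVC sample carries background only. ACTH
#' stimulation multiplies gland fluxes by the two multipliers (background is
#' held fixed); the multipliers cancel in every cortisol-normalized index at
#' zero noise. Measurement-level biological noise is multiplicative
#' lognormal with unit mean and coefficient of variation `noise_cv`.
#'
#' @param units_normal Aldosterone output of a healthy gland (default 1).
#' @param units_apa Aldosterone output of a gland carrying a producing
#'   lesion (default 10).
#' @param cortisol_flux_per_gland Cortisol output per gland, identical for
#'   both glands.
#' @param adv_flow Effective dilution flow at an adrenal-vein sampling site.
#' @param ivc_flow Effective dilution flow at the substitute right
#'   adrenal-vein site.
#' @param peripheral_aldo,peripheral_cortisol Background (recirculating)
#'   concentrations seen at every site.
#' @param acth_aldo_multiplier,acth_cortisol_multiplier Post-ACTH flux
#'   multipliers, at least 1.
#' @param noise_cv Coefficient of variation of the per-measurement
#'   multiplicative lognormal noise, >= 0.
#' @param seed Optional integer seed used by [simulate_patient()] when no
#'   explicit seed is passed.
#' @return An object of class `mechanistic_params`.
#' @export
mechanistic_params <- function(units_normal = 1, units_apa = 10,
                               cortisol_flux_per_gland = 10,
                               adv_flow = 1, ivc_flow = 10,
                               peripheral_aldo = 0.5,
                               peripheral_cortisol = 0.5,
                               acth_aldo_multiplier = 3,
                               acth_cortisol_multiplier = 2,
                               noise_cv = 0.25, seed = NULL) {
  p <- list(units_normal = units_normal, units_apa = units_apa,
            cortisol_flux_per_gland = cortisol_flux_per_gland,
            adv_flow = adv_flow, ivc_flow = ivc_flow,
            peripheral_aldo = peripheral_aldo,
            peripheral_cortisol = peripheral_cortisol,
            acth_aldo_multiplier = acth_aldo_multiplier,
            acth_cortisol_multiplier = acth_cortisol_multiplier,
            noise_cv = noise_cv, seed = seed)
  for (nm in c("units_normal", "units_apa", "cortisol_flux_per_gland",
               "adv_flow", "ivc_flow")) {
    check_positive(p[[nm]], nm, class = "avs_invalid_parameter")
  }
  for (nm in c("peripheral_aldo", "peripheral_cortisol", "noise_cv")) {
    check_positive(p[[nm]], nm, allow_zero = TRUE,
                   class = "avs_invalid_parameter")
  }
  if (acth_aldo_multiplier < 1 || acth_cortisol_multiplier < 1) {
    abort_avs("avs_invalid_parameter", "ACTH multipliers must be at least 1")
  }
  structure(p, class = "mechanistic_params")
}

gland_fluxes <- function(subtype, params) {
  switch(subtype,
         rt_APA = c(left = params$units_normal, right = params$units_apa),
         lt_APA = c(left = params$units_apa, right = params$units_normal),
         IHA = c(left = params$units_apa, right = params$units_apa),
         abort_avs("avs_invalid_input",
                   sprintf("unknown subtype '%s'", subtype)))
}

## noise-free site concentrations for one subtype and phase
site_concentrations <- function(subtype, params, phase) {
  fl <- gland_fluxes(subtype, params)
  ma <- if (phase == "post_acth") params$acth_aldo_multiplier else 1
  mc <- if (phase == "post_acth") params$acth_cortisol_multiplier else 1
  cf <- params$cortisol_flux_per_gland * mc
  al <- fl * ma
  data.frame(
    site = avs_sites(),
    cortisol = c(params$peripheral_cortisol,
                 params$peripheral_cortisol + cf / params$adv_flow,
                 params$peripheral_cortisol + cf / params$adv_flow,
                 params$peripheral_cortisol + 2 * cf / params$ivc_flow),
    aldosterone = c(params$peripheral_aldo,
                    params$peripheral_aldo + al[["left"]] / params$adv_flow,
                    params$peripheral_aldo + al[["right"]] / params$adv_flow,
                    params$peripheral_aldo + sum(al) / params$ivc_flow),
    stringsAsFactors = FALSE
  )
}

noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log1p(cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate one patient's AVS measurements
#'
#' Draws the full four-site, two-phase measurement set of one synthetic
#' patient from the mechanistic model (see [mechanistic_params()] for the
#' model). With `noise_cv = 0` the output is an exact closed-form function
#' of the parameters.
#'
#' @param subtype One of [avs_subtypes()].
#' @param params A [mechanistic_params()] object.
#' @param patient_id Identifier stored in the measurement rows.
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched. Defaults to `params$seed`.
#' @return An object of class `avs_patient`: list with `patient_id`,
#'   `subtype` and `measurements` (8-row data frame with columns
#'   `patient_id`, `site`, `phase`, `cortisol`, `aldosterone`).
#' @examples
#' simulate_patient("rt_APA", mechanistic_params(noise_cv = 0))
#' @export
simulate_patient <- function(subtype, params = mechanistic_params(),
                             patient_id = "P1", seed = params$seed) {
  stopifnot(inherits(params, "mechanistic_params"))
  draw <- function() {
    rows <- do.call(rbind, lapply(avs_phases(), function(ph) {
      conc <- site_concentrations(subtype, params, ph)
      cbind(data.frame(patient_id = patient_id, phase = ph,
                       stringsAsFactors = FALSE),
            conc)
    }))
    rows$cortisol <- rows$cortisol * noise_factors(nrow(rows), params$noise_cv)
    rows$aldosterone <- rows$aldosterone * noise_factors(nrow(rows), params$noise_cv)
    rows[, c("patient_id", "site", "phase", "cortisol", "aldosterone")]
  }
  measurements <- with_seed(seed, draw())
  rownames(measurements) <- NULL
  structure(list(patient_id = patient_id, subtype = subtype,
                 measurements = measurements),
            class = "avs_patient")
}

#' Vectorized modified-LI draws from the mechanistic model
#'
#' Samples `n` independent modified lateralized indices for one subtype
#' without materializing full patient records — the same arithmetic as
#' running [simulate_patient()] through [compute_index_set()], at cohort
#' scale. Used for calibration checks and large Monte-Carlo validation.
#'
#' @inheritParams simulate_patient
#' @param n Number of draws.
#' @param phase Phase whose measurements feed the index.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` modified-LI values.
#' @export
simulate_modified_li <- function(subtype, n, params = mechanistic_params(),
                                 phase = c("post_acth", "pre_acth"),
                                 seed = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(params, "mechanistic_params"), n >= 0)
  conc <- site_concentrations(subtype, params, phase)
  a_lt <- conc$aldosterone[conc$site == "lt_adv"]
  c_lt <- conc$cortisol[conc$site == "lt_adv"]
  a_srt <- conc$aldosterone[conc$site == "s_rt_adv"]
  c_srt <- conc$cortisol[conc$site == "s_rt_adv"]
  with_seed(seed, {
    (a_lt * noise_factors(n, params$noise_cv) /
       (c_lt * noise_factors(n, params$noise_cv))) /
      (a_srt * noise_factors(n, params$noise_cv) /
         (c_srt * noise_factors(n, params$noise_cv)))
  })
}

#' Reference class-wise moments used to calibrate synthetic cohorts
#'
#' Arithmetic mean and standard deviation of the modified and conventional
#' lateralized indices, and of the aldosterone-renin ratio, for each subtype
#' class in the 44-patient reference cohort the generator emulates (right
#' APA n = 8, left APA n = 12, idiopathic hyperaldosteronism n = 24). These
#' are the default calibration targets of [draw_cohort()] and
#' [calibrate_mechanistic()].
#'
#' @return A list of data frames `modified_li`, `conventional_li`, `arr`,
#'   each with columns `class`, `mean`, `sd`.
#' @export
default_cohort_moments <- function() {
  cls <- avs_subtypes()
  list(
    modified_li = data.frame(class = cls,
                             mean = c(0.37, 3.46, 1.52),
                             sd = c(0.38, 1.97, 1.11),
                             stringsAsFactors = FALSE),
    conventional_li = data.frame(class = cls,
                                 mean = c(23.26, 7.05, 1.56),
                                 sd = c(25.76, 5.33, 1.32),
                                 stringsAsFactors = FALSE),
    arr = data.frame(class = cls,
                     mean = c(1429.9, 1562.1, 560.6),
                     sd = c(902.6, 1429.9, 356.8),
                     stringsAsFactors = FALSE)
  )
}

#' Cohort specification
#'
#' Class counts, generator mode and seed for [draw_cohort()]. Defaults
#' reproduce the reference cohort composition: 8 right APA, 12 left APA, 24
#' idiopathic.
#'
#' @param n_rt_apa,n_lt_apa,n_iha Non-negative class counts.
#' @param mode `"mechanistic"` (full patient records from the
#'   secretion/dilution model) or `"distributional"` (index scores drawn
#'   directly from per-class lognormals).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `avs_cohort_spec`.
#' @export
cohort_spec <- function(n_rt_apa = 8, n_lt_apa = 12, n_iha = 24,
                        mode = c("mechanistic", "distributional"),
                        seed = 1L) {
  mode <- match.arg(mode)
  counts <- c(n_rt_apa, n_lt_apa, n_iha)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_avs("avs_invalid_parameter", "class counts must be non-negative integers")
  }
  structure(list(n_rt_apa = as.integer(n_rt_apa),
                 n_lt_apa = as.integer(n_lt_apa),
                 n_iha = as.integer(n_iha),
                 mode = mode, seed = as.integer(seed)),
            class = "avs_cohort_spec")
}

class_counts <- function(spec) {
  c(rt_APA = spec$n_rt_apa, lt_APA = spec$n_lt_apa, IHA = spec$n_iha)
}

moments_row <- function(df, cls) {
  row <- df[df$class == cls, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort_avs("avs_invalid_parameter",
              sprintf("calibration is missing class '%s'", cls))
  }
  row
}

#' Draw a synthetic cohort
#'
#' In distributional mode, per-patient modified and conventional
#' lateralized-index scores are drawn directly from per-class lognormal
#' distributions moment-matched to the calibration table (defaults:
#' [default_cohort_moments()]). In mechanistic mode, full patient records
#' are simulated from the secretion/dilution model and metadata (eligibility
#' flags, PRA/ARR/PAC) is attached so the cohort can run through the whole
#' analysis pipeline.
#'
#' @param spec A [cohort_spec()].
#' @param calibration Distributional mode: a list of per-class moment tables
#'   as returned by [default_cohort_moments()] (elements `modified_li` and,
#'   optionally, `conventional_li`). Mechanistic mode: a
#'   [mechanistic_params()] object. `NULL` uses the defaults.
#' @return Distributional mode: a data frame with columns `patient_id`,
#'   `class`, `modified_li` and (when calibrated) `conventional_li`.
#'   Mechanistic mode: an object of class `avs_cohort` — a list with
#'   `measurements` (long data frame) and `meta` (one row per patient with
#'   class label, eligibility flags and PAC/PRA/ARR).
#' @examples
#' draw_cohort(cohort_spec(2, 3, 4, mode = "distributional", seed = 7))
#' @export
draw_cohort <- function(spec, calibration = NULL) {
  stopifnot(inherits(spec, "avs_cohort_spec"))
  counts <- class_counts(spec)
  if (spec$mode == "distributional") {
    cal <- calibration %||% default_cohort_moments()
    if (is.null(cal$modified_li)) {
      abort_avs("avs_invalid_parameter",
                "distributional calibration needs a `modified_li` moment table")
    }
    with_seed(spec$seed, {
      out <- lapply(names(counts), function(cls) {
        n <- counts[[cls]]
        if (n == 0L) return(NULL)
        mrow <- moments_row(cal$modified_li, cls)
        lp <- lognormal_from_moments(mrow$mean, mrow$sd)
        df <- data.frame(class = rep(cls, n),
                         modified_li = stats::rlnorm(n, lp$mu, lp$sigma),
                         stringsAsFactors = FALSE)
        if (!is.null(cal$conventional_li)) {
          crow <- moments_row(cal$conventional_li, cls)
          cp <- lognormal_from_moments(crow$mean, crow$sd)
          df$conventional_li <- stats::rlnorm(n, cp$mu, cp$sigma)
        }
        df
      })
      out <- do.call(rbind, out)
      if (is.null(out)) {
        out <- data.frame(class = character(0), modified_li = numeric(0))
      }
      out <- cbind(patient_id = sprintf("S%04d", seq_len(nrow(out))), out,
                   stringsAsFactors = FALSE)
      rownames(out) <- NULL
      out
    })
  } else {
    params <- calibration %||% mechanistic_params()
    stopifnot(inherits(params, "mechanistic_params"))
    arr_mom <- default_cohort_moments()$arr
    pra_lp <- lognormal_from_moments(0.3, 0.2)
    with_seed(spec$seed, {
      ids <- sprintf("M%04d", seq_len(sum(counts)))
      classes <- rep(names(counts), counts)
      patients <- lapply(seq_along(ids), function(i) {
        simulate_patient(classes[i], params, patient_id = ids[i], seed = NULL)
      })
      measurements <- do.call(rbind, lapply(patients, `[[`, "measurements"))
      rownames(measurements) <- NULL
      arr <- vapply(classes, function(cls) {
        m <- moments_row(arr_mom, cls)
        lp <- lognormal_from_moments(m$mean, m$sd)
        stats::rlnorm(1, lp$mu, lp$sigma)
      }, numeric(1))
      pra <- stats::rlnorm(length(ids), pra_lp$mu, pra_lp$sigma)
      meta <- data.frame(
        patient_id = ids, class = classes,
        pac = arr * pra, pra = pra, arr = arr,
        rt_sampling_complete = TRUE, surgery_done_if_uapa = TRUE,
        postop_arr = NA_real_, postop_bp_normal = NA,
        followup_available = TRUE,
        stringsAsFactors = FALSE
      )
      rownames(meta) <- NULL
      structure(list(measurements = measurements, meta = meta),
                class = "avs_cohort")
    })
  }
}

#' @export
print.avs_cohort <- function(x, ...) {
  cat(sprintf("AVS cohort: %d patients, %d measurement rows\n",
              nrow(x$meta), nrow(x$measurements)))
  if ("class" %in% names(x$meta)) print(table(x$meta$class))
  invisible(x)
}
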