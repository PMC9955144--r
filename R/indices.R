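#' Selectivity index
#'
#' Ratio of adrenal-vein cortisol to cortisol at the lowest point of the
#' inferior vena cava. A high ratio indicates the catheter tip sampled
#' adrenal effluent rather than mixed caval blood; by convention a value of
#' at least 5 under ACTH stimulation counts as successful catheterization
#' (see [catheterization_success()]).
#'
#' @param cortisol_adv Adrenal-vein plasma cortisol (ug/dL), positive.
#' @param cortisol_ivc_low Cortisol at the lowest IVC sampling point (ug/dL),
#'   positive.
#' @return The dimensionless ratio `cortisol_adv / cortisol_ivc_low`.
#'   Vectorized over both arguments.
#' @examples
#' selectivity_index(25, 5)
#' @export
selectivity_index <- function(cortisol_adv, cortisol_ivc_low) {
  check_positive(cortisol_adv, "cortisol_adv")
  check_positive(cortisol_ivc_low, "cortisol_ivc_low")
  cortisol_adv / cortisol_ivc_low
}

#' Aldosterone/cortisol ratio
#'
#' Cortisol-normalized aldosterone at a sampling site. Normalizing by
#' cortisol corrects for dilution of adrenal effluent, so A/C ratios from
#' differently diluted sites are comparable. Units (pg/mL over ug/dL) are
#' treated as a unitless score; every downstream index is a ratio of A/C
#' ratios in which they cancel.
#'
#' @param aldosterone Plasma aldosterone concentration (pg/mL), non-negative.
#' @param cortisol Plasma cortisol concentration (ug/dL), positive.
#' @return `aldosterone / cortisol`. Vectorized.
#' @examples
#' ac_ratio(100, 10)
#' @export
ac_ratio <- function(aldosterone, cortisol) {
  check_positive(aldosterone, "aldosterone", allow_zero = TRUE)
  check_positive(cortisol, "cortisol")
  aldosterone / cortisol
}

#' Conventional lateralized index
#'
#' The larger of the two adrenal-vein A/C ratios divided by the smaller, with
#' the side carrying the larger ratio recorded as dominant. Always at least 1.
#' Equal ratios give an index of exactly 1 and side `"tie"`.
#'
#' @param ac_left Left adrenal-vein A/C ratio, positive.
#' @param ac_right Right adrenal-vein A/C ratio, positive.
#' @return A data frame with columns `li` (max/min ratio, >= 1) and
#'   `dominant_side` (`"left"`, `"right"` or `"tie"`). Vectorized.
#' @examples
#' conventional_li(10, 2)
#' @export
conventional_li <- function(ac_left, ac_right) {
  check_positive(ac_left, "ac_left")
  check_positive(ac_right, "ac_right")
  li <- pmax(ac_left, ac_right) / pmin(ac_left, ac_right)
  side <- ifelse(ac_left > ac_right, "left",
                 ifelse(ac_right > ac_left, "right", "tie"))
  data.frame(li = li, dominant_side = side, stringsAsFactors = FALSE)
}

#' Modified lateralized index
#'
#' Left adrenal-vein A/C ratio over the A/C ratio at the substitute right
#' adrenal vein (S-rt.AdV), an IVC sample one vertebral level above the right
#' adrenal vein confluence. Because the S-rt.AdV sample carries the output of
#' both adrenal glands, low values point to a right-sided aldosterone source,
#' high values to a left-sided one, and intermediate values to bilateral
#' (idiopathic) disease.
#'
#' @param ac_left Left adrenal-vein A/C ratio, positive.
#' @param ac_srt S-rt.AdV A/C ratio, positive.
#' @return `ac_left / ac_srt`. Vectorized.
#' @examples
#' modified_li(10, 11) # right-sided lesion pattern, ~0.9
#' @export
modified_li <- function(ac_left, ac_srt) {
  check_positive(ac_left, "ac_left")
  check_positive(ac_srt, "ac_srt")
  ac_left / ac_srt
}

#' Dilution-free toy modified lateralized index
#'
#' The unit-secretion thought experiment behind the modified index: a normal
#' adrenal gland secretes one unit of hormone, a hormone-producing lesion ten
#' units, and the substitute right adrenal vein detects the sum of both
#' glands' output while the left adrenal vein detects only the left gland's.
#' Ignoring dilution entirely, the modified index is then
#' `left_units / (left_units + right_units)`, which is at most 1: roughly 0.1
#' for a right-sided lesion (1/11), 0.5 for bilateral lesions (10/20), and
#' 0.9 for a left-sided lesion (10/11).
#'
#' @param left_units Hormone output of the left gland, positive.
#' @param right_units Hormone output of the right gland, non-negative.
#' @return `left_units / (left_units + right_units)`, in (0, 1]. Vectorized.
#' @examples
#' toy_modified_li(1, 10)
#' toy_modified_li(10, 10)
#' toy_modified_li(10, 1)
#' @export
toy_modified_li <- function(left_units, right_units) {
  check_positive(left_units, "left_units", class = "avs_invalid_input")
  check_positive(right_units, "right_units", allow_zero = TRUE,
                 class = "avs_invalid_input")
  left_units / (left_units + right_units)
}

#' Derive all per-patient indices from one phase of sampling
#'
#' Aggregates the raw four-site hormone measurements of a single patient into
#' the full index set: site-wise A/C ratios, left and right selectivity
#' indices, the conventional lateralized index with its dominant side, and
#' the modified lateralized index. Indices are computed from one stimulation
#' phase; the post-ACTH phase is the default since the selectivity criterion
#' is defined for stimulated sampling.
#'
#' @param measurements Data frame with columns `site`, `phase`, `cortisol`,
#'   `aldosterone` holding one patient's samples. All four sites
#'   ([avs_sites()]) must be present for the requested phase.
#' @param phase `"post_acth"` (default) or `"pre_acth"`.
#' @return An object of class `avs_index_set`: a list with elements `phase`,
#'   `si_left`, `si_right`, `ac_ivc`, `ac_left`, `ac_right`, `ac_srt`,
#'   `conventional_li`, `dominant_side`, `modified_li`.
#' @examples
#' m <- data.frame(
#'   site = c("ivc_low", "lt_adv", "rt_adv", "s_rt_adv"),
#'   phase = "post_acth",
#'   cortisol = c(10, 250, 300, 16),
#'   aldosterone = c(150, 900, 9000, 700)
#' )
#' compute_index_set(m)
#' @export
compute_index_set <- function(measurements, phase = c("post_acth", "pre_acth")) {
  phase <- match.arg(phase)
  need <- c("site", "phase", "cortisol", "aldosterone")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    abort_avs("avs_invalid_input",
              sprintf("`measurements` must be a data frame with columns %s",
                      paste(need, collapse = ", ")))
  }
  m <- measurements[measurements$phase == phase, , drop = FALSE]
  missing <- setdiff(avs_sites(), m$site)
  if (length(missing)) {
    abort_avs("avs_incomplete_sampling",
              sprintf("incomplete sampling: missing %s",
                      paste(sprintf("(%s, %s)", missing, phase), collapse = ", ")),
              missing_sites = missing, phase = phase)
  }
  if (anyDuplicated(m$site)) {
    abort_avs("avs_invalid_measurement",
              sprintf("duplicated site(s) %s for phase %s",
                      paste(unique(m$site[duplicated(m$site)]), collapse = ", "),
                      phase))
  }
  val <- function(site, what) m[[what]][m$site == site]

  ac <- vapply(avs_sites(),
               function(s) ac_ratio(val(s, "aldosterone"), val(s, "cortisol")),
               numeric(1))
  conv <- conventional_li(ac[["lt_adv"]], ac[["rt_adv"]])
  structure(list(
    phase = phase,
    si_left = selectivity_index(val("lt_adv", "cortisol"), val("ivc_low", "cortisol")),
    si_right = selectivity_index(val("rt_adv", "cortisol"), val("ivc_low", "cortisol")),
    ac_ivc = ac[["ivc_low"]],
    ac_left = ac[["lt_adv"]],
    ac_right = ac[["rt_adv"]],
    ac_srt = ac[["s_rt_adv"]],
    conventional_li = conv$li,
    dominant_side = conv$dominant_side,
    modified_li = modified_li(ac[["lt_adv"]], ac[["s_rt_adv"]])
  ), class = "avs_index_set")
}

#' @export
print.avs_index_set <- function(x, ...) {
  cat(sprintf("AVS index set (%s)\n", x$phase))
  cat(sprintf("  SI left/right:     %.2f / %.2f\n", x$si_left, x$si_right))
  cat(sprintf("  A/C ivc,lt,rt,srt: %.3g, %.3g, %.3g, %.3g\n",
              x$ac_ivc, x$ac_left, x$ac_right, x$ac_srt))
  cat(sprintf("  conventional LI:   %.3g (dominant %s)\n",
              x$conventional_li, x$dominant_side))
  cat(sprintf("  modified LI:       %.3g\n", x$modified_li))
  invisible(x)
}
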