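#' Decision thresholds for AVS classification
#'
#' Bundles the cutoffs used by the classification rules. Defaults follow the
#' guideline conventions for ACTH-stimulated sampling: a selectivity index of
#' at least 5 marks successful catheterization, a conventional lateralized
#' index of at least 4 marks unilateral disease, and modified-LI cutoffs of
#' 0.7 (at or below: right APA) and 2.2 (at or above: left APA) bracket the
#' idiopathic range.
#'
#' @param si_success Selectivity-index cutoff for catheterization success
#'   (inclusive), > 1.
#' @param li_uapa Conventional-LI cutoff for unilateral disease (inclusive),
#'   > 1.
#' @param mli_rt Modified-LI cutoff at or below which right APA is called.
#' @param mli_lt Modified-LI cutoff at or above which left APA is called;
#'   must exceed `mli_rt`.
#' @return An object of class `avs_thresholds`.
#' @examples
#' avs_thresholds()
#' avs_thresholds(mli_rt = 0.3, mli_lt = 3.1) # alternative published pair
#' @export
avs_thresholds <- function(si_success = 5.0, li_uapa = 4.0,
                           mli_rt = 0.7, mli_lt = 2.2) {
  for (nm in c("si_success", "li_uapa", "mli_rt", "mli_lt")) {
    check_positive(get(nm), nm, class = "avs_invalid_parameter")
  }
  if (!(mli_rt < mli_lt)) {
    abort_avs("avs_invalid_parameter", "`mli_rt` must be smaller than `mli_lt`")
  }
  if (si_success <= 1 || li_uapa <= 1) {
    abort_avs("avs_invalid_parameter",
              "`si_success` and `li_uapa` must both exceed 1")
  }
  structure(list(si_success = si_success, li_uapa = li_uapa,
                 mli_rt = mli_rt, mli_lt = mli_lt),
            class = "avs_thresholds")
}

#' @export
print.avs_thresholds <- function(x, ...) {
  cat(sprintf(
    "AVS thresholds: SI >= %.3g, conventional LI >= %.3g, modified LI <= %.3g | >= %.3g\n",
    x$si_success, x$li_uapa, x$mli_rt, x$mli_lt))
  invisible(x)
}

#' Catheterization success from the selectivity index
#'
#' @param si Selectivity index, positive.
#' @param thresholds An [avs_thresholds()] object.
#' @return Logical: `TRUE` when `si >= si_success` (inclusive). Vectorized.
#' @examples
#' catheterization_success(c(5, 4.99))
#' @export
catheterization_success <- function(si, thresholds = avs_thresholds()) {
  check_positive(si, "si")
  si >= thresholds$si_success
}

new_subtype_call <- function(label, rule, indices = NULL) {
  structure(list(label = label, rule = rule, indices = indices),
            class = "avs_subtype_call")
}

#' @export
print.avs_subtype_call <- function(x, ...) {
  cat(sprintf("subtype call: %s (%s rule)\n", x$label, x$rule))
  invisible(x)
}

#' Conventional subtype rule
#'
#' Applies the two-adrenal-vein rule: a conventional lateralized index at or
#' above the cutoff diagnoses unilateral disease lateralized to the dominant
#' side; below the cutoff, idiopathic hyperaldosteronism. A tied index (LI =
#' 1) always falls below the cutoff, so a tie never lateralizes.
#'
#' @param index_set An [compute_index_set()] result.
#' @param thresholds An [avs_thresholds()] object.
#' @return An `avs_subtype_call` with `label` in
#'   `c("rt_APA", "lt_APA", "IHA")` and `rule = "conventional"`.
#' @export
subtype_conventional <- function(index_set, thresholds = avs_thresholds()) {
  stopifnot(inherits(index_set, "avs_index_set"))
  label <- if (index_set$conventional_li >= thresholds$li_uapa) {
    switch(index_set$dominant_side, left = "lt_APA", right = "rt_APA",
           abort_avs("avs_invalid_input",
                     "lateralized index at/above cutoff with tied sides"))
  } else {
    "IHA"
  }
  new_subtype_call(label, "conventional", index_set)
}

mli_label <- function(mli, thresholds) {
  ifelse(mli <= thresholds$mli_rt, "rt_APA",
         ifelse(mli >= thresholds$mli_lt, "lt_APA", "IHA"))
}

#' Modified-LI tri-class rule
#'
#' Classifies from the modified lateralized index alone: values at or below
#' `mli_rt` call right APA, values at or above `mli_lt` call left APA, and
#' the intermediate band calls idiopathic hyperaldosteronism. Boundaries are
#' attached to the abnormal class, mirroring the inclusive conventional-LI
#' convention. The three bands partition the positive axis, so every positive
#' index receives exactly one label.
#'
#' @param modified_li Modified lateralized index, positive scalar.
#' @param thresholds An [avs_thresholds()] object.
#' @return An `avs_subtype_call` with `rule = "modified"`.
#' @examples
#' subtype_modified(0.37)$label
#' subtype_modified(1.52)$label
#' subtype_modified(3.46)$label
#' @export
subtype_modified <- function(modified_li, thresholds = avs_thresholds()) {
  check_positive(modified_li, "modified_li")
  stopifnot(length(modified_li) == 1L)
  new_subtype_call(mli_label(modified_li, thresholds), "modified")
}

#' Adjudicate between the conventional and modified rules
#'
#' Dispatches on right adrenal-vein selectivity: when right-sided sampling
#' was selective the conventional two-vein rule applies; when it failed, the
#' modified index (which does not use the right adrenal vein) is used as the
#' fallback. The fallback call is identical to [subtype_modified()] except
#' that its `rule` field records `"fallback"`.
#'
#' @param index_set An [compute_index_set()] result.
#' @param si_right_ok Logical: did the right adrenal vein meet the
#'   selectivity criterion?
#' @param thresholds An [avs_thresholds()] object.
#' @return An `avs_subtype_call`.
#' @export
adjudicate <- function(index_set, si_right_ok, thresholds = avs_thresholds()) {
  stopifnot(inherits(index_set, "avs_index_set"), is.logical(si_right_ok),
            length(si_right_ok) == 1L, !is.na(si_right_ok))
  if (si_right_ok) {
    subtype_conventional(index_set, thresholds)
  } else {
    call <- subtype_modified(index_set$modified_li, thresholds)
    call$rule <- "fallback"
    call$indices <- index_set
    call
  }
}

#' Exclusion reasons applied by [cohort_filter()], in order.
#' @export
exclusion_reasons <- function() {
  c("rt_sampling_incomplete", "uapa_without_surgery",
    "postop_arr_not_normalized", "postop_bp_not_normalized",
    "followup_unavailable")
}

#' Cohort eligibility filter
#'
#' Applies the study's exclusion cascade to a patient metadata table, in
#' fixed order: (1) incomplete right adrenal-vein sampling; (2) a unilateral
#' adenoma diagnosis without subsequent surgery; (3) post-operative
#' aldosterone-renin ratio not normalized (>= 200); (4) post-operative blood
#' pressure not normalized; (5) follow-up unavailable. A patient failing
#' several checks is counted once, under the first failing reason, so the
#' included count plus the tally always sums to the input count.
#'
#' @param meta Data frame with one row per patient. Required logical columns
#'   (no `NA`): `rt_sampling_complete`, `surgery_done_if_uapa`,
#'   `followup_available`. Optional columns `postop_arr` (numeric, `NA` when
#'   not applicable) and `postop_bp_normal` (logical, `NA` when not
#'   applicable).
#' @return A list with `included` (surviving rows), `excluded` (dropped rows
#'   plus a `reason` column) and `tally` (named integer vector over
#'   [exclusion_reasons()]).
#' @export
cohort_filter <- function(meta) {
  stopifnot(is.data.frame(meta))
  req <- c("rt_sampling_complete", "surgery_done_if_uapa", "followup_available")
  absent <- setdiff(req, names(meta))
  if (length(absent)) {
    abort_avs("avs_incomplete_metadata",
              sprintf("missing eligibility column(s): %s",
                      paste(absent, collapse = ", ")))
  }
  for (col in req) {
    if (anyNA(meta[[col]])) {
      abort_avs("avs_incomplete_metadata",
                sprintf("eligibility flag `%s` has missing values", col))
    }
  }
  n <- nrow(meta)
  postop_arr <- meta$postop_arr %||% rep(NA_real_, n)
  postop_bp <- meta$postop_bp_normal %||% rep(NA, n)

  fails <- list(
    rt_sampling_incomplete = !meta$rt_sampling_complete,
    uapa_without_surgery = !meta$surgery_done_if_uapa,
    postop_arr_not_normalized = !is.na(postop_arr) & postop_arr >= 200,
    postop_bp_not_normalized = !is.na(postop_bp) & !postop_bp,
    followup_unavailable = !meta$followup_available
  )
  reason <- rep(NA_character_, n)
  for (nm in rev(names(fails))) reason[fails[[nm]]] <- nm

  tally <- table(factor(reason, levels = exclusion_reasons()))
  tally <- stats::setNames(as.integer(tally), exclusion_reasons())
  excluded <- meta[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  list(included = meta[is.na(reason), , drop = FALSE],
       excluded = excluded,
       tally = tally)
}
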