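#' Run the full AVS analysis pipeline on a cohort
#'
#' Orchestrates the whole analysis: eligibility filtering, per-patient index
#' derivation, selectivity assessment, subtype classification (conventional
#' rule when the right adrenal vein was selective, modified-index fallback
#' otherwise), class-wise summary statistics, rank-sum group comparisons and
#' ROC/likelihood-ratio threshold tables. Deterministic given its input.
#'
#' @param cohort An `avs_cohort` (from [draw_cohort()] in mechanistic mode,
#'   or [read_cohort()]).
#' @param thresholds An [avs_thresholds()] object.
#' @param phase Phase whose measurements feed the indices.
#' @return An object of class `avs_report`: list with
#'   \describe{
#'     \item{per_patient}{indices, selectivity flags and subtype call per
#'       included patient}
#'     \item{exclusion_tally}{named counts per exclusion reason}
#'     \item{group_stats}{per-class n and mean/SD of both lateralized
#'       indices (and of the aldosterone-renin ratio when present)}
#'     \item{group_tests}{two-sided rank-sum comparisons between classes}
#'     \item{roc_table}{AUC and likelihood-ratio-maximizing threshold with
#'       its sensitivity/specificity, one row per diagnostic task}
#'   }
#' @export
run_pipeline <- function(cohort, thresholds = avs_thresholds(),
                         phase = c("post_acth", "pre_acth")) {
  phase <- match.arg(phase)
  stopifnot(inherits(cohort, "avs_cohort"))
  filt <- cohort_filter(cohort$meta)
  inc <- filt$included

  per_patient <- do.call(rbind, lapply(seq_len(nrow(inc)), function(i) {
    pid <- inc$patient_id[i]
    ms <- cohort$measurements[cohort$measurements$patient_id == pid, , drop = FALSE]
    ix <- compute_index_set(ms, phase)
    si_l_ok <- catheterization_success(ix$si_left, thresholds)
    si_r_ok <- catheterization_success(ix$si_right, thresholds)
    call <- adjudicate(ix, si_r_ok, thresholds)
    data.frame(patient_id = pid,
               class = if ("class" %in% names(inc)) inc$class[i] else NA_character_,
               si_left = ix$si_left, si_right = ix$si_right,
               si_left_ok = si_l_ok, si_right_ok = si_r_ok,
               ac_left = ix$ac_left, ac_right = ix$ac_right,
               ac_srt = ix$ac_srt,
               conventional_li = ix$conventional_li,
               dominant_side = ix$dominant_side,
               modified_li = ix$modified_li,
               call = call$label, rule = call$rule,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_patient)) {
    abort_avs("avs_invalid_input", "no patients survive the eligibility filter")
  }
  if ("arr" %in% names(inc)) {
    per_patient$arr <- inc$arr[match(per_patient$patient_id, inc$patient_id)]
  }

  grouping <- if (all(is.na(per_patient$class))) per_patient$call else per_patient$class
  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  group_stats <- do.call(rbind, lapply(avs_subtypes(), function(cls) {
    sel <- grouping == cls
    if (!any(sel)) return(NULL)
    row <- data.frame(class = cls, n = sum(sel),
                      conventional_li_mean = mean(per_patient$conventional_li[sel]),
                      conventional_li_sd = stats::sd(per_patient$conventional_li[sel]),
                      modified_li_mean = mean(per_patient$modified_li[sel]),
                      modified_li_sd = stats::sd(per_patient$modified_li[sel]),
                      stringsAsFactors = FALSE)
    if ("arr" %in% names(per_patient)) {
      row$arr_mean <- mean(per_patient$arr[sel])
      row$arr_sd <- stats::sd(per_patient$arr[sel])
    }
    row
  }))

  group_tests <- NULL
  pairs <- list(c("rt_APA", "IHA"), c("lt_APA", "IHA"), c("rt_APA", "lt_APA"))
  for (pr in pairs) {
    a <- per_patient$modified_li[grouping == pr[1]]
    b <- per_patient$modified_li[grouping == pr[2]]
    if (length(a) && length(b)) {
      ts <- rank_sum_test(a, b)
      group_tests <- rbind(group_tests, data.frame(
        variable = "modified_li", comparison = paste(pr, collapse = " vs "),
        statistic = unname(ts$statistic), p_value = ts$p_value,
        method = ts$method_used, stringsAsFactors = FALSE))
    }
  }
  uapa <- per_patient$conventional_li[grouping %in% c("rt_APA", "lt_APA")]
  iha <- per_patient$conventional_li[grouping == "IHA"]
  if (length(uapa) && length(iha)) {
    ts <- rank_sum_test(uapa, iha)
    group_tests <- rbind(group_tests, data.frame(
      variable = "conventional_li", comparison = "UAPA vs IHA",
      statistic = unname(ts$statistic), p_value = ts$p_value,
      method = ts$method_used, stringsAsFactors = FALSE))
  }

  roc_table <- NULL
  tasks <- list(
    list(variable = "conventional_li", task = "UAPA",
         labels = grouping %in% c("rt_APA", "lt_APA"),
         scores = per_patient$conventional_li, direction = "higher_is_positive"),
    list(variable = "modified_li", task = "rt_APA",
         labels = grouping == "rt_APA",
         scores = per_patient$modified_li, direction = "lower_is_positive"),
    list(variable = "modified_li", task = "lt_APA",
         labels = grouping == "lt_APA",
         scores = per_patient$modified_li, direction = "higher_is_positive")
  )
  for (tk in tasks) {
    if (!any(tk$labels) || all(tk$labels)) next
    curve <- roc_curve(tk$scores, tk$labels, tk$direction)
    best <- tryCatch(best_threshold_by_lr(curve), avs_no_finite_lr = function(e) NULL)
    roc_table <- rbind(roc_table, data.frame(
      variable = tk$variable, task = tk$task, direction = tk$direction,
      auc = auc_rank(tk$scores, tk$labels, tk$direction),
      threshold = if (is.null(best)) NA_real_ else best$threshold,
      sensitivity = if (is.null(best)) NA_real_ else best$sensitivity,
      specificity = if (is.null(best)) NA_real_ else best$specificity,
      lr_positive = if (is.null(best)) NA_real_ else best$lr_positive,
      stringsAsFactors = FALSE))
  }

  structure(list(per_patient = per_patient,
                 exclusion_tally = filt$tally,
                 group_stats = group_stats,
                 group_tests = group_tests,
                 roc_table = roc_table,
                 thresholds = thresholds, phase = phase),
            class = "avs_report")
}

#' @export
print.avs_report <- function(x, ...) {
  cat(sprintf("AVS analysis report (%s phase)\n", x$phase))
  cat(sprintf("  included: %d patients; excluded: %d (%s)\n",
              nrow(x$per_patient), sum(x$exclusion_tally),
              paste(sprintf("%s=%d", names(x$exclusion_tally), x$exclusion_tally),
                    collapse = ", ")))
  cat("\nGroup statistics:\n")
  print(x$group_stats, row.names = FALSE, digits = 3)
  if (!is.null(x$group_tests)) {
    cat("\nRank-sum comparisons:\n")
    print(x$group_tests, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$roc_table)) {
    cat("\nROC / likelihood-ratio thresholds:\n")
    print(x$roc_table, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a pipeline report to CSV files
#'
#' One CSV per report component, under `dir`. Re-running the pipeline on the
#' same cohort with the same configuration reproduces the files byte for
#' byte.
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "avs_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(per_patient = file.path(dir, "per_patient.csv"),
             exclusion_tally = file.path(dir, "exclusion_tally.csv"),
             group_stats = file.path(dir, "group_stats.csv"),
             group_tests = file.path(dir, "group_tests.csv"),
             roc_table = file.path(dir, "roc_table.csv"))
  utils::write.csv(report$per_patient, paths[["per_patient"]], row.names = FALSE)
  utils::write.csv(data.frame(reason = names(report$exclusion_tally),
                              n = unname(report$exclusion_tally)),
                   paths[["exclusion_tally"]], row.names = FALSE)
  utils::write.csv(report$group_stats, paths[["group_stats"]], row.names = FALSE)
  if (!is.null(report$group_tests)) {
    utils::write.csv(report$group_tests, paths[["group_tests"]], row.names = FALSE)
  }
  if (!is.null(report$roc_table)) {
    utils::write.csv(report$roc_table, paths[["roc_table"]], row.names = FALSE)
  }
  invisible(paths)
}
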