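# fixtures are built in code; no files

make_patient_measurements <- function(patient_id = "P1", phase = "post_acth",
                                      cortisol = c(ivc_low = 10, lt_adv = 250,
                                                   rt_adv = 300, s_rt_adv = 16),
                                      aldosterone = c(ivc_low = 150, lt_adv = 900,
                                                      rt_adv = 9000, s_rt_adv = 700)) {
  data.frame(patient_id = patient_id, site = avs_sites(), phase = phase,
             cortisol = unname(cortisol[avs_sites()]),
             aldosterone = unname(aldosterone[avs_sites()]),
             stringsAsFactors = FALSE)
}

# roster reproducing the study's exclusion cascade counts
make_roster <- function(n_ok = 44, n_rt = 9, n_surg = 2, n_arr = 2,
                        n_bp = 0, n_fu = 1) {
  n <- n_ok + n_rt + n_surg + n_arr + n_bp + n_fu
  meta <- data.frame(
    patient_id = sprintf("R%02d", seq_len(n)),
    rt_sampling_complete = rep(TRUE, n), surgery_done_if_uapa = rep(TRUE, n),
    postop_arr = rep(NA_real_, n), postop_bp_normal = rep(NA, n),
    followup_available = rep(TRUE, n), stringsAsFactors = FALSE
  )
  i <- n_ok
  if (n_rt) meta$rt_sampling_complete[i + seq_len(n_rt)] <- FALSE
  i <- i + n_rt
  if (n_surg) meta$surgery_done_if_uapa[i + seq_len(n_surg)] <- FALSE
  i <- i + n_surg
  if (n_arr) meta$postop_arr[i + seq_len(n_arr)] <- 250
  i <- i + n_arr
  if (n_bp) meta$postop_bp_normal[i + seq_len(n_bp)] <- FALSE
  i <- i + n_bp
  if (n_fu) meta$followup_available[i + seq_len(n_fu)] <- FALSE
  meta
}

# brute-force diagnostic counting at a cutoff, independent of roc_curve()
brute_sens_spec <- function(scores, labels, threshold, direction) {
  pos <- if (direction == "higher_is_positive") scores >= threshold else scores <= threshold
  c(sensitivity = sum(pos & labels) / sum(labels),
    specificity = sum(!pos & !labels) / sum(!labels))
}

# AUC by exhaustive pair enumeration
brute_auc <- function(scores, labels, direction) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    better <- if (direction == "higher_is_positive") p > q else p < q
    tot <- tot + better + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# hand-rolled avs_roc for threshold-choice unit tests
fake_roc <- function(threshold, sensitivity, specificity,
                     direction = "higher_is_positive") {
  lr <- ifelse(specificity < 1, sensitivity / (1 - specificity),
               ifelse(sensitivity > 0, Inf, NaN))
  structure(data.frame(threshold = threshold, sensitivity = sensitivity,
                       specificity = specificity, lr_positive = lr),
            class = c("avs_roc", "data.frame"), direction = direction,
            n_pos = 10L, n_neg = 10L)
}
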