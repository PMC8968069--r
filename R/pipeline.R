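# End-to-end orchestration: session -> traces -> channel selection ->
# window features -> cross-validated detection -> period-level evaluation.

#' Run the full state-detection analysis on a session
#'
#' @param session list with \code{recording}, \code{events}, \code{truth}
#'   (as from [simulate_session()] or [read_session()]).
#' @param window_ms sliding-window length (ms).
#' @param step_ms window step (ms).
#' @param feature_set \code{"four_type"} (default), \code{"all16"},
#'   \code{"single:<trace>:<op>"} (see [extract_features()]), or a
#'   comparator route \code{"ar"}, \code{"stft"}, \code{"wavelet"}
#'   (optionally \code{"<method>:<band>"}; default band high_gamma), which
#'   extracts that method's band feature from the notch-filtered,
#'   re-referenced broadband signal on the band's selected channels.
#' @param classifier \code{"hmm"}, \code{"lda"}, \code{"svm"} or
#'   \code{"rf"}.
#' @param three_class detect \{idle, own, other\} instead of
#'   \{idle, active\}.
#' @param select_alpha,select_n_perm channel-selection significance level and
#'   permutation count.
#' @param feature_n_perm permutations for feature-dimension selection.
#' @param keep feature dimensions kept (per contrast).
#' @param k_max maximum GMM components.
#' @param decode HMM decoding method.
#' @param seed integer seed for all stochastic stages.
#' @param selections optional precomputed channel selections (skips that
#'   stage).
#' @param traces optional precomputed trace list (skips preprocessing).
#' @param zero_phase zero-phase (default) or causal filtering throughout.
#' @return list of class \code{session_result}: \code{report} (a
#'   \code{detection_report}), \code{cv}, \code{features},
#'   \code{selections}, \code{windows}, and for three-class runs the
#'   \code{threeclass} tables.
#' @export
detect_session <- function(session, window_ms = 400, step_ms = 50,
                           feature_set = "four_type", classifier = "hmm",
                           three_class = FALSE, select_alpha = 0.05,
                           select_n_perm = 1000, feature_n_perm = 200,
                           keep = 10, k_max = 5, decode = "viterbi",
                           seed = 1, selections = NULL, traces = NULL,
                           zero_phase = TRUE) {
  rec <- session$recording
  events <- session$events
  truth <- session$truth
  comparator <- grepl("^(ar|stft|wavelet)(:|$)", feature_set[1])
  if (comparator) {
    parts <- strsplit(feature_set[1], ":")[[1]]
    method <- parts[1]
    band_kind <- if (length(parts) > 1) parts[2] else "high_gamma"
    kinds <- band_kind
  } else {
    fspec <- resolve_feature_set(feature_set,
                                 c("high_gamma", "beta", "alpha", "erp"))
    kinds <- unique(fspec$trace)
  }
  if (is.null(traces))
    traces <- compute_traces(rec, kinds = kinds, zero_phase = zero_phase)
  if (is.null(selections))
    selections <- select_channels_all(traces[kinds], events,
                                      alpha = select_alpha,
                                      n_perm = select_n_perm,
                                      seed = child_seed(seed, 101))
  windows <- make_windows(ncol(rec$data), rec$fs, window_ms = window_ms,
                          step_ms = step_ms)
  labels <- label_windows(windows, truth, collapse = !three_class)
  if (comparator) {
    reref <- laplacian_rereference(comb_notch(rec, zero_phase = zero_phase))
    feats <- extract_comparator_features(reref, selections[band_kind],
                                         windows, method = method,
                                         labels = labels)
  } else {
    selected_ids <- lapply(selections, function(s)
      if (is.character(s)) s else s$channel[s$selected])
    ztr <- smooth_traces(zscore_traces(
      subset_traces(traces[kinds], selected_ids), events))
    feats <- extract_features(ztr, selections, windows,
                              feature_set = fspec, labels = labels)
  }
  if (three_class) {
    tc <- detect_three_state(feats, keep = keep, n_perm = feature_n_perm,
                             k_max = k_max, seed = child_seed(seed, 202))
    cv <- tc$cv
    report <- suppressWarnings(
      evaluate_detection(collapse_to_active(cv$predictions),
                         collapse_to_active(labels), windows))
  } else {
    tc <- NULL
    cv <- run_cv(feats, classifier = classifier, keep = keep,
                 n_perm = feature_n_perm, k_max = k_max, decode = decode,
                 seed = child_seed(seed, 202))
    report <- evaluate_detection(cv$predictions, labels, windows)
  }
  structure(list(report = report, cv = cv, features = feats,
                 selections = selections, windows = windows,
                 threeclass = tc, classifier = classifier, seed = seed),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> classifier=%s seed=%s\n", x$classifier,
              format(x$seed)))
  print(x$report)
  invisible(x)
}

default_config <- function() {
  list(seed = 1,
       paradigm = list(n_trials = 120, stim_duration_ms = 1000,
                       iti_ms = c(1100, 1300), cue_ms = 100, prep_ms = 500,
                       fs = 1000),
       n_channels = 20,
       window_ms = 400, step_ms = 50,
       feature_set = "four_type", classifier = "hmm",
       three_class = FALSE,
       select_n_perm = 1000, feature_n_perm = 200, keep = 10, k_max = 5,
       chance = FALSE, chance_n_perm = 100, zero_phase = TRUE,
       input = NULL)
}

validate_config <- function(cfg) {
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  merged <- utils::modifyList(default_config(), cfg)
  if (!merged$classifier %in% c("hmm", "lda", "svm", "rf"))
    stop("classifier must be one of hmm/lda/svm/rf", call. = FALSE)
  if (!(merged$window_ms >= 150 && merged$window_ms <= 500))
    stop("window_ms must lie in [150, 500]", call. = FALSE)
  merged
}

#' Run the pipeline from a config file
#'
#' Reads a YAML (or list) configuration, simulates or loads a session, runs
#' the full analysis, and writes a run directory containing the detection
#' report (JSON), the channel-selection table and the per-window predictions
#' (TSV), together with the resolved configuration for reproducibility.  Two
#' runs with the same config and seed produce identical reports.
#'
#' @param config path to a YAML config file, or a named list.  Fields (all
#'   optional): \code{seed}, \code{paradigm} (n_trials, stim_duration_ms,
#'   iti_ms, cue_ms, prep_ms, fs), \code{n_channels}, \code{window_ms},
#'   \code{step_ms}, \code{feature_set}, \code{classifier},
#'   \code{three_class}, \code{select_n_perm}, \code{feature_n_perm},
#'   \code{keep}, \code{k_max}, \code{chance}, \code{chance_n_perm},
#'   \code{input} (a [write_session()] directory; omit to simulate).
#' @param out_dir run directory (created); \code{NULL} to skip writing.
#' @return the \code{session_result}, invisibly, with the report also under
#'   \code{$report_json}.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  session <- if (!is.null(cfg$input)) {
    if (!dir.exists(cfg$input)) stop("input session not found: ", cfg$input,
                                     call. = FALSE)
    read_session(cfg$input)
  } else {
    pc <- do.call(paradigm_config, cfg$paradigm)
    simulate_session(pc, n_channels = cfg$n_channels, seed = cfg$seed)
  }
  res <- detect_session(session, window_ms = cfg$window_ms,
                        step_ms = cfg$step_ms,
                        feature_set = cfg$feature_set,
                        classifier = cfg$classifier,
                        three_class = isTRUE(cfg$three_class),
                        select_n_perm = cfg$select_n_perm,
                        feature_n_perm = cfg$feature_n_perm,
                        keep = cfg$keep, k_max = cfg$k_max, seed = cfg$seed,
                        zero_phase = isTRUE(cfg$zero_phase))
  chance <- NULL
  if (isTRUE(cfg$chance))
    chance <- chance_level(res$features, classifier = cfg$classifier,
                           n_perm = cfg$chance_n_perm,
                           seed = child_seed(cfg$seed, 99))
  rep <- res$report
  report <- list(sensitivity = rep$sensitivity, precision = rep$precision,
                 accuracy = rep$accuracy,
                 counts = list(TP = rep$ledger$TP, FP = rep$ledger$FP,
                               FN = rep$ledger$FN, TN = rep$ledger$TN),
                 onset_diff_mean_s = rep$timing$onset_mean_s,
                 end_diff_mean_s = rep$timing$end_mean_s,
                 chance = chance[c("sensitivity", "precision", "accuracy")],
                 classifier = cfg$classifier, seed = cfg$seed,
                 config_hash = digest_config(cfg),
                 r_version = as.character(getRversion()))
  if (!is.null(res$threeclass))
    report$threeclass_period_table <- as.data.frame(
      res$threeclass$table_period)
  res$report_json <- report
  res$chance <- chance
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    write_selection_report(res$selections,
                           file.path(out_dir, "channel_selection.tsv"))
    utils::write.table(
      data.frame(start_s = res$windows$start_s, end_s = res$windows$end_s,
                 label = res$features$labels,
                 predicted = res$cv$predictions),
      file.path(out_dir, "predictions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

# Stable short hash of the resolved config (order-independent).
digest_config <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 4294967291)
}
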