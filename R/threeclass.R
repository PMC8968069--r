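# Three-class extension: idle / own name / other name.
#
# Feature selection is run once per state pair (idle-own, idle-other,
# own-other), keeping the ten smallest-p dimensions per pair; the final
# feature set is their union.  A single 3-state GMM-HMM decodes the stream.

#' Pairwise permutation feature selection for three states
#'
#' @param x training feature matrix.
#' @param labels3 factor with three levels (idle first).
#' @param keep_per_pair columns kept per state pair.
#' @param n_perm label shufflings per column.
#' @param seed integer seed.
#' @return data.frame of class \code{feature_selection} with \code{kept} =
#'   union of the three per-pair selections (at most \code{3 * keep_per_pair}
#'   columns) and a \code{pairs} attribute of per-pair results.
#' @export
select_feature_dims_pairwise <- function(x, labels3, keep_per_pair = 10,
                                         n_perm = 200, seed = NULL) {
  labels3 <- as.factor(labels3)
  lev <- levels(labels3)
  if (length(lev) != 3L || any(tabulate(labels3, 3) == 0))
    stop("all three states must be present", call. = FALSE)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  kept <- rep(FALSE, ncol(x))
  per_pair <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    rows <- labels3 %in% pr
    lab <- ifelse(labels3[rows] == pr[1], 1, -1)
    sel <- select_feature_dims(x[rows, , drop = FALSE], lab,
                               keep = keep_per_pair, n_perm = n_perm,
                               seed = child_seed(seed, pi))
    kept <- kept | sel$kept
    per_pair[[paste(pr, collapse = "-")]] <- sel
  }
  out <- data.frame(column = seq_len(ncol(x)), kept = kept)
  if (!is.null(colnames(x))) out$name <- colnames(x)
  attr(out, "pairs") <- per_pair
  class(out) <- c("feature_selection", "data.frame")
  out
}

# Modal label of the windows falling inside a period.
modal_state_in_period <- function(period, predictions, windows) {
  inside <- windows$mid_s >= period[1] & windows$mid_s < period[2]
  if (!any(inside)) return(NA_character_)
  tab <- table(predictions[inside])
  names(tab)[which.max(tab)]
}

# Row-normalised actual x detected state table (%), period level: actual
# periods are maximal runs of the actual label stream (idle runs included);
# each period is attributed the modal detected window label within it.
period_state_table <- function(predictions, labels, windows) {
  lev <- levels(labels)
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  counts <- matrix(0, length(lev), length(lev),
                   dimnames = list(actual = lev, detected = lev))
  for (i in seq_along(r$values)) {
    span <- c(windows$mid_s[starts[i]], windows$mid_s[ends[i]] +
                1e-9)  # half-open, include last midpoint
    det <- modal_state_in_period(span, predictions, windows)
    if (!is.na(det)) counts[r$values[i], det] <- counts[r$values[i], det] + 1
  }
  100 * counts / pmax(rowSums(counts), 1)
}

#' Three-class state detection with a single 3-state GMM-HMM
#'
#' Runs the cross-validated pipeline with pairwise feature selection and a
#' three-state HMM, and tabulates row-normalised actual-by-detected state
#' accuracies at both the period level (a period's detected state is the
#' modal window label within it) and the window level.
#'
#' @param features a \code{window_features} object whose labels have three
#'   levels (idle plus the two stimulus types).
#' @param ... passed to [run_cv()] (seed, keep, n_perm, k_max, ...).
#' @return list of class \code{threeclass_result}: \code{cv},
#'   \code{predictions}, \code{table_period}, \code{table_window}.
#' @export
detect_three_state <- function(features, ...) {
  labels <- features$labels
  if (nlevels(labels) != 3L)
    stop("three-class detection needs three label levels", call. = FALSE)
  cv <- run_cv(features, classifier = "hmm", pairwise = TRUE, ...)
  tw <- table(actual = labels, detected = cv$predictions)
  tw <- 100 * tw / pmax(rowSums(tw), 1)
  tp <- period_state_table(cv$predictions, labels, features$windows)
  structure(list(cv = cv, predictions = cv$predictions,
                 table_period = tp, table_window = tw),
            class = "threeclass_result")
}

#' Collapse three-class predictions to active/idle
#'
#' @param predictions factor with idle plus stimulus-type levels.
#' @return factor with levels \code{idle}, \code{active}.
#' @export
collapse_to_active <- function(predictions) {
  lev <- levels(predictions)
  factor(ifelse(predictions == lev[1], "idle", "active"),
         levels = c("idle", "active"))
}
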