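# Randomization (label-shuffling) Spearman test, shared by channel selection
# and feature-dimension selection.
#
# The observed statistic is the Spearman correlation between a value vector
# and its -1/+1 state labels.  Labels are shuffled n_perm times to build a
# surrogate r distribution; the p-value is read from a normal fit to the
# surrogates (default) or from the empirical tail.

# Spearman r of values against binary labels = Pearson r of rank(values)
# against labels (ranking a two-valued vector is an affine transform).
spearman_binary <- function(rank_values, labels) {
  suppressWarnings(stats::cor(rank_values, labels))
}

#' Permutation Spearman test of state-dependence
#'
#' @param values numeric vector (e.g. concatenated per-trial active and idle
#'   means, or one feature column across windows).
#' @param labels vector of -1/+1 state labels, same length as \code{values}.
#' @param n_perm number of label shufflings.
#' @param seed integer seed.
#' @param method \code{"normal"}: two-sided p from a normal distribution
#'   fitted to the surrogate r values; \code{"empirical"}: empirical tail
#'   proportion.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}
#'   (upper tail of r itself).
#' @return list of class \code{perm_result}: \code{r_obs}, \code{p},
#'   \code{surrogate_mean}, \code{surrogate_sd}, \code{n_perm}.
#' @export
permutation_spearman <- function(values, labels, n_perm = 1000, seed = NULL,
                                 method = c("normal", "empirical"),
                                 alternative = c("two.sided", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both labels must be present", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("constant values: correlation undefined, p set to 1", call. = FALSE)
    return(structure(list(r_obs = NA_real_, p = 1, surrogate_mean = NA_real_,
                          surrogate_sd = NA_real_, n_perm = n_perm),
                     class = "perm_result"))
  }
  rv <- rank(values)
  r_obs <- spearman_binary(rv, labels)
  local_seed(seed, {
    perms <- replicate(n_perm, sample(labels))
    r_s <- as.numeric(suppressWarnings(stats::cor(rv, perms)))
    p <- perm_pvalue(r_obs, r_s, method, alternative)
    structure(list(r_obs = r_obs, p = p, surrogate_mean = mean(r_s),
                   surrogate_sd = stats::sd(r_s), n_perm = n_perm),
              class = "perm_result")
  })
}

perm_pvalue <- function(r_obs, r_s, method, alternative) {
  if (method == "normal") {
    mu <- mean(r_s)
    sd_s <- stats::sd(r_s)
    if (!is.finite(sd_s) || sd_s == 0) return(1)
    z <- (r_obs - mu) / sd_s
    if (alternative == "two.sided") 2 * stats::pnorm(-abs(z))
    else stats::pnorm(-z)
  } else {
    if (alternative == "two.sided")
      (1 + sum(abs(r_s - mean(r_s)) >= abs(r_obs - mean(r_s)))) /
        (length(r_s) + 1)
    else (1 + sum(r_s >= r_obs)) / (length(r_s) + 1)
  }
}

# Vectorised version over columns of a matrix: one rank pass per column and
# one shuffled label matrix shared by all columns.  Returns a data.frame with
# one row per column (r_obs, p).
perm_spearman_columns <- function(x, labels, n_perm = 1000, seed = NULL,
                                  method = "normal",
                                  alternative = "two.sided") {
  nc <- ncol(x)
  local_seed(seed, {
    perms <- replicate(n_perm, sample(labels))
    r_obs <- rep(NA_real_, nc)
    p <- rep(1, nc)
    for (j in seq_len(nc)) {
      v <- x[, j]
      if (!all(is.finite(v))) stop("non-finite feature values", call. = FALSE)
      if (stats::sd(v) == 0) next  # degenerate column: p = 1
      rv <- rank(v)
      r_obs[j] <- spearman_binary(rv, labels)
      r_s <- as.numeric(suppressWarnings(stats::cor(rv, perms)))
      p[j] <- perm_pvalue(r_obs[j], r_s, method, alternative)
    }
    data.frame(column = seq_len(nc), r_obs = r_obs, p = p)
  })
}
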