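# Model-human alignment metrics: baseline-referenced CCI differences,
# accuracy/bias/normalized error, Lin's concordance correlation, the
# leave-one-out inter-human agreement, and its ratio (ncCCC).

#' Baseline-referenced CCI difference
#'
#' Element-wise `condition - baseline` on matched keys. Both inputs are data
#' frames with a `cci` column and identical key columns (any columns other
#' than `cci`); a key present in one table but not the other is an error.
#'
#' @param condition_cci,baseline_cci Data frames with key columns and `cci`.
#' @return Data frame with the keys of `condition_cci` and `delta_cci`.
#' @export
delta_cci <- function(condition_cci, baseline_cci) {
  keys <- setdiff(names(condition_cci), "cci")
  if (!identical(sort(keys), sort(setdiff(names(baseline_cci), "cci")))) {
    stop("condition and baseline tables must share key columns",
         call. = FALSE)
  }
  merged <- merge(condition_cci, baseline_cci, by = keys,
                  suffixes = c("_cond", "_base"), all = TRUE)
  if (any(is.na(merged$cci_cond)) || any(is.na(merged$cci_base))) {
    stop("key mismatch between condition and baseline tables",
         call. = FALSE)
  }
  out <- merged[keys]
  out$delta_cci <- merged$cci_cond - merged$cci_base
  out
}

human_mean_vector <- function(human_cci) {
  h <- as.matrix(human_cci)
  if (nrow(h) < 1 || ncol(h) < 1) stop("empty human matrix", call. = FALSE)
  colMeans(h)
}

#' Accuracy, bias and normalized error of a model against human data
#'
#' Accuracy is the Pearson correlation between the model's CCI vector and
#' the mean human CCI across conditions; bias is the mean of
#' (model - human mean); the normalized error is the RMSE between model and
#' human mean divided by the standard deviation of the human mean.
#'
#' @param model_cci Numeric vector of model CCIs over conditions.
#' @param human_cci Participants x conditions matrix of human CCIs (columns
#'   aligned with `model_cci`).
#' @param sd_denom `"sample"` (n - 1, default) or `"population"` (n)
#'   denominator for the human SD.
#' @return List with `accuracy`, `bias`, `normalized_error`; `accuracy` is
#'   `NA` (with a warning) when either vector has zero variance.
#' @export
accuracy_bias_error <- function(model_cci, human_cci,
                                sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  hm <- human_mean_vector(human_cci)
  if (length(model_cci) != length(hm)) {
    stop("model vector and human matrix disagree on conditions",
         call. = FALSE)
  }
  if (length(hm) < 3) stop("need at least 3 conditions", call. = FALSE)
  diffs <- model_cci - hm
  n <- length(hm)
  s <- stats::sd(hm)
  if (sd_denom == "population") s <- s * sqrt((n - 1) / n)
  if (stats::sd(model_cci) == 0 || s == 0) {
    warning("zero-variance input; accuracy undefined", call. = FALSE)
    r <- NA_real_
  } else {
    r <- stats::cor(model_cci, hm)
  }
  list(accuracy = r, bias = mean(diffs),
       normalized_error = sqrt(mean(diffs^2)) / s)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' measuring agreement in both correlation and scale/location. Population
#' (1/n) moments by default, following the concordance literature.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param denom `"population"` (1/n, default) or `"sample"` (1/(n-1))
#'   moments.
#' @return Scalar in [-1, 1].
#' @export
lin_ccc <- function(x, y, denom = c("population", "sample")) {
  denom <- match.arg(denom)
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  f <- if (denom == "population") (n - 1) / n else 1
  sxy <- stats::cov(x, y) * f
  sx <- stats::var(x) * f
  sy <- stats::var(y) * f
  2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
}

#' Leave-one-out inter-human agreement
#'
#' For each participant, Lin's CCC between their CCI vector and the mean
#' vector of all other participants; the agreement is the mean over
#' participants. This is the human reliability ceiling against which model
#' concordance is normalized.
#'
#' @param human_cci Participants x conditions matrix (>= 2 participants).
#' @param denom Moment convention passed to [lin_ccc()].
#' @return Scalar mean leave-one-out CCC, with attribute `"per_participant"`.
#' @export
loo_agreement <- function(human_cci, denom = "population") {
  if (is.null(dim(human_cci))) {
    stop("leave-one-out agreement needs at least 2 participants",
         call. = FALSE)
  }
  h <- as.matrix(human_cci)
  if (nrow(h) < 2) {
    stop("leave-one-out agreement needs at least 2 participants",
         call. = FALSE)
  }
  per <- vapply(seq_len(nrow(h)), function(i) {
    lin_ccc(h[i, ], colMeans(h[-i, , drop = FALSE]), denom = denom)
  }, numeric(1))
  structure(mean(per), per_participant = per)
}

#' Normalized concordance (ncCCC)
#'
#' Model-human agreement (Lin's CCC between the model vector and the mean
#' human vector) divided by the leave-one-out inter-human agreement. Values
#' above 1 mean the model tracks the mean human response more consistently
#' than individual humans agree with each other.
#'
#' @param model_cci Numeric vector of model CCIs over conditions.
#' @param human_cci Participants x conditions matrix.
#' @param denom Moment convention passed to [lin_ccc()].
#' @return Scalar ncCCC with attributes `"ccc"` and `"loo"`; `NA` with a
#'   warning when the leave-one-out agreement is zero.
#' @export
nccc <- function(model_cci, human_cci, denom = "population") {
  loo <- loo_agreement(human_cci, denom = denom)
  ccc <- lin_ccc(model_cci, human_mean_vector(human_cci), denom = denom)
  if (abs(as.numeric(loo)) < 1e-12) {
    warning("leave-one-out agreement is zero; ncCCC undefined",
            call. = FALSE)
    return(structure(NA_real_, ccc = ccc, loo = as.numeric(loo)))
  }
  structure(ccc / as.numeric(loo), ccc = ccc, loo = as.numeric(loo))
}

#' Full agreement report for one model
#'
#' Bundles [accuracy_bias_error()], [lin_ccc()], [loo_agreement()] and
#' [nccc()] for a model CCI vector against a human pool.
#'
#' @inheritParams nccc
#' @param grouping Optional label for the condition grouping (e.g. scene).
#' @return List of class `agreement_report`.
#' @export
agreement_report <- function(model_cci, human_cci, grouping = "all",
                             denom = "population") {
  abe <- accuracy_bias_error(model_cci, human_cci)
  loo <- loo_agreement(human_cci, denom = denom)
  nc <- nccc(model_cci, human_cci, denom = denom)
  structure(list(grouping = grouping, accuracy = abe$accuracy,
                 bias = abe$bias, normalized_error = abe$normalized_error,
                 ccc = attr(nc, "ccc"), loo = as.numeric(loo),
                 nccc = as.numeric(nc)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report [%s]> accuracy = %.3f, ",
                     "bias = %.2f, n.err = %.3f, CCC = %.3f, ",
                     "LOO = %.3f, ncCCC = %.3f\n"),
              x$grouping, x$accuracy, x$bias, x$normalized_error,
              x$ccc, x$loo, x$nccc))
  invisible(x)
}
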