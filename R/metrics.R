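#' @include AllClasses.R
NULL

#' Multiclass confusion counts
#'
#' @param truth,predicted Integer class codes of equal length.
#' @param nClasses Number of classes (codes 0..nClasses-1).
#' @return A \linkS4class{ConfusionCounts} (rows = truth, cols = predicted).
#' @export
confusionCounts <- function(truth, predicted, nClasses = 4L) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (any(truth >= nClasses | truth < 0) ||
      any(predicted >= nClasses | predicted < 0))
    stop("labels must be in 0..nClasses-1")
  cls <- 0:(nClasses - 1L)
  tab <- table(factor(truth, levels = cls), factor(predicted, levels = cls))
  new("ConfusionCounts",
      table = matrix(as.integer(tab), nClasses, nClasses,
                     dimnames = dimnames(tab)),
      classes = as.integer(cls))
}

#' One-vs-rest counts for a class
#'
#' @param cc A \linkS4class{ConfusionCounts}.
#' @param class Class code.
#' @return Named vector (TP, FP, TN, FN).
#' @export
classCounts <- function(cc, class) {
  i <- match(class, cc@classes)
  if (is.na(i)) stop("unknown class")
  tab <- cc@table
  TP <- tab[i, i]
  FP <- sum(tab[-i, i])
  FN <- sum(tab[i, -i])
  TN <- sum(tab) - TP - FP - FN
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Overall accuracy
#'
#' Fraction of correctly classified samples (trace of the confusion matrix
#' over the total count).
#'
#' @param cc A \linkS4class{ConfusionCounts}.
#' @return Proportion in [0, 1].
#' @export
overallAccuracy <- function(cc) {
  sum(diag(cc@table)) / sum(cc@table)
}

#' Per-class sensitivity (recall): TP / (TP + FN)
#'
#' @param cc A \linkS4class{ConfusionCounts}.
#' @param class Class code.
#' @return Proportion, or NA when the class has no positives.
#' @export
sensitivity <- function(cc, class) {
  k <- classCounts(cc, class)
  if (k["TP"] + k["FN"] == 0) return(NA_real_)
  unname(k["TP"] / (k["TP"] + k["FN"]))
}

#' Per-class specificity: TN / (TN + FP)
#'
#' @param cc A \linkS4class{ConfusionCounts}.
#' @param class Class code.
#' @return Proportion, or NA when the class has no negatives.
#' @export
specificity <- function(cc, class) {
  k <- classCounts(cc, class)
  if (k["TN"] + k["FP"] == 0) return(NA_real_)
  unname(k["TN"] / (k["TN"] + k["FP"]))
}

#' Per-class accuracy (alias of sensitivity)
#'
#' In a multiclass problem the per-class accuracy TP / (TP + FN) equals the
#' class sensitivity; the alias keeps the figure-of-merit formula readable.
#'
#' @inheritParams sensitivity
#' @export
accPerClass <- function(cc, class) sensitivity(cc, class)

#' Matthews correlation coefficient (one-vs-rest)
#'
#' \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}, defined as
#' 0 when any factor of the denominator is zero.
#'
#' @inheritParams sensitivity
#' @return Value in [-1, 1].
#' @export
mcc <- function(cc, class) {
  k <- as.numeric(classCounts(cc, class))
  names(k) <- c("TP", "FP", "TN", "FN")
  den <- (k["TP"] + k["FP"]) * (k["TP"] + k["FN"]) *
    (k["TN"] + k["FP"]) * (k["TN"] + k["FN"])
  if (den == 0) return(0)
  unname((k["TP"] * k["TN"] - k["FP"] * k["FN"]) / sqrt(den))
}

#' Normalized Matthews correlation coefficient: (MCC + 1) / 2
#'
#' @inheritParams sensitivity
#' @return Value in [0, 1].
#' @export
mccNorm <- function(cc, class) (mcc(cc, class) + 1) / 2

#' Pairwise balanced figure of merit
#'
#' Rewards accuracy profiles that are both high and balanced across
#' classes:
#' \deqn{FoM = \frac{1}{2} \left( \sum_{i<j} \frac{ACC_i + ACC_j}{|ACC_i - ACC_j| + 1} \right) \binom{n}{2}^{-1}}
#' Equal accuracies give \code{FoM = mean(accs)}; imbalance between a pair
#' shrinks that pair's contribution.
#'
#' @param accs Per-class accuracies in [0, 1], length >= 2 (NA not allowed).
#' @return Score in [0, 1].
#' @examples
#' fom(c(1, 0))    # 0.25
#' fom(c(1, 1, 1)) # 1
#' @export
fom <- function(accs) {
  n <- length(accs)
  if (n < 2) stop("fom requires at least 2 per-class accuracies")
  if (any(is.na(accs)) || any(accs < 0 | accs > 1))
    stop("accuracies must be in [0, 1]")
  pairs <- combn(n, 2)
  s <- sum((accs[pairs[1, ]] + accs[pairs[2, ]]) /
             (abs(accs[pairs[1, ]] - accs[pairs[2, ]]) + 1))
  0.5 * s / choose(n, 2)
}

#' Penalized band-selection fitness
#'
#' Combines the classification error of a base metric (OA or FoM) with a
#' multiplicative penalty growing with the fraction of bands used:
#' \code{(1 - base) * (1 + lambda / lambdaMax)}. Lower is better; a perfect
#' base metric gives 0 regardless of subset size, and for a fixed base the
#' value strictly increases with the number of selected bands.
#'
#' @param base Base metric value in [0, 1] (OA or FoM).
#' @param nSelected Number of selected bands (lambda, >= 1).
#' @param nTotal Total number of bands (lambdaMax).
#' @param which Base metric tag, "oa_p" or "fom_p".
#' @return A \linkS4class{FitnessValue}.
#' @examples
#' fitnessValue(penalizedFitness(0.8, 48, 128))  # 0.275
#' @export
penalizedFitness <- function(base, nSelected, nTotal,
                             which = c("oa_p", "fom_p")) {
  which <- match.arg(which)
  if (is.na(base) || base < 0 || base > 1)
    stop("base metric must be in [0, 1]")
  if (nSelected < 1 || nSelected > nTotal)
    stop("nSelected must be in 1..nTotal")
  new("FitnessValue",
      value = (1 - base) * (1 + nSelected / nTotal),
      baseMetric = which, nSelected = as.integer(nSelected),
      nTotal = as.integer(nTotal))
}

#' Numeric value of a FitnessValue
#' @param x A \linkS4class{FitnessValue}.
#' @export
fitnessValue <- function(x) x@value

#' Full metrics report from confusion counts
#'
#' Computes OA, per-class sensitivity/specificity/MCC/normalized MCC and
#' the figure of merit over the per-class accuracies (classes with no
#' positives in the truth are excluded from the FoM).
#'
#' @param cc A \linkS4class{ConfusionCounts}.
#' @return A \linkS4class{MetricsReport}.
#' @export
metricsReport <- function(cc) {
  cls <- cc@classes
  nm <- if (length(cls) == 4 && all(cls == 0:3)) .CLASS_NAMES
        else paste0("class_", cls)
  sens <- vapply(cls, function(c) sensitivity(cc, c), numeric(1))
  spec <- vapply(cls, function(c) specificity(cc, c), numeric(1))
  m <- vapply(cls, function(c) mcc(cc, c), numeric(1))
  names(sens) <- names(spec) <- names(m) <- nm
  accs <- sens[!is.na(sens)]
  f <- if (length(accs) >= 2) fom(accs) else NA_real_
  new("MetricsReport", confusion = cc, oa = overallAccuracy(cc),
      sensitivity = sens, specificity = spec, mcc = m,
      mccNorm = (m + 1) / 2, fom = f)
}

#' Aggregate per-fold metrics reports
#'
#' @param reports List of \linkS4class{MetricsReport}s (one per fold).
#' @return data.frame with one row per metric: mean and sd across folds
#'   (NA entries dropped per metric).
#' @export
aggregateReports <- function(reports) {
  pull <- function(r) c(oa = r@oa, fom = r@fom,
                        stats::setNames(r@sensitivity,
                                        paste0("sens_", names(r@sensitivity))),
                        stats::setNames(r@specificity,
                                        paste0("spec_", names(r@specificity))),
                        stats::setNames(r@mccNorm,
                                        paste0("mccn_", names(r@mccNorm))))
  M <- vapply(reports, pull, pull(reports[[1]]))
  data.frame(metric = rownames(M),
             mean = apply(M, 1, mean, na.rm = TRUE),
             sd = apply(M, 1, sd, na.rm = TRUE),
             row.names = NULL)
}

#' Export an aggregated metrics table as CSV
#'
#' Writes the fold-aggregated metric table (mean and standard deviation per
#' metric, per-class sensitivity/specificity/normalized MCC rows) in a
#' layout mirroring the usual published summary tables.
#'
#' @param summary data.frame from \code{\link{aggregateReports}}.
#' @param path Output .csv path.
#' @export
exportMetricsCSV <- function(summary, path) {
  data.table::fwrite(summary, path)
  invisible(path)
}
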