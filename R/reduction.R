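#' @include AllClasses.R
NULL

#' Spectral angle between two spectra
#'
#' The angle between two spectra viewed as vectors,
#' \code{acos((a . b) / (|a| |b|))}, in radians. Brightness-insensitive:
#' scaling either spectrum leaves the angle unchanged.
#'
#' @param a,b Numeric vectors of equal length, both nonzero.
#' @return Angle in radians, in [0, pi].
#' @examples
#' spectralAngle(c(1, 1), c(1, 0))  # pi/4
#' @export
spectralAngle <- function(a, b) {
  if (length(a) != length(b)) stop("spectra must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined angle for a zero vector")
  acos(min(1, max(-1, sum(a * b) / (na * nb))))
}

#' Training-set reduction configuration
#'
#' Defaults follow the standard recipe: 100 clusters per class with the 10
#' spectrally most similar pixels kept per centroid, i.e. 1000 prototype
#' pixels per class and 4000 in total for four classes.
#'
#' @param kPerClass Number of k-means clusters per class (default 100).
#' @param pixelsPerCentroid Prototypes kept per centroid (default 10).
#' @param seed Integer seed for the clustering.
#' @return A classed list of settings.
#' @export
reductionConfig <- function(kPerClass = 100L, pixelsPerCentroid = 10L,
                            seed = 1L) {
  stopifnot(kPerClass >= 1L, pixelsPerCentroid >= 1L)
  structure(list(kPerClass = as.integer(kPerClass),
                 pixelsPerCentroid = as.integer(pixelsPerCentroid),
                 seed = as.integer(seed)),
            class = "reductionConfig")
}

## Angles from every class pixel (columns of M, bands x n) to each centroid
## (rows of C, k x bands); returns n x k matrix.
.anglesToCentroids <- function(M, C) {
  Mn <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  Cn <- C / sqrt(rowSums(C^2))
  cosv <- crossprod(Mn, t(Cn))
  cosv[cosv > 1] <- 1; cosv[cosv < -1] <- -1
  acos(cosv)
}

#' Reduce a labeled training set to balanced spectral prototypes
#'
#' For each class independently: cluster the class pixels with seeded
#' k-means (Euclidean distance, \code{kPerClass} clusters), then for each
#' centroid in index order select the \code{pixelsPerCentroid} class pixels
#' with the smallest spectral angle to that centroid. Selection is without
#' replacement across centroids of the same class, so the per-class quota is
#' met by distinct original pixels. With the defaults and four classes the
#' result is 4 x 100 x 10 = 4000 prototype pixels, class-balanced.
#'
#' Classes with fewer than \code{kPerClass * pixelsPerCentroid} pixels get a
#' proportionally reduced cluster count (with a warning) so the procedure
#' stays total on small datasets.
#'
#' @param data A \linkS4class{LabeledDataset} containing all four classes.
#' @param cfg A \code{\link{reductionConfig}}.
#' @return A \linkS4class{LabeledDataset} of prototype pixels (a subset of
#'   the input columns, original patient/image ids preserved).
#' @export
reduceTrainingSet <- function(data, cfg = reductionConfig()) {
  labs <- pixelLabels(data)
  present <- sort(unique(labs))
  missing <- setdiff(0:3, present)
  if (length(missing))
    stop("class absent from data: ",
         paste(.CLASS_NAMES[missing + 1L], collapse = ", "))
  M <- spectra(data)
  keep <- integer(0)
  withr::with_seed(cfg$seed, {
    for (cl in 0:3) {
      idx <- which(labs == cl)
      n <- length(idx)
      k <- cfg$kPerClass
      p <- cfg$pixelsPerCentroid
      if (n < k * p) {
        k <- max(1L, n %/% p)
        p <- min(p, n)
        warning(sprintf(
          "class %s has %d pixels < quota; reduced to %d clusters",
          .CLASS_NAMES[cl + 1L], n, k))
      }
      X <- t(M[, idx, drop = FALSE])  # pixels x bands for kmeans
      km <- suppressWarnings(
        kmeans(X, centers = k, nstart = 10L, iter.max = 50L))
      ang <- .anglesToCentroids(M[, idx, drop = FALSE], km$centers)
      taken <- logical(n)
      for (j in seq_len(k)) {
        ord <- order(ang[, j])
        free <- ord[!taken[ord]]
        pick <- head(free, p)
        taken[pick] <- TRUE
        keep <- c(keep, idx[pick])
      }
    }
  })
  data[, sort(keep)]
}
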