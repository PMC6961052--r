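#' @include AllClasses.R
NULL

#' Aggregate per-fold band subsets into coincidence levels
#'
#' Level \code{L_i} is the set of bands selected in at least \code{i} of
#' the per-fold subsets: \code{L_1} is the union of all subsets (coincident
#' and non-coincident bands) and levels are nested, each contained in the
#' previous one. Band identity is by index on the shared grid.
#'
#' @param bandSets List of \linkS4class{BandSubset}s over the same grid.
#' @return A \linkS4class{CoincidenceLevels}.
#' @examples
#' s <- function(i) bandSubset(i, nTotal = 10)
#' cl <- computeLevels(list(s(c(1, 2)), s(c(2, 3)), s(c(3, 4))))
#' bandIndices(coincidentBands(cl, 2))  # 2 3
#' @export
computeLevels <- function(bandSets) {
  if (!length(bandSets)) stop("need at least one band set")
  nt <- unique(vapply(bandSets, function(s) s@nTotal, integer(1)))
  if (length(nt) != 1L) stop("band sets are on mismatched grids")
  wl <- numeric(0)
  for (s in bandSets) if (length(s@wavelengths)) { wl <- s@wavelengths; break }
  counts <- integer(nt)
  for (s in bandSets)
    counts[s@indices] <- counts[s@indices] + 1L
  nf <- length(bandSets)
  levels <- lapply(seq_len(nf), function(i) {
    idx <- which(counts >= i)
    if (!length(idx)) return(NULL)
    if (length(wl)) new("BandSubset", indices = idx, nTotal = nt,
                        wavelengths = wl)
    else new("BandSubset", indices = idx, nTotal = nt,
             wavelengths = numeric(0))
  })
  new("CoincidenceLevels", levels = levels, nFolds = as.integer(nf))
}

#' Extract one coincidence level
#'
#' @param x A \linkS4class{CoincidenceLevels}.
#' @param i Level index (bands selected in >= i folds).
#' @return A \linkS4class{BandSubset}, or NULL when the level is empty.
#' @export
coincidentBands <- function(x, i) {
  if (i < 1L || i > length(x@levels)) stop("level out of range")
  x@levels[[i]]
}

#' Contiguous spectral ranges of a band subset
#'
#' Merges the selected bands into wavelength intervals, bridging gaps of at
#' most \code{gapTolerance} unselected bands (default 0: only adjacent
#' bands merge). A single isolated band yields a zero-width range.
#'
#' @param subset A \linkS4class{BandSubset} carrying wavelengths.
#' @param gapTolerance Maximum bridged gap, in bands.
#' @return data.frame with columns \code{from_nm}, \code{to_nm},
#'   \code{n_bands}.
#' @export
contiguousRanges <- function(subset, gapTolerance = 0L) {
  idx <- subset@indices
  wl <- subset@wavelengths
  if (!length(wl)) stop("band subset carries no wavelength axis")
  brk <- c(0L, which(diff(idx) > gapTolerance + 1L), length(idx))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(r) {
    run <- idx[(brk[r] + 1L):brk[r + 1L]]
    data.frame(from_nm = wl[run[1L]], to_nm = wl[run[length(run)]],
               n_bands = length(run))
  }))
  rownames(out) <- NULL
  out
}

#' Re-evaluate the pipeline at each coincidence level
#'
#' Runs the supplied harness (typically a full leave-one-patient-out
#' evaluation) restricted to each level's bands. Empty levels are skipped
#' with a warning.
#'
#' @param levels A \linkS4class{CoincidenceLevels}.
#' @param evalHarness Function(\linkS4class{BandSubset}) -> result.
#' @return Named list of results (L1, L2, ...), NULL for skipped levels.
#' @export
evaluateLevels <- function(levels, evalHarness) {
  out <- vector("list", length(levels@levels))
  names(out) <- paste0("L", seq_along(out))
  for (i in seq_along(out)) {
    lv <- levels@levels[[i]]
    if (is.null(lv)) {
      warning(sprintf("level L%d is empty; skipped", i))
      next
    }
    out[[i]] <- evalHarness(lv)
  }
  out
}
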