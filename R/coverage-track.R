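#' Coverage tracks
#'
#' A coverage track is per-chromosome piecewise-constant signal, stored as a
#' run-length encoded vector ([S4Vectors::Rle]) per chromosome, with a strand
#' label (`"+"`, `"-"`, or `"unstranded"`) and a multiplicative
#' `scale_factor` applied at query time. Position `p` (0-based) maps to Rle
#' element `p + 1`; every position outside the encoded extent reads as 0,
#' matching depth-of-coverage semantics.
#'
#' @param runs a `data.frame` with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals), or a named list of numeric [S4Vectors::Rle]
#'   vectors.
#' @param strand `"+"`, `"-"` or `"unstranded"`.
#' @param scale_factor positive multiplier applied to all queried values.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(runs, strand = "unstranded", scale_factor = 1) {
  stopifnot(strand %in% c("+", "-", "unstranded"), scale_factor > 0,
            is.finite(scale_factor))
  if (is.data.frame(runs)) {
    rle_list <- runs_to_rle(runs)
  } else if (is.list(runs)) {
    if (length(runs) && is.null(names(runs))) stop("Rle list must be named by chromosome")
    rle_list <- runs
  } else {
    stop("runs must be a data.frame of (chrom,start,end,value) or a named Rle list")
  }
  structure(
    list(rle = rle_list, strand = strand, scale_factor = scale_factor),
    class = "coverage_track"
  )
}

runs_to_rle <- function(runs) {
  req <- c("chrom", "start", "end", "value")
  if (!all(req %in% names(runs))) {
    stop("coverage runs need columns: ", paste(req, collapse = ", "))
  }
  if (any(runs$start >= runs$end)) stop("coverage runs must have start < end")
  if (any(runs$start < 0)) stop("coverage runs must have start >= 0")
  if (any(!is.finite(runs$value))) stop("coverage values must be finite")
  if (any(runs$value < 0)) stop("coverage values must be >= 0")
  out <- list()
  for (chr in unique(runs$chrom)) {
    r <- runs[runs$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    overlaps <- which(r$start[-1] < r$end[-nrow(r)])
    if (length(overlaps)) {
      bad <- overlaps[r$value[overlaps] != r$value[overlaps + 1L]]
      if (length(bad)) {
        stop(sprintf("overlapping runs with unequal values on %s near position %d",
                     chr, r$start[bad[1] + 1L]))
      }
      # equal-valued overlaps: truncate the earlier run
      r$end[overlaps] <- r$start[overlaps + 1L]
      r <- r[r$start < r$end, , drop = FALSE]
    }
    out[[chr]] <- rle_from_sorted_runs(r$start, r$end, r$value)
  }
  out
}

# Non-overlapping sorted runs -> Rle over [0, max(end)), gaps filled with 0.
rle_from_sorted_runs <- function(start, end, value) {
  gaps <- start - c(0L, end[-length(end)])
  vals <- as.vector(rbind(0, value))
  lens <- as.vector(rbind(gaps, end - start))
  keep <- lens > 0
  S4Vectors::Rle(vals[keep], lens[keep])
}

#' @export
print.coverage_track <- function(x, ...) {
  ext <- vapply(x$rle, length, integer(1))
  cat(sprintf("coverage_track [%s, scale %.4g]: %d chromosome(s)\n",
              x$strand, x$scale_factor, length(x$rle)))
  for (chr in names(x$rle)) cat(sprintf("  %s: %d bp encoded\n", chr, ext[[chr]]))
  invisible(x)
}

#' Windowed statistics on a coverage track
#'
#' Computes the per-window mean or sum of per-base signal over 0-based
#' half-open windows, with the track's `scale_factor` applied. Positions
#' outside the encoded extent (including negative coordinates after clipping
#' upstream extensions) contribute 0 to sums, and windows keep their nominal
#' length in the mean's denominator.
#'
#' @param track a [coverage_track()].
#' @param chrom,start,end parallel vectors of windows.
#' @param stat `"mean"` or `"sum"`.
#' @return Numeric vector, one value per window; `NA` for windows with
#'   non-positive length.
#' @export
track_window_stat <- function(track, chrom, start, end, stat = c("mean", "sum")) {
  stopifnot(inherits(track, "coverage_track"))
  stat <- match.arg(stat)
  n <- length(start)
  stopifnot(length(chrom) == n, length(end) == n)
  out <- rep(NA_real_, n)
  width <- end - start
  ok <- which(width > 0)
  for (chr in unique(chrom[ok])) {
    idx <- ok[chrom[ok] == chr]
    rle <- track$rle[[chr]]
    len <- if (is.null(rle)) 0L else length(rle)
    sums <- numeric(length(idx))
    if (len > 0L) {
      s <- pmax(start[idx], 0L)
      e <- pmin(end[idx], len)
      has <- which(s < e)
      if (length(has)) {
        v <- IRanges::Views(rle, start = s[has] + 1L, end = e[has])
        sums[has] <- IRanges::viewSums(v)
      }
    }
    out[idx] <- sums * track$scale_factor
  }
  if (stat == "mean") out[ok] <- out[ok] / width[ok]
  out[width <= 0] <- NA_real_
  out
}

#' Rescale a coverage track
#'
#' Returns the same track with its scale factor multiplied by `factor`
#' (e.g. a spike-in scale factor from [chip_scale_factors()]).
#'
#' @param track a [coverage_track()].
#' @param factor positive multiplier.
#' @return A `coverage_track`.
#' @export
scale_track <- function(track, factor) {
  stopifnot(inherits(track, "coverage_track"), factor > 0, is.finite(factor))
  track$scale_factor <- track$scale_factor * factor
  track
}

#' Binned ratio of two coverage tracks
#'
#' Computes, per fixed-width bin, `(mean_num + pseudocount) /
#' (mean_den + pseudocount)` after applying each track's scale factor — the
#' track-level analogue of bigwigCompare-style ratio tracks used for
#' pSer2/RPB1 and TT-seq/pSer2 comparisons.
#'
#' @param numerator,denominator [coverage_track()] objects on the same
#'   chromosome universe.
#' @param bin bin width in bp (default 10).
#' @param pseudocount added to both binned means before the ratio (default 1).
#' @return An unstranded `coverage_track` of binned ratio values.
#' @export
ratio_track <- function(numerator, denominator, bin = 10L, pseudocount = 1) {
  stopifnot(inherits(numerator, "coverage_track"),
            inherits(denominator, "coverage_track"),
            bin >= 1, pseudocount >= 0)
  chr_num <- names(numerator$rle)
  chr_den <- names(denominator$rle)
  if (!setequal(chr_num, chr_den)) {
    stop("numerator and denominator tracks cover different chromosome universes")
  }
  bin <- as.integer(bin)
  out <- list()
  for (chr in chr_num) {
    len <- max(length(numerator$rle[[chr]]), length(denominator$rle[[chr]]))
    n_bins <- ceiling(len / bin)
    starts <- (seq_len(n_bins) - 1L) * bin
    ends <- pmin(starts + bin, len)
    m_num <- track_window_stat(numerator, rep(chr, n_bins), starts, ends, "mean")
    m_den <- track_window_stat(denominator, rep(chr, n_bins), starts, ends, "mean")
    vals <- (m_num + pseudocount) / (m_den + pseudocount)
    out[[chr]] <- S4Vectors::Rle(vals, ends - starts)
  }
  coverage_track(out, strand = "unstranded", scale_factor = 1)
}
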