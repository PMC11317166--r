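#' Spike-in scale factors for coverage tracks
#'
#' ChIP-style spike-in normalization: each sample's track is rescaled in
#' proportion to the reciprocal of its spike-in (e.g. hg19) read count, so
#' that spike-in-implied depth is equalized across samples. The factors are
#' rescaled to geometric mean 1 (only the proportionality is substantive;
#' the overall scale is a convention).
#'
#' @param spike_read_counts named numeric vector of per-sample spike-in read
#'   counts, all strictly positive.
#' @return Numeric vector of scale factors `s_j` with geometric mean 1, plus
#'   attribute `method = "chip_reciprocal"`.
#' @export
chip_scale_factors <- function(spike_read_counts) {
  x <- as.numeric(spike_read_counts)
  if (length(x) < 1) stop("need at least one sample")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("spike-in read counts must be positive (zero spike-in reads cannot anchor a scale factor)")
  }
  s <- 1 / x
  s <- s / exp(mean(log(s)))
  names(s) <- names(spike_read_counts)
  attr(s, "method") <- "chip_reciprocal"
  s
}

#' Spike-in size factors for count matrices
#'
#' Median-of-ratios size factors computed over spike-in genes only:
#' `s_j = median_g( N_gj / geomean_j'(N_gj') )` with the median taken over
#' spike-in genes whose geometric mean across samples is positive. Because
#' only spike-in genes enter, the factors are invariant to any change in
#' target-gene counts — the central spike-in guarantee under global
#' repression. With fewer than `min_genes` usable spike-in genes the total
#' spike-in count ratio is used instead (with a warning).
#'
#' @param counts a [count_matrix()] with at least one spike-in gene.
#' @param min_genes minimum usable spike-in genes for the median-of-ratios
#'   estimator (default 5).
#' @return Numeric size factors per sample with a `method` attribute
#'   (`"median_of_ratios_spikein"` or `"total_spikein"`).
#' @export
spikein_size_factors <- function(counts, min_genes = 5L) {
  stopifnot(inherits(counts, "count_matrix"))
  sp <- counts$counts[counts$species == "spikein", , drop = FALSE]
  if (nrow(sp) == 0) stop("no spikein genes in count matrix")
  geo <- exp(rowMeans(log(sp)))        # 0 whenever any sample has a zero
  usable <- is.finite(geo) & geo > 0
  if (!any(usable)) stop("no spikein gene has nonzero counts in every sample")
  if (sum(usable) >= min_genes) {
    # median taken in log space (the reference estimator's convention;
    # identical to the ratio-space median except at even-count ties)
    lr <- log(sp[usable, , drop = FALSE]) - log(geo[usable])
    s <- exp(apply(lr, 2, stats::median))
    method <- "median_of_ratios_spikein"
  } else {
    warning("only ", sum(usable), " usable spikein gene(s); ",
            "falling back to total spike-in count ratio")
    tot <- colSums(sp)
    if (any(tot == 0)) stop("a sample has zero total spike-in counts")
    s <- tot / exp(mean(log(tot)))
    method <- "total_spikein"
  }
  if (any(s <= 0)) stop("degenerate size factor (<= 0); check spike-in counts")
  names(s) <- colnames(counts$counts)
  attr(s, "method") <- method
  s
}

#' Naive (spike-in-blind) size factors
#'
#' Library-size estimators a practitioner would use without spike-ins:
#' DESeq-style median-of-ratios over all genes (default) or total-count
#' ratios. Under a global repression regime these estimators absorb the
#' repression into the size factor and make unchanged genes look induced —
#' the hazard spike-in normalization exists to avoid. Provided for the
#' directional contrast, not for routine use.
#'
#' @param counts a [count_matrix()].
#' @param method `"median_of_ratios"` or `"total"`.
#' @return Numeric size factors per sample with a `method` attribute.
#' @export
naive_size_factors <- function(counts, method = c("median_of_ratios", "total")) {
  stopifnot(inherits(counts, "count_matrix"))
  method <- match.arg(method)
  m <- counts$counts
  if (method == "median_of_ratios") {
    geo <- exp(rowMeans(log(m)))
    usable <- is.finite(geo) & geo > 0
    if (!any(usable)) stop("no gene has nonzero counts in every sample")
    lr <- log(m[usable, , drop = FALSE]) - log(geo[usable])
    s <- exp(apply(lr, 2, stats::median))
  } else {
    tot <- colSums(m)
    if (any(tot == 0)) stop("a sample has zero total counts")
    s <- tot / exp(mean(log(tot)))
  }
  names(s) <- colnames(m)
  attr(s, "method") <- paste0("naive_", method)
  s
}

#' RPKM / TPM expression matrices
#'
#' `RPKM_gj = N_gj * 1e9 / (L_g * sum_g N_gj)`;
#' `TPM_gj = (N_gj / L_g) * 1e6 / sum_g'(N_g'j / L_g')`.
#' Spike-in genes are excluded both from the returned rows and from the
#' per-sample denominators: their abundance reflects the mixing ratio, not
#' the transcriptome.
#'
#' @param counts a [count_matrix()].
#' @param unit `"RPKM"` or `"TPM"`.
#' @return Numeric matrix (target genes x samples) with attribute `unit`.
#' @export
rpkm_tpm <- function(counts, unit = c("RPKM", "TPM")) {
  stopifnot(inherits(counts, "count_matrix"))
  unit <- match.arg(unit)
  keep <- counts$species == "target"
  m <- counts$counts[keep, , drop = FALSE]
  len <- counts$lengths[keep]
  if (unit == "RPKM") {
    lib <- colSums(m)
    if (any(lib == 0)) stop("zero library size over target genes")
    out <- sweep(m, 2, lib, "/") * 1e9 / len
  } else {
    rate <- m / len
    denom <- colSums(rate)
    if (any(denom == 0)) stop("zero total length-normalized counts")
    out <- sweep(rate, 2, denom, "/") * 1e6
  }
  attr(out, "unit") <- unit
  out
}

#' Apply size factors to a count matrix
#'
#' Divides each sample's counts by its size factor, yielding normalized
#' (non-integer) abundances on a common scale.
#'
#' @param counts a [count_matrix()].
#' @param size_factors positive numeric vector, one per sample.
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, size_factors) {
  stopifnot(inherits(counts, "count_matrix"),
            length(size_factors) == ncol(counts$counts),
            all(size_factors > 0))
  sweep(counts$counts, 2, as.numeric(size_factors), "/")
}
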