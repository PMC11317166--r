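#' Strand-aware analysis windows around TSS and TES
#'
#' Builds, per gene, the coverage windows the transcription indices are
#' defined on, in internal 0-based half-open coordinates and sense
#' orientation (for a `-` strand gene "downstream" means decreasing genomic
#' coordinate):
#'
#' * `tss`: -30 bp to +300 bp of the TSS (the promoter-proximal pause zone);
#' * `body`: +300 bp of the TSS to the TES;
#' * `gene_body_char`: alias of `body`, the TT-seq/ChAR counting window;
#' * `pre_term`: the 2 kb ending at (and including) the TES, truncated to the
#'   gene when the gene is shorter;
#' * `term`: the 2 kb starting just past the TES.
#'
#' `tss` and `body` require gene length > 330 bp; shorter genes get an
#' invalid window with reason `"short_gene"`. Windows reaching past the
#' chromosome start (or past the end, when the annotation carries
#' `seqlengths`) are clipped and flagged.
#'
#' @param ann a [gene_annotation()].
#' @param role window role (see above).
#' @param tss_upstream,tss_downstream,term_window window constants in bp.
#' @return A data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `valid`, `reason`, `clipped`.
#' @export
build_windows <- function(ann, role = c("tss", "body", "gene_body_char",
                                        "pre_term", "term"),
                          tss_upstream = 30L, tss_downstream = 300L,
                          term_window = 2000L) {
  role <- match.arg(role)
  validate_gene_annotation(ann)
  plus <- ann$strand == "+"
  L <- ann$end - ann$start
  start <- end <- integer(nrow(ann))
  valid <- rep(TRUE, nrow(ann))
  reason <- rep(NA_character_, nrow(ann))
  if (role %in% c("tss", "body", "gene_body_char")) {
    short <- L <= (tss_upstream + tss_downstream)
    valid[short] <- FALSE
    reason[short] <- "short_gene"
  }
  if (role == "tss") {
    start <- ifelse(plus, ann$start - tss_upstream, ann$end - tss_downstream)
    end   <- ifelse(plus, ann$start + tss_downstream, ann$end + tss_upstream)
  } else if (role %in% c("body", "gene_body_char")) {
    start <- ifelse(plus, ann$start + tss_downstream, ann$start)
    end   <- ifelse(plus, ann$end, ann$end - tss_downstream)
  } else if (role == "pre_term") {
    start <- ifelse(plus, pmax(ann$end - term_window, ann$start), ann$start)
    end   <- ifelse(plus, ann$end, pmin(ann$start + term_window, ann$end))
  } else { # term
    start <- ifelse(plus, ann$end, ann$start - term_window)
    end   <- ifelse(plus, ann$end + term_window, ann$start)
  }
  clipped <- rep(FALSE, nrow(ann))
  neg <- start < 0
  clipped[neg] <- TRUE
  start[neg] <- 0L
  sl <- attr(ann, "seqlengths")
  if (!is.null(sl)) {
    lim <- unname(sl[ann$chrom])
    over <- !is.na(lim) & end > lim
    clipped[over] <- TRUE
    end[over] <- lim[over]
  }
  empty <- valid & start >= end
  valid[empty] <- FALSE
  reason[empty] <- "empty_window"
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = ann$strand, valid = valid, reason = reason,
             clipped = clipped, stringsAsFactors = FALSE)
}

window_means <- function(track, win) {
  out <- rep(NA_real_, nrow(win))
  v <- win$valid
  out[v] <- track_window_stat(track, win$chrom[v], win$start[v], win$end[v], "mean")
  out
}

index_frame <- function(ann, num_mean, den_mean, reason, index_name) {
  idx <- ifelse(!is.na(den_mean) & den_mean > 0, num_mean / den_mean, NA_real_)
  reason[is.na(reason) & !is.na(den_mean) & den_mean == 0] <- "zero_denominator"
  out <- data.frame(gene_id = ann$gene_id, num_mean = num_mean,
                    den_mean = den_mean, index = idx, reason = reason,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "index"] <- index_name
  out
}

#' Pol II pausing index
#'
#' Ratio of mean per-base occupancy in the promoter-proximal window (-30 bp
#' to +300 bp of the TSS) to mean occupancy over the gene body (+300 bp of
#' the TSS to the TES). Computed from an unstranded occupancy track (e.g.
#' RPB1 ChIP-seq) or a sense-matched track. `NA` with a reason code for
#' short genes and zero-signal bodies.
#'
#' @param track a [coverage_track()].
#' @param ann a [gene_annotation()].
#' @return Data.frame: `gene_id`, `num_mean` (TSS window), `den_mean`
#'   (body), `pausing_index`, `reason`.
#' @export
pausing_index <- function(track, ann) {
  tssw <- build_windows(ann, "tss")
  bodyw <- build_windows(ann, "body")
  index_frame(ann, window_means(track, tssw), window_means(track, bodyw),
              ifelse(tssw$valid, NA_character_, tssw$reason), "pausing_index")
}

#' Transcriptional readthrough index
#'
#' Ratio of mean signal in the termination window (2 kb downstream of the
#' TES) to the pre-termination window (2 kb upstream of, and including, the
#' TES). Readthrough continues on the transcribed strand, so by default each
#' gene is scored on its own sense strand of a stranded track pair; set
#' `mode = "forward"` to score every gene on the `+` (forward) track, as
#' some track-level workflows do.
#'
#' @param tracks either a single [coverage_track()] used for all genes, or a
#'   named list `list(plus = , minus = )` of stranded tracks.
#' @param ann a [gene_annotation()].
#' @param mode `"sense"` (default) or `"forward"`.
#' @return Data.frame: `gene_id`, `num_mean` (term), `den_mean` (pre-term),
#'   `readthrough_index`, `reason`.
#' @export
readthrough_index <- function(tracks, ann, mode = c("sense", "forward")) {
  mode <- match.arg(mode)
  termw <- build_windows(ann, "term")
  prew <- build_windows(ann, "pre_term")
  if (inherits(tracks, "coverage_track")) {
    num <- window_means(tracks, termw)
    den <- window_means(tracks, prew)
  } else {
    if (!all(c("plus", "minus") %in% names(tracks))) {
      stop("tracks must be a coverage_track or list(plus = , minus = )")
    }
    pick <- if (mode == "forward") rep("plus", nrow(ann)) else
      ifelse(ann$strand == "+", "plus", "minus")
    num <- den <- rep(NA_real_, nrow(ann))
    for (tr in unique(pick)) {
      sel <- pick == tr
      num[sel] <- window_means(tracks[[tr]], termw[sel, , drop = FALSE])
      den[sel] <- window_means(tracks[[tr]], prew[sel, , drop = FALSE])
    }
  }
  index_frame(ann, num, den, rep(NA_character_, nrow(ann)), "readthrough_index")
}

#' Elongation index (nascent RNA over elongating Pol II)
#'
#' Ratio of mean TT-seq signal to mean pSer2 ChIP-seq signal over the gene
#' body counting window (+300 bp of the TSS to the TES), after each track's
#' scale factor. A proxy for elongation rate: more nascent RNA per
#' elongating polymerase means faster elongation.
#'
#' @param tt_track,pser2_track [coverage_track()] objects with their
#'   spike-in scale factors already attached.
#' @param ann a [gene_annotation()].
#' @return Data.frame: `gene_id`, `num_mean` (TT), `den_mean` (pSer2),
#'   `elongation_index`, `reason`.
#' @export
elongation_index <- function(tt_track, pser2_track, ann) {
  bodyw <- build_windows(ann, "gene_body_char")
  index_frame(ann, window_means(tt_track, bodyw),
              window_means(pser2_track, bodyw),
              ifelse(bodyw$valid, NA_character_, bodyw$reason),
              "elongation_index")
}

#' Metagene profile around TSS anchors
#'
#' Bins coverage around each gene's TSS (`upstream` bp before to
#' `downstream` bp after, in sense orientation) and averages across genes.
#' Rows of `-` strand genes are reversed so bin 1 is always the most
#' upstream position; the track's scale factor is applied.
#'
#' @param track a [coverage_track()].
#' @param ann a [gene_annotation()]; must be non-empty.
#' @param upstream,downstream window half-widths in bp.
#' @param bin bin width in bp; must divide `upstream + downstream`.
#' @return List with `matrix` (gene x bin mean coverage), `profile` (column
#'   means) and `offset` (sense-orientation bin start offsets relative to
#'   the TSS).
#' @export
metagene_profile <- function(track, ann, upstream = 2000L, downstream = 2000L,
                             bin = 50L) {
  validate_gene_annotation(ann)
  if (nrow(ann) == 0) stop("empty gene set")
  width <- upstream + downstream
  if (width %% bin != 0) stop("bin must divide upstream + downstream")
  n_bins <- width %/% bin
  anchors <- tss(ann)
  plus <- ann$strand == "+"
  # genomic left edge of the window covering sense offsets [-upstream, downstream)
  left <- ifelse(plus, anchors - upstream, anchors - downstream + 1L)
  starts <- rep(left, each = n_bins) + (seq_len(n_bins) - 1L) * bin
  chroms <- rep(ann$chrom, each = n_bins)
  vals <- track_window_stat(track, chroms, starts, starts + bin, "mean")
  m <- matrix(vals, nrow = nrow(ann), ncol = n_bins, byrow = TRUE,
              dimnames = list(ann$gene_id, NULL))
  m[!plus, ] <- m[!plus, n_bins:1, drop = FALSE]
  list(matrix = m, profile = colMeans(m),
       offset = -upstream + (seq_len(n_bins) - 1L) * bin)
}
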