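#' Gene length classes
#'
#' The study's three length strata: `Short` (0-10 kb, upper bound
#' inclusive), `Medium` (10-75 kb, upper bound inclusive), `Long` (>75 kb).
#'
#' @param x a [gene_annotation()] or a numeric vector of gene lengths (bp).
#' @param short_max,medium_max class boundaries in bp.
#' @return Factor with levels `Short`, `Medium`, `Long`.
#' @export
length_class <- function(x, short_max = 10000, medium_max = 75000) {
  len <- if (inherits(x, "gene_annotation")) gene_length(x) else as.numeric(x)
  cls <- ifelse(len <= short_max, "Short",
                ifelse(len <= medium_max, "Medium", "Long"))
  factor(cls, levels = c("Short", "Medium", "Long"))
}

#' Pol II degradation-upregulated genes
#'
#' The intersection rule: a gene is degradation-upregulated iff it is called
#' `up` in *both* degron experiments (e.g. the RPB1 NTD and CTD constructs)
#' and is expressed (maximum RPKM across the experiments' samples above
#' `rpkm_threshold`). Requiring both constructs excludes upregulation
#' artifacts specific to one degron (such as CTD-truncation readthrough).
#'
#' @param de_ntd,de_ctd `de_result` data.frames with a `status` column (from
#'   [call_de()]); must share a gene universe.
#' @param expr RPKM matrix (genes x samples) covering the shared universe.
#' @param rpkm_threshold strict expression floor (default 1).
#' @return Character vector of upregulated gene ids.
#' @export
define_upregulated <- function(de_ntd, de_ctd, expr, rpkm_threshold = 1) {
  if (!"status" %in% names(de_ntd) || !"status" %in% names(de_ctd)) {
    stop("both DE results need a status column; run call_de() first")
  }
  shared <- intersect(de_ntd$gene_id, de_ctd$gene_id)
  if (!length(shared)) stop("DE results have disjoint gene universes")
  up <- intersect(de_ntd$gene_id[de_ntd$status == "up"],
                  de_ctd$gene_id[de_ctd$status == "up"])
  if (!length(up)) return(character(0))
  missing_ids <- setdiff(up, rownames(expr))
  if (length(missing_ids)) {
    stop("expression matrix missing genes: ", paste(missing_ids, collapse = ", "))
  }
  mx <- apply(expr[up, , drop = FALSE], 1, max)
  up[mx > rpkm_threshold]
}

#' Control gene set
#'
#' Control genes for comparisons against the degradation-upregulated set:
#' genes shorter than `max_length` (strict, default 10 kb), excluding
#' histone genes and the upregulated set itself.
#'
#' @param ann a [gene_annotation()].
#' @param upregulated upregulated gene ids.
#' @param histone_ids histone gene ids to exclude (an empty list is allowed
#'   but warned about, since real annotations contain histone genes).
#' @param max_length strict length cutoff in bp.
#' @return Character vector of control gene ids.
#' @export
control_genes <- function(ann, upregulated, histone_ids = character(),
                          max_length = 10000) {
  validate_gene_annotation(ann)
  if (!length(histone_ids)) {
    warning("empty histone gene list; no histone exclusion applied")
  }
  len <- gene_length(ann)
  ids <- ann$gene_id[len < max_length]
  setdiff(ids, union(upregulated, histone_ids))
}

#' Peak-bound genes
#'
#' A gene is bound by a factor iff any peak overlaps, by at least 1 bp, the
#' gene extent extended upstream (in sense orientation) by
#' `promoter_upstream` bp. Intervals are 0-based half-open, so a peak that
#' only touches the half-open end coordinate does not overlap.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (from
#'   [read_peaks()] or built in code).
#' @param ann a [gene_annotation()].
#' @param promoter_upstream upstream extension in bp (default 3000).
#' @return Character vector of bound gene ids.
#' @export
binding_genes <- function(peaks, ann, promoter_upstream = 3000) {
  validate_gene_annotation(ann)
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  ext_start <- ifelse(ann$strand == "+", ann$start - promoter_upstream, ann$start)
  ext_end <- ifelse(ann$strand == "+", ann$end, ann$end + promoter_upstream)
  bound <- logical(nrow(ann))
  for (chr in unique(ann$chrom)) {
    gi <- which(ann$chrom == chr)
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (!nrow(pk)) next
    # half-open overlap: convert to 1-based closed for IRanges
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(start = ext_start[gi] + 1L, end = ext_end[gi]),
      IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    )
    bound[gi] <- hits
  }
  ann$gene_id[bound]
}
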