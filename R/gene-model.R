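#' Gene annotation tables
#'
#' A gene annotation is a plain `data.frame` (class `"gene_annotation"`) with
#' one row per gene and columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `biotype`, `species`. Coordinates are 0-based half-open (BED convention)
#' throughout the package; GTF input is converted on ingest. The transcription
#' start site (TSS) of a `-` strand gene is `end - 1` (its last base in genomic
#' coordinates) and its transcription end site (TES) is `start`.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval, `start < end`.
#' @param strand `"+"` or `"-"` per gene.
#' @param biotype optional biotype label, default `"protein_coding"`.
#' @param species `"target"` or `"spikein"` per gene.
#' @param seqlengths optional named integer vector of chromosome lengths,
#'   stored as an attribute and used for window clipping.
#'
#' @return A `gene_annotation` data.frame.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand,
                            biotype = "protein_coding", species = "target",
                            seqlengths = NULL) {
  ann <- data.frame(
    gene_id = as.character(gene_id),
    chrom   = as.character(chrom),
    start   = as.integer(start),
    end     = as.integer(end),
    strand  = as.character(strand),
    biotype = rep_len(as.character(biotype), length(gene_id)),
    species = rep_len(as.character(species), length(gene_id)),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("gene_annotation", "data.frame")
  attr(ann, "seqlengths") <- seqlengths
  validate_gene_annotation(ann)
}

validate_gene_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  req <- c("gene_id", "chrom", "start", "end", "strand", "biotype", "species")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols)) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ann$gene_id)) {
    dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
    stop("duplicate gene_id in annotation: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(ann$start >= ann$end)) {
    stop("annotation has records with start >= end (coordinates are 0-based half-open)")
  }
  if (any(ann$start < 0)) stop("annotation has negative start coordinates")
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every gene")
  }
  if (!all(ann$species %in% c("target", "spikein"))) {
    bad <- unique(ann$species[!ann$species %in% c("target", "spikein")])
    stop("species must be 'target' or 'spikein' (got: ",
         paste(bad, collapse = ", "),
         "); map organism labels (e.g. 'dm6', 'hg19') to this vocabulary on ingest")
  }
  ann
}

#' TSS, TES and length of annotated genes
#'
#' Strand-aware anchors in internal 0-based coordinates: for a `+` gene the
#' TSS is `start` and the TES is `end - 1`; for a `-` gene the TSS is
#' `end - 1` and the TES is `start`.
#'
#' @param ann a [gene_annotation()] data.frame.
#' @return Integer vector, one value per gene, named by `gene_id`.
#' @export
tss <- function(ann) {
  out <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  stats::setNames(as.integer(out), ann$gene_id)
}

#' @rdname tss
#' @export
tes <- function(ann) {
  out <- ifelse(ann$strand == "+", ann$end - 1L, ann$start)
  stats::setNames(as.integer(out), ann$gene_id)
}

#' @rdname tss
#' @export
gene_length <- function(ann) {
  stats::setNames(ann$end - ann$start, ann$gene_id)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes (%d target, %d spikein) on %d chromosome(s)\n",
              nrow(x), sum(x$species == "target"), sum(x$species == "spikein"),
              length(unique(x$chrom))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Gene by gene count matrix with species tags
#'
#' Container for a gene-by-sample integer count matrix carrying, per gene, the
#' species tag (`target` for the assayed genome, `spikein` for the exogenous
#' spike-in genome) and the gene length in bp used by RPKM/TPM.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param species character vector, `"target"`/`"spikein"`, one per gene.
#' @param lengths integer vector of gene lengths (bp), one per gene.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, species, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max in sums
  species <- rep_len(as.character(species), nrow(counts))
  if (!all(species %in% c("target", "spikein"))) {
    stop("species must be 'target' or 'spikein' per gene")
  }
  lengths <- rep_len(as.numeric(lengths), nrow(counts))
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  structure(
    list(counts = counts, species = species, lengths = lengths),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes (%d spikein) x %d samples\n",
              nrow(x$counts), sum(x$species == "spikein"), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or sample
#'
#' @param x a [count_matrix()].
#' @param genes gene ids or logical/integer index over rows.
#' @param samples sample ids or index over columns.
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  si <- if (is.null(samples)) seq_len(ncol(x$counts)) else samples
  if (is.character(gi)) gi <- match(gi, rownames(x$counts))
  if (anyNA(gi)) stop("unknown gene ids in selection")
  count_matrix(x$counts[gi, si, drop = FALSE], x$species[gi], x$lengths[gi])
}
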