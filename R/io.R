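#' Read a gene annotation from GTF or BED
#'
#' GTF coordinates (1-based, inclusive) are converted to the package's
#' internal 0-based half-open convention on ingest; BED6/BED12 are already in
#' that convention. For BED12 only the gene-level extent is used. Records with
#' unknown strand (`*` / `.`) are dropped with a warning; duplicate gene ids
#' are an error.
#'
#' @param path file path.
#' @param format `"gtf"`, `"bed6"` or `"bed12"`.
#' @param spikein_chroms chromosomes whose genes are tagged `species =
#'   "spikein"` (a GTF `gene_species` attribute, when present, wins).
#' @param seqlengths optional named chromosome lengths, kept for window
#'   clipping.
#' @return A [gene_annotation()] data.frame.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed6", "bed12"),
                                 spikein_chroms = character(),
                                 seqlengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gtf") "gtf" else "bed"),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (format == "gtf" && "type" %in% names(S4Vectors::mcols(gr))) {
    if (any(S4Vectors::mcols(gr)$type == "gene")) {
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    }
  }
  str <- as.character(GenomicRanges::strand(gr))
  if (any(!str %in% c("+", "-"))) {
    warning(sum(!str %in% c("+", "-")),
            " record(s) with unknown strand dropped from ", path)
    gr <- gr[str %in% c("+", "-")]
    str <- as.character(GenomicRanges::strand(gr))
  }
  mc <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(mc)) mc$gene_id else if ("name" %in% names(mc)) mc$name else NULL
  if (is.null(ids) || anyNA(ids)) stop("every record in ", path, " needs a gene id")
  biotype <- if ("gene_biotype" %in% names(mc)) mc$gene_biotype else "protein_coding"
  chrom <- as.character(GenomicRanges::seqnames(gr))
  species <- ifelse(chrom %in% spikein_chroms, "spikein", "target")
  if ("gene_species" %in% names(mc)) {
    species <- ifelse(is.na(mc$gene_species), species, mc$gene_species)
  }
  gene_annotation(
    gene_id = ids, chrom = chrom,
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = str, biotype = biotype, species = species,
    seqlengths = seqlengths
  )
}

#' Write a gene annotation
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @param format `"bed6"` (0-based half-open, as stored) or `"gtf"` (1-based
#'   inclusive gene records carrying `gene_id`, `gene_biotype` and
#'   `gene_species` attributes).
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  validate_gene_annotation(ann)
  if (format == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     ann$chrom, ann$start, ann$end, ann$gene_id, ann$strand)
  } else {
    lines <- sprintf(
      paste0("%s\tdegrontx\tgene\t%d\t%d\t.\t%s\t.\t",
             "gene_id \"%s\"; gene_biotype \"%s\"; gene_species \"%s\";"),
      ann$chrom, ann$start + 1L, ann$end, ann$strand,
      ann$gene_id, ann$biotype, ann$species)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' bedGraph intervals are 0-based half-open. Overlapping intervals with
#' unequal values are rejected; negative values are rejected (occupancy
#' semantics). Uncovered positions read as 0.
#'
#' @param path bedGraph file path.
#' @param strand strand label for the track (`"+"`, `"-"`, `"unstranded"`).
#' @param scale_factor multiplicative scale factor attached to the track.
#' @return A [coverage_track()].
#' @export
read_coverage_track <- function(path, strand = "unstranded", scale_factor = 1) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  runs <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = S4Vectors::mcols(gr)$score,
    stringsAsFactors = FALSE
  )
  coverage_track(runs, strand = strand, scale_factor = scale_factor)
}

#' Write a coverage track as bedGraph
#'
#' Zero-valued runs are omitted (the gap convention makes them implicit).
#' Values are printed with full double precision so write-then-read is the
#' identity.
#'
#' @param track a [coverage_track()]. The scale factor is not baked in; the
#'   stored per-base values are written.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chr in names(track$rle)) {
    rle <- track$rle[[chr]]
    ends <- cumsum(S4Vectors::runLength(rle))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(rle)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%.17g",
                         chr, starts[keep], ends[keep], vals[keep]), con)
    }
  }
  invisible(path)
}

#' Read a gene-by-sample count table
#'
#' Expected layout: a TSV whose header names the metadata columns `gene_id`,
#' `species`, `length` followed by one column per sample; `#`-prefixed lines
#' are treated as comments. Counts must be non-negative integers and species
#' must use the `target`/`spikein` vocabulary.
#'
#' @param path TSV path.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("gene_id", "species", "length")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("count table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(df), req)
  if (!length(sample_cols)) stop("count table ", path, " has no sample columns")
  cnt <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(cnt) || any(is.na(cnt))) stop("non-numeric count in ", path)
  if (any(cnt != round(cnt))) stop("non-integer count in ", path)
  if (any(cnt < 0)) stop("negative count in ", path)
  rownames(cnt) <- df$gene_id
  count_matrix(cnt, species = df$species, lengths = df$length)
}

#' Write a gene-by-sample count table
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines written first.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, header_lines = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), species = x$species,
                   length = x$lengths, x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peak intervals from BED
#'
#' @param path BED file (0-based half-open), at least 3 columns.
#' @return A `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `score`, sorted by chromosome then start.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  peaks <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if ("score" %in% names(S4Vectors::mcols(gr))) {
    peaks$score <- S4Vectors::mcols(gr)$score
  }
  if (any(peaks$start >= peaks$end)) stop("peaks must have start < end")
  peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
}
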