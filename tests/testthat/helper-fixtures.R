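# Small in-code fixtures shared across tests.

toy_annotation <- function() {
  gene_annotation(
    gene_id = c("plusA", "minusB", "shortC"),
    chrom   = c("chr1", "chr1", "chr2"),
    start   = c(10000L, 30000L, 5000L),
    end     = c(15000L, 35000L, 5200L),
    strand  = c("+", "-", "+"),
    seqlengths = c(chr1 = 60000L, chr2 = 20000L)
  )
}

# uniform coverage `value` over [start, end) on one chromosome
uniform_track <- function(chrom, start, end, value, strand = "unstranded") {
  coverage_track(data.frame(chrom = chrom, start = start, end = end,
                            value = value),
                 strand = strand)
}

# track realizing exact pausing/readthrough indices for one + strand gene
constructed_gene_track <- function(ann, tss_level, body_level, tail_level) {
  stopifnot(nrow(ann) == 1)
  s <- ann$start; e <- ann$end
  if (ann$strand == "+") {
    runs <- data.frame(
      chrom = ann$chrom,
      start = c(s - 30L, s + 300L, e),
      end   = c(s + 300L, e, e + 2000L),
      value = c(tss_level, body_level, tail_level))
  } else {
    runs <- data.frame(
      chrom = ann$chrom,
      start = c(e - 300L, s, s - 2000L),
      end   = c(e + 30L, e - 300L, s),
      value = c(tss_level, body_level, tail_level))
  }
  coverage_track(runs[runs$value > 0, , drop = FALSE])
}

toy_counts <- function() {
  # 4 genes x 3 samples: 2 target, 2 spikein
  cnt <- matrix(c(10, 20, 30,
                  5, 10, 15,
                  100, 100, 100,
                  200, 200, 200), nrow = 4, byrow = TRUE,
                dimnames = list(c("g1", "g2", "s1", "s2"),
                                c("a1", "a2", "a3")))
  count_matrix(cnt, species = c("target", "target", "spikein", "spikein"),
               lengths = c(1000, 2000, 500, 500))
}
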