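#!/usr/bin/env Rscript
# Stage 5: gene-set classification -- the two-construct intersection + RPKM
# filter defining degradation-upregulated genes, short non-upregulated
# control genes, length classes, and peak-bound genes against a toy peak set.

suppressMessages(library(degrontx))

outdir <- "results/analysis"
ann <- read_gene_annotation(file.path(outdir, "annotation.bed"), "bed6",
                            spikein_chroms = paste0("spike", 1:10))
target <- ann[ann$species == "target", ]
class(target) <- class(ann)
cm <- read_count_table(file.path(outdir, "counts_ntd.tsv"))
truth <- utils::read.delim(file.path(outdir, "truth_de.tsv"))

load_de <- function(tag) {
  de <- utils::read.delim(file.path(outdir, paste0("de_", tag, ".tsv")))
  class(de) <- c("de_result", "data.frame")
  de
}
rpkm <- rpkm_tpm(cm, "RPKM")
up <- define_upregulated(load_de("ntd"), load_de("ctd"), rpkm, rpkm_threshold = 1)
true_up <- truth$gene_id[truth$group == "up"]
message(sprintf("upregulated set: %d genes (truth %d; %d shared)",
                length(up), length(true_up), length(intersect(up, true_up))))

ctrl <- suppressWarnings(control_genes(target, up, histone_ids = character(0)))
anchors <- tss(target)
sel <- seq(1, nrow(target), by = 3L)
peaks <- data.frame(chrom = target$chrom[sel],
                    start = pmax(anchors[sel] - 200L, 0L),
                    end = anchors[sel] + 200L)
bound <- binding_genes(peaks, target, promoter_upstream = 3000)

labels <- data.frame(gene_id = target$gene_id,
                     length_class = as.character(length_class(target)),
                     upregulated = target$gene_id %in% up,
                     control = target$gene_id %in% ctrl,
                     bound_toyfactor = target$gene_id %in% bound)
utils::write.table(labels, file.path(outdir, "labels.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("labels: %d control genes, %d peak-bound; length classes %s",
                sum(labels$control), sum(labels$bound_toyfactor),
                paste(names(table(labels$length_class)),
                      table(labels$length_class), collapse = " ", sep = "=")))
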