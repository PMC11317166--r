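#!/usr/bin/env Rscript
# Stage 3: coverage-based transcription indices from the simulated stranded
# tracks -- promoter-proximal pausing, post-TES readthrough, and a TSS
# metagene profile -- checked against the simulator's recorded truth.

suppressMessages(library(degrontx))

outdir <- "results/analysis"
ann <- read_gene_annotation(file.path(outdir, "annotation.bed"), "bed6",
                            spikein_chroms = paste0("spike", 1:10))
target <- ann[ann$species == "target", ]
class(target) <- class(ann)
plus <- read_coverage_track(file.path(outdir, "tracks_plus.bedGraph"), "+")
minus <- read_coverage_track(file.path(outdir, "tracks_minus.bedGraph"), "-")
truth <- utils::read.delim(file.path(outdir, "truth_indices.tsv"))

# an unstranded occupancy view: genes never overlap, so strand sum is exact
len <- sapply(unique(target$chrom), function(ch)
  max(length(plus$rle[[ch]]), length(minus$rle[[ch]])))
combined <- coverage_track(stats::setNames(lapply(unique(target$chrom), function(ch) {
  pad <- function(x) if (is.null(x)) S4Vectors::Rle(0, len[[ch]]) else
    c(x, S4Vectors::Rle(0, len[[ch]] - length(x)))
  pad(plus$rle[[ch]]) + pad(minus$rle[[ch]])
}), unique(target$chrom)))

pi_tab <- pausing_index(combined, target)
ri_tab <- readthrough_index(list(plus = plus, minus = minus), target, "sense")
idx <- merge(merge(pi_tab, ri_tab, by = "gene_id"), truth, by = "gene_id")
utils::write.table(idx, file.path(outdir, "indices.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "pausing index: median rel. error vs truth %.2f%%; readthrough: %.2f%% (n = %d)",
  100 * median(abs(idx$pausing_index - idx$true_pausing) / idx$true_pausing, na.rm = TRUE),
  100 * median(abs(idx$readthrough_index - idx$true_readthrough) / idx$true_readthrough, na.rm = TRUE),
  nrow(idx)))

mp <- metagene_profile(combined, target, upstream = 2000L, downstream = 2000L,
                       bin = 50L)
utils::write.table(data.frame(offset = mp$offset, mean_signal = mp$profile),
                   file.path(outdir, "metagene_profile.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
peak_bin <- mp$offset[which.max(mp$profile)]
message(sprintf("metagene: profile peaks at %+d bp from the TSS (the simulated pause bump)",
                peak_bin))
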