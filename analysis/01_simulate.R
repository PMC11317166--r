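#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a toy genome annotation, two
# spike-in RNA-seq experiments (emulating RPB1 NTD and CTD degron constructs
# that share one true up-set), stranded coverage tracks with known pausing /
# readthrough indices, and a two-condition 4sU pulse-chase time course.
# Everything downstream reads these tables; ground truth is stored alongside.

suppressMessages(library(degrontx))

outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260101)
saveRDS_path <- NULL  # all artifacts are plain text; no binary outputs

ann <- simulate_annotation(cfg)
write_gene_annotation(ann, file.path(outdir, "annotation.bed"), "bed6")
message(sprintf("annotation: %d target + %d spike-in genes on %d chromosomes",
                sum(ann$species == "target"), sum(ann$species == "spikein"),
                length(unique(ann$chrom))))
print(table(length_class(ann[ann$species == "target", ])))

ntd <- simulate_counts(ann, cfg, seed_offset = 0L)
ctd <- simulate_counts(ann, cfg, truth = ntd$truth, seed_offset = 1L)
write_count_table(ntd$counts, file.path(outdir, "counts_ntd.tsv"))
write_count_table(ctd$counts, file.path(outdir, "counts_ctd.tsv"))
utils::write.table(ntd$truth, file.path(outdir, "truth_de.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("counts: %d x %d per construct; true up-set %d genes, %d repressed 5-fold",
                nrow(ntd$counts$counts), ncol(ntd$counts$counts),
                sum(ntd$truth$group == "up"), sum(ntd$truth$group == "repressed")))

trk <- simulate_tracks(ann, cfg)
write_coverage_track(trk$tracks$plus, file.path(outdir, "tracks_plus.bedGraph"))
write_coverage_track(trk$tracks$minus, file.path(outdir, "tracks_minus.bedGraph"))
utils::write.table(trk$truth, file.path(outdir, "truth_indices.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("tracks: TSS bump / uniform body / post-TES tail per gene, noise CV ",
        cfg$track_noise_cv)

up_true <- ntd$truth$gene_id[ntd$truth$group == "up"]
pc <- simulate_pulse_chase(ann, cfg, conditions = list(
  untreated = NULL, treated = list(multiplier = 2, genes = up_true)))
utils::write.table(
  data.frame(gene_id = rownames(pc$tpm), pc$tpm, check.names = FALSE),
  file.path(outdir, "pulse_chase_tpm.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pc$meta, file.path(outdir, "pulse_chase_meta.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pc$truth$halflife, file.path(outdir, "truth_halflife.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(pc$truth$stable_genes, file.path(outdir, "stable_genes.txt"))
message(sprintf("pulse-chase: %d samples over t = %s h; treated condition doubles t1/2 of the true up-set",
                nrow(pc$meta), paste(sort(unique(pc$meta$timepoint_h)), collapse = "/")))
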