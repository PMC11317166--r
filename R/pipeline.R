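#' Pipeline configuration
#'
#' Bundles the simulation configuration with the analysis thresholds used by
#' [run_pipeline()]: the 2-fold / FDR < 0.05 differential-expression
#' convention, the RPKM > 1 expression floor of the upregulated-gene
#' definition, the TPM > 0.2 pulse-chase filter, and the 3 kb promoter
#' extension for peak-to-gene assignment.
#'
#' @param sim a [sim_config()].
#' @param lfc_threshold minimum `|log2FC|` for a DE call.
#' @param fdr_threshold FDR cutoff for a DE call.
#' @param rpkm_threshold strict RPKM floor of [define_upregulated()].
#' @param tpm_threshold strict TPM floor of the pulse-chase filter.
#' @param promoter_upstream promoter extension (bp) for [binding_genes()].
#' @param halflife_multiplier half-life multiplier applied, in the treated
#'   pulse-chase condition, to the truly upregulated gene set.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            lfc_threshold = 1, fdr_threshold = 0.05,
                            rpkm_threshold = 1, tpm_threshold = 0.2,
                            promoter_upstream = 3000,
                            halflife_multiplier = 2) {
  stopifnot(inherits(sim, "sim_config"),
            lfc_threshold > 0, fdr_threshold > 0, fdr_threshold < 1,
            rpkm_threshold >= 0, tpm_threshold >= 0, promoter_upstream >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_tsv <- function(df, path, provenance) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data pipeline
#'
#' End-to-end driver: simulate an annotation and two spike-in count
#' experiments sharing one true up-set (emulating the two degron constructs),
#' normalize with spike-in size factors, test differential expression, call
#' the degradation-upregulated set by intersection + RPKM filter, simulate
#' coverage tracks and compute pausing/readthrough indices and a TSS
#' metagene, simulate a two-condition pulse-chase (treated half-lives of the
#' true up-set scaled by `halflife_multiplier`) and fit half-lives, and
#' write gene labels (length class, upregulated, control, peak-bound against
#' simulated TSS peaks).
#'
#' Every output TSV starts with a provenance comment (package version,
#' config hash, seed); no stage records wall-clock time, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a manifest data.frame (`file`, `md5`) also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  prov <- sprintf("degrontx %s; config_hash=%s; seed=%d",
                  as.character(utils::packageVersion("degrontx")),
                  config_hash(config), config$sim$seed)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_stage_tsv(df, p, prov)
    paths <<- c(paths, p)
    p
  }

  say("[simulate] annotation")
  ann <- simulate_annotation(config$sim)
  p_ann <- file.path(outdir, "annotation.bed")
  write_gene_annotation(ann, p_ann, "bed6")
  paths <- c(paths, p_ann)

  say("[simulate] spike-in count matrices (two degron constructs)")
  sim_ntd <- simulate_counts(ann, config$sim, seed_offset = 0L)
  sim_ctd <- simulate_counts(ann, config$sim, truth = sim_ntd$truth,
                             seed_offset = 1L)
  emit(sim_ntd$truth, "truth_de.tsv")

  say("[normalize] spike-in size factors")
  groups <- sub("_[0-9]+$", "", colnames(sim_ntd$counts$counts))
  sf_ntd <- spikein_size_factors(sim_ntd$counts)
  sf_ctd <- spikein_size_factors(sim_ctd$counts)
  emit(data.frame(sample_id = names(sf_ntd), ntd = as.numeric(sf_ntd),
                  ctd = as.numeric(sf_ctd)), "size_factors.tsv")
  rpkm <- rpkm_tpm(sim_ntd$counts, "RPKM")

  say("[de] negative-binomial Wald tests")
  de_ntd <- call_de(nb_wald_test(sim_ntd$counts, groups, sf_ntd),
                    config$lfc_threshold, config$fdr_threshold)
  de_ctd <- call_de(nb_wald_test(sim_ctd$counts, groups, sf_ctd),
                    config$lfc_threshold, config$fdr_threshold)
  emit(de_ntd, "de_ntd.tsv")
  emit(de_ctd, "de_ctd.tsv")
  say(sprintf("[de] up calls: ntd=%d ctd=%d",
              sum(de_ntd$status == "up"), sum(de_ctd$status == "up")))

  say("[indices] simulated tracks, pausing/readthrough, metagene")
  trk <- simulate_tracks(ann, config$sim)
  pi_tab <- pausing_index(trk$tracks$combined, ann[ann$species == "target", ])
  ri_tab <- readthrough_index(trk$tracks[c("plus", "minus")],
                              ann[ann$species == "target", ], mode = "sense")
  idx <- data.frame(gene_id = pi_tab$gene_id,
                    tss_mean = pi_tab$num_mean, body_mean = pi_tab$den_mean,
                    pausing_index = pi_tab$pausing_index,
                    term_mean = ri_tab$num_mean, pre_term_mean = ri_tab$den_mean,
                    readthrough_index = ri_tab$readthrough_index,
                    reason = ifelse(is.na(pi_tab$reason), ri_tab$reason,
                                    pi_tab$reason),
                    stringsAsFactors = FALSE)
  emit(idx, "indices.tsv")
  emit(trk$truth, "truth_indices.tsv")
  meta_prof <- metagene_profile(trk$tracks$combined,
                                ann[ann$species == "target", ],
                                upstream = 2000L, downstream = 2000L, bin = 50L)
  emit(data.frame(offset = meta_prof$offset, mean_signal = meta_prof$profile),
       "metagene_profile.tsv")

  say("[halflife] two-condition pulse-chase")
  up_true <- sim_ntd$truth$gene_id[sim_ntd$truth$group == "up"]
  pc <- simulate_pulse_chase(
    ann, config$sim,
    conditions = list(
      untreated = NULL,
      treated = list(multiplier = config$halflife_multiplier, genes = up_true)))
  hl <- halflife_table(pc$tpm, pc$meta, pc$truth$stable_genes,
                       tpm_threshold = config$tpm_threshold)
  emit(hl$fits, "halflife.tsv")
  if (!is.null(hl$delta)) emit(hl$delta, "halflife_delta.tsv")
  emit(pc$truth$halflife, "truth_halflife.tsv")

  say("[classify] gene labels")
  up_called <- define_upregulated(de_ntd, de_ctd, rpkm, config$rpkm_threshold)
  target_ann <- ann[ann$species == "target", , drop = FALSE]
  ctrl <- suppressWarnings(
    control_genes(target_ann, up_called, histone_ids = character(0)))
  # toy peak set over the TSS of every third target gene, to exercise binding
  anchors <- tss(target_ann)
  sel <- seq(1, nrow(target_ann), by = 3L)
  peaks <- data.frame(chrom = target_ann$chrom[sel],
                      start = pmax(anchors[sel] - 200L, 0L),
                      end = anchors[sel] + 200L, stringsAsFactors = FALSE)
  bound <- binding_genes(peaks, target_ann, config$promoter_upstream)
  labels <- data.frame(
    gene_id = target_ann$gene_id,
    length_class = as.character(length_class(target_ann)),
    upregulated = target_ann$gene_id %in% up_called,
    control = target_ann$gene_id %in% ctrl,
    bound_toyfactor = target_ann$gene_id %in% bound,
    stringsAsFactors = FALSE)
  emit(labels, "labels.tsv")
  say(sprintf("[classify] upregulated=%d control=%d bound=%d",
              length(up_called), length(ctrl), length(bound)))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write_stage_tsv(manifest, file.path(outdir, "manifest.tsv"), prov)
  invisible(manifest)
}
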