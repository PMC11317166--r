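test_that("simulators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 60, n_spikein = 20, seed = 5)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  c1 <- simulate_counts(a1, cfg)
  c2 <- simulate_counts(a1, cfg)
  expect_identical(c1$counts$counts, c2$counts$counts)
  p1 <- simulate_pulse_chase(a1, cfg)
  p2 <- simulate_pulse_chase(a1, cfg)
  expect_identical(p1$tpm, p2$tpm)
  t1 <- simulate_tracks(a1, cfg)
  t2 <- simulate_tracks(a1, cfg)
  expect_identical(t1$truth, t2$truth)
  expect_identical(as.numeric(t1$tracks$plus$rle[[1]]),
                   as.numeric(t2$tracks$plus$rle[[1]]))
  a3 <- simulate_annotation(sim_config(n_genes = 60, n_spikein = 20, seed = 6))
  expect_false(identical(a1$end, a3$end))
})

test_that("simulated annotations respect gaps, strands and length classes", {
  cfg <- sim_config(n_genes = 300, n_spikein = 30, seed = 2)
  ann <- simulate_annotation(cfg)
  expect_setequal(unique(ann$strand), c("+", "-"))
  for (chr in unique(ann$chrom)) {
    sub <- ann[ann$chrom == chr, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      gaps <- sub$start[-1] - sub$end[-nrow(sub)]
      expect_true(all(gaps >= cfg$intergenic_gap))
    }
  }
  # default length distribution straddles 10 kb and 75 kb
  cls <- table(length_class(ann))
  expect_true(all(cls > 0))
  expect_error(simulate_annotation(
    sim_config(n_genes = 100, genes_per_chrom = 100, chrom_length = 5e4,
               seed = 1)), "infeasible")
  expect_error(sim_config(intergenic_gap = 1000), "2000")
})

test_that("null count simulation is exchangeable and spike-in totals track depth only", {
  cfg <- sim_config(n_genes = 500, n_spikein = 50, fraction_upregulated = 0,
                    fraction_unchanged = 1, repression_factor = 1, seed = 9)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  expect_true(all(sim$truth$true_log2fc == 0))
  groups <- rep(c("control", "treated"), each = 3)
  tot <- colSums(sim$counts$counts)
  expect_lt(abs(log2(mean(tot[1:3]) / mean(tot[4:6]))), 0.05)

  # under global repression the spike-in side must stay put
  cfg2 <- sim_config(n_genes = 500, n_spikein = 50, seed = 9)
  sim2 <- simulate_counts(ann, cfg2)
  sp <- sim2$counts$counts[sim2$counts$species == "spikein", ]
  expect_lt(abs(log2(mean(colSums(sp[, 4:6])) / mean(colSums(sp[, 1:3])))), 0.1)
  tg <- sim2$counts$counts[sim2$counts$species == "target", ]
  expect_lt(log2(mean(colSums(tg[, 4:6])) / mean(colSums(tg[, 1:3]))), -0.3)
})

test_that("near-Poisson deep counts recover the true fold change after spike-in normalization", {
  # law-of-large-numbers check: dispersion ~ 0 at depth 1e6
  cfg <- sim_config(n_genes = 100, n_spikein = 30, depth = 1e6,
                    dispersion = 0, fraction_upregulated = 0.2,
                    fraction_unchanged = 0.8, upregulated_log2fc = 2,
                    repression_factor = 1, seed = 31)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  sf <- spikein_size_factors(sim$counts)
  q <- normalize_counts(sim$counts, sf)
  truth <- sim$truth
  up <- truth$gene_id[truth$group == "up"]
  ratio <- rowMeans(q[up, 4:6, drop = FALSE]) / rowMeans(q[up, 1:3, drop = FALSE])
  expect_equal(median(ratio), 4, tolerance = 0.05)
})

test_that("pulse-chase closed forms hold at zero noise", {
  cfg <- sim_config(n_genes = 40, n_spikein = 5, noise_cv = 0,
                    timepoints = c(0, 1, 3), pulse_reps = 1,
                    distortion_range = c(1, 1), halflife_range = c(1, 1),
                    n_stable = 4, seed = 13)
  ann <- simulate_annotation(cfg)
  pc <- simulate_pulse_chase(ann, cfg)
  tr <- pc$truth$halflife
  decaying <- tr$gene_id[is.finite(tr$true_halflife)]
  g <- decaying[1]
  cols <- pc$meta$sample_id[order(pc$meta$timepoint_h)]
  v <- pc$tpm[g, cols]
  # t1/2 = 1 h: values at t = 0, 1, 3 are E, E/2, E/8
  expect_equal(unname(v[2] / v[1]), 0.5, tolerance = 1e-12)
  expect_equal(unname(v[3] / v[1]), 0.125, tolerance = 1e-12)
  stable <- tr$gene_id[tr$stable]
  expect_true(all(apply(pc$tpm[stable, cols, drop = FALSE], 1,
                        function(x) diff(range(x))) < 1e-9))
  expect_error(simulate_pulse_chase(ann, sim_config(timepoints = c(-1, 0))),
               "non-negative")
})

test_that("per-sample distortions are recovered exactly by stable-gene scaling", {
  cfg <- sim_config(n_genes = 50, n_spikein = 5, noise_cv = 0,
                    timepoints = c(0, 1, 3, 12), pulse_reps = 1,
                    distortion_range = c(0.7, 1.3), n_stable = 5, seed = 17)
  ann <- simulate_annotation(cfg)
  pc <- simulate_pulse_chase(ann, cfg)
  sc <- stable_gene_scaling(pc$tpm, pc$truth$stable_genes,
                            pc$meta$sample_id[pc$meta$timepoint_h == 0])
  expect_equal(unname(sc$scale_factors),
               pc$truth$distortion$distortion, tolerance = 1e-9)
})

test_that("constructed tracks realize their true indices exactly at zero noise", {
  cfg <- sim_config(n_genes = 30, n_spikein = 5, track_noise_cv = 0,
                    seed = 23)
  ann <- simulate_annotation(cfg)
  trk <- simulate_tracks(ann, cfg)
  target <- ann[ann$species == "target", ]
  class(target) <- class(ann)
  pi_tab <- pausing_index(trk$tracks$combined, target)
  ri_tab <- readthrough_index(trk$tracks[c("plus", "minus")], target)
  m <- merge(merge(pi_tab, ri_tab, by = "gene_id"), trk$truth, by = "gene_id")
  expect_equal(m$pausing_index, m$true_pausing, tolerance = 1e-9)
  expect_equal(m$readthrough_index, m$true_readthrough, tolerance = 1e-9)
})
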