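test_that("stable-gene scaling identities hold on constructed matrices", {
  tpm <- rbind(st1 = c(t0 = 8, t3 = 4), st2 = c(2, 1), g = c(10, 10))
  sc <- stable_gene_scaling(tpm, c("st1", "st2"), "t0")
  # every stable gene halved at t = 3 -> c = 0.5 and all genes double back
  expect_equal(unname(sc$scale_factors), c(1, 0.5))
  expect_equal(unname(sc$rescaled["g", ]), c(10, 20))

  flat <- rbind(st1 = c(5, 5, 5), st2 = c(7, 7, 7), g = c(9, 4, 2))
  colnames(flat) <- c("t0", "t1", "t3")
  expect_equal(unname(stable_gene_scaling(flat, c("st1", "st2"),
                                          "t0")$scale_factors), c(1, 1, 1))

  zero <- rbind(st1 = c(t0 = 0, t3 = 1), st2 = c(4, 2), g = c(1, 1))
  expect_warning(sc2 <- stable_gene_scaling(zero, c("st1", "st2"), "t0"),
                 "dropping")
  expect_equal(sc2$stable_used, "st2")
  allzero <- rbind(st1 = c(t0 = 0, t3 = 1), g = c(1, 1))
  expect_error(suppressWarnings(stable_gene_scaling(allzero, "st1", "t0")),
               "no usable")
})

test_that("expression filter applies a strict TPM > 0.2 boundary", {
  tpm <- rbind(a = c(u0a = 0.3, u0b = 0.3),
               b = c(0.2, 0.2),
               c = c(0, 0),
               d = c(0.15, 0.30))
  kept <- filter_expressed(tpm, c("u0a", "u0b"), 0.2)
  expect_setequal(kept, c("a", "d"))  # d: mean 0.225 > 0.2
  expect_error(filter_expressed(tpm, character(0)), "reference")
})

test_that("decay fits recover closed-form kinetics and flag degenerate series", {
  fit <- fit_decay(c(0, 1, 2), c(1, 0.5, 0.25))
  expect_equal(fit$k, log(2), tolerance = 1e-12)
  expect_equal(fit$halflife, 1, tolerance = 1e-12)
  expect_equal(fit$flag, "ok")

  const <- fit_decay(c(0, 1, 3, 12), rep(4, 4))
  expect_equal(const$k, 0)
  expect_equal(const$halflife, Inf)
  expect_equal(const$flag, "nondecaying")

  few <- fit_decay(c(0, 1, 3), c(5, 0, 0))
  expect_equal(few$flag, "insufficient_points")
  expect_equal(few$n_dropped, 2L)
  expect_true(is.na(few$halflife))

  # replicates averaged on the log scale: heavily replicated late point
  # must not gain leverage
  a <- fit_decay(c(0, 1, 2), c(1, 0.5, 0.25))
  b <- fit_decay(c(0, 1, 2, 2, 2), c(1, 0.5, 0.25, 0.25, 0.25))
  expect_equal(a$k, b$k, tolerance = 1e-12)
})

test_that("decay fits are invariant to value scaling and consistent across time units", {
  t_h <- c(0, 1, 3, 12)
  set.seed(8)
  v <- 10 * exp(-0.4 * t_h) * exp(rnorm(4, 0, 0.05))
  f1 <- fit_decay(t_h, v)
  f2 <- fit_decay(t_h, 1e3 * v)
  expect_equal(f1$k, f2$k, tolerance = 1e-12)
  expect_equal(f2$intercept / f1$intercept, 1e3, tolerance = 1e-9)
  f_min <- fit_decay(t_h * 60, v)
  expect_equal(f_min$k * 60, f1$k, tolerance = 1e-12)
})

test_that("stable genes themselves come out non-decaying after scaling", {
  cfg <- sim_config(n_genes = 40, n_spikein = 5, noise_cv = 0,
                    pulse_reps = 1, n_stable = 5, seed = 3)
  ann <- simulate_annotation(cfg)
  pc <- simulate_pulse_chase(ann, cfg)
  hl <- halflife_table(pc$tpm, pc$meta, pc$truth$stable_genes)
  st <- hl$fits[hl$fits$gene_id %in% pc$truth$stable_genes, ]
  expect_true(all(st$flag == "nondecaying"))
  expect_true(all(is.infinite(st$halflife)))
})

test_that("two identical conditions give near-zero half-life shifts", {
  cfg <- sim_config(n_genes = 150, n_spikein = 10, noise_cv = 0.1,
                    pulse_reps = 2, seed = 19)
  ann <- simulate_annotation(cfg)
  pc <- simulate_pulse_chase(ann, cfg,
                             conditions = list(untreated = NULL, treated = NULL))
  hl <- halflife_table(pc$tpm, pc$meta, pc$truth$stable_genes)
  d <- hl$delta$delta_log2_treated
  expect_lt(abs(median(d, na.rm = TRUE)), 0.05)
})

test_that("a doubled-half-life subset is recovered in the paired table", {
  cfg <- sim_config(n_genes = 200, n_spikein = 10, noise_cv = 0.1,
                    pulse_reps = 2, halflife_range = c(0.5, 8), seed = 29)
  ann <- simulate_annotation(cfg)
  target_ids <- ann$gene_id[ann$species == "target"]
  subset_ids <- setdiff(target_ids, character(0))[1:60]
  pc <- simulate_pulse_chase(
    ann, cfg, conditions = list(
      untreated = NULL,
      treated = list(multiplier = 2, genes = subset_ids)))
  hl <- halflife_table(pc$tpm, pc$meta, pc$truth$stable_genes)
  d <- hl$delta
  in_sub <- d$gene_id %in% setdiff(subset_ids, pc$truth$stable_genes)
  expect_lt(abs(median(d$delta_log2_treated[in_sub], na.rm = TRUE) - 1), 0.2)
  expect_lt(abs(median(d$delta_log2_treated[!in_sub], na.rm = TRUE)), 0.2)
})

test_that("low-expression genes are flagged, not fitted", {
  tpm <- rbind(hi = c(10, 5, 2.5, 1.25), lo = c(0.1, 0.05, 0.02, 0.01),
               st = c(50, 50, 50, 50))
  colnames(tpm) <- c("untreated_t0_r1", "untreated_t1_r1",
                     "untreated_t3_r1", "untreated_t12_r1")
  meta <- data.frame(sample_id = colnames(tpm), condition = "untreated",
                     timepoint_h = c(0, 1, 3, 12), replicate = 1)
  hl <- halflife_table(tpm, meta, "st")
  expect_equal(hl$fits$flag[hl$fits$gene_id == "lo"], "filtered_low_expr")
  expect_true(is.na(hl$fits$halflife[hl$fits$gene_id == "lo"]))
  expect_equal(hl$fits$flag[hl$fits$gene_id == "hi"], "ok")
})
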