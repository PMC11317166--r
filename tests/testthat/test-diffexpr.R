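make_null_counts <- function(n_genes = 60, n_rep = 3, mu = 200, seed = 99) {
  set.seed(seed)
  cnt <- matrix(rnbinom(n_genes * 2 * n_rep, mu = mu, size = 20),
                nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                c(paste0("c", 1:n_rep), paste0("t", 1:n_rep))))
  count_matrix(cnt, species = "target", lengths = 1000)
}

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("swapping group labels negates log2FC and keeps p-values", {
  x <- make_null_counts()
  groups <- rep(c("control", "treated"), each = 3)
  s <- rep(1, 6)
  a <- nb_wald_test(x, factor(groups, c("control", "treated")), s)
  b <- nb_wald_test(x, factor(groups, c("treated", "control")), s)
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
})

test_that("scaling one sample's counts and size factor together changes nothing", {
  x <- make_null_counts(n_genes = 40)
  groups <- rep(c("control", "treated"), each = 3)
  s <- c(1, 1, 1, 1, 1, 1)
  a <- nb_wald_test(x, groups, s)
  cnt2 <- x$counts
  cnt2[, 2] <- cnt2[, 2] * 5
  x2 <- count_matrix(cnt2, species = x$species, lengths = x$lengths)
  s2 <- s; s2[2] <- 5
  b <- nb_wald_test(x2, groups, s2)
  expect_equal(a$log2FC, b$log2FC, tolerance = 1e-12)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
})

test_that("constant counts give log2FC 0 and p ~ 1; degenerate designs error", {
  cnt <- matrix(50, nrow = 3, ncol = 6,
                dimnames = list(c("g1", "g2", "g3"),
                                c(paste0("c", 1:3), paste0("t", 1:3))))
  x <- count_matrix(cnt, species = "target", lengths = 1000)
  res <- nb_wald_test(x, rep(c("control", "treated"), each = 3), rep(1, 6))
  expect_equal(res$log2FC, rep(0, 3))
  expect_true(all(res$pvalue > 0.99))

  expect_error(nb_wald_test(x, c("control", rep("treated", 5)), rep(1, 6)),
               "2 replicates")
  zero <- count_matrix(matrix(c(0, 0, 5, 6), nrow = 1,
                              dimnames = list("g", paste0("s", 1:4))),
                       species = "target", lengths = 100)
  expect_error(nb_wald_test(zero, rep(c("control", "treated"), each = 2),
                            rep(1, 4)), "all-zero")
})

test_that("log2FC is recovered within +-0.3 for a strong true effect", {
  # 200 independent genes all with true log2FC = 2 stand in for 200
  # replicate simulations of one gene at depth-1e5-scale counts
  set.seed(1234)
  n <- 200
  muC <- 500
  cnt <- cbind(
    matrix(rnbinom(3 * n, mu = muC, size = 100), nrow = n),
    matrix(rnbinom(3 * n, mu = 4 * muC, size = 100), nrow = n))
  dimnames(cnt) <- list(sprintf("g%03d", 1:n),
                        c(paste0("c", 1:3), paste0("t", 1:3)))
  x <- count_matrix(cnt, species = "target", lengths = 1000)
  res <- nb_wald_test(x, rep(c("control", "treated"), each = 3), rep(1, 6))
  expect_gte(mean(abs(res$log2FC - 2) <= 0.3), 0.95)
})

test_that("power increases with sequencing depth", {
  cfg_for <- function(depth, seed) {
    sim_config(n_genes = 400, n_spikein = 60, depth = depth,
               fraction_upregulated = 0.25, fraction_unchanged = 0.75,
               upregulated_log2fc = 2, repression_factor = 1, seed = seed)
  }
  power_at <- function(depth) {
    cfg <- cfg_for(depth, seed = 42)
    ann <- simulate_annotation(cfg)
    sim <- simulate_counts(ann, cfg)
    groups <- rep(c("control", "treated"), each = 3)
    de <- call_de(nb_wald_test(sim$counts, groups,
                               spikein_size_factors(sim$counts)))
    truth <- sim$truth[sim$truth$species == "target", ]
    mean(de$status[match(truth$gene_id[truth$group == "up"],
                         de$gene_id)] == "up")
  }
  p <- vapply(c(2e3, 2e4, 2e5), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], p[1])
})

test_that("status thresholds follow the 2-fold / FDR < 0.05 convention", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    baseMeanC = 10, baseMeanT = 20,
                    log2FC = c(1.5, 1.5, -3, 0.2),
                    SE = 0.1, stat = 1,
                    pvalue = c(0.001, 0.1, 1e-7, 0.5),
                    FDR = c(0.01, 0.2, 1e-6, 0.9),
                    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  out <- call_de(res)
  expect_equal(out$status, c("up", "ns", "down", "ns"))
  expr <- matrix(c(0.5, 2, 3, 4), ncol = 1,
                 dimnames = list(c("a", "b", "c", "d"), "s1"))
  out2 <- call_de(res, min_expr = 1, expr = expr)
  expect_equal(out2$status[1], "low_expr")
  expect_equal(out2$status[3], "down")
})

test_that("fold-change estimates agree with an established NB GLM on simulated data", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 150, n_spikein = 40, depth = 3e5,
                    fraction_upregulated = 0.2, fraction_unchanged = 0.3,
                    repression_factor = 0.4, seed = 21)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  groups <- rep(c("control", "treated"), each = 3)
  sf <- spikein_size_factors(sim$counts)
  ours <- nb_wald_test(sim$counts, groups, sf)

  cnt <- sim$counts$counts[sim$counts$species == "target", ]
  storage.mode(cnt) <- "integer"
  cd <- data.frame(condition = factor(groups, c("control", "treated")))
  dds <- DESeq2::DESeqDataSetFromMatrix(cnt, cd, ~condition)
  DESeq2::sizeFactors(dds) <- as.numeric(sf)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)$log2FoldChange
  keep <- is.finite(ref) & abs(ref) < 5
  expect_gt(cor(ours$log2FC[keep], ref[keep]), 0.98)
  expect_lt(median(abs(ours$log2FC[keep] - ref[keep])), 0.1)
})
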