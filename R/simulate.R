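#' Simulation configuration
#'
#' One configuration object drives every simulator. The defaults describe the
#' study conditions the analysis stages are validated against: a dual-species
#' experiment with ~10% spike-in material, 3 vs 3 replicates at 2 million
#' reads each, negative-binomial dispersion 0.05, 80% of target genes
#' repressed 5-fold with a 10% minority truly upregulated 4-fold (the global
#' repression regime an acute Pol II degron produces), pulse-chase timepoints
#' 0/1/3/12 h with half-lives log-uniform on 0.5-24 h and 10% multiplicative
#' noise, and coverage tracks with a TSS bump, uniform body and optional
#' post-TES tail.
#'
#' All randomness flows from `seed` through a documented splitting scheme
#' (one derived sub-seed per simulator), so every simulator is independently
#' reproducible.
#'
#' @param n_genes number of target genes.
#' @param n_spikein number of spike-in genes.
#' @param gene_length_meanlog,gene_length_sdlog lognormal gene-length
#'   parameters (bp); defaults span the Short/Medium/Long classes.
#' @param gene_length_min,gene_length_max clamp on simulated lengths (bp).
#' @param intergenic_gap minimum gap between genes (bp); must be >= 2000 so
#'   that 2 kb TES windows never collide, default 5000 so TSS bumps and TES
#'   tails of convergent neighbours cannot touch either.
#' @param genes_per_chrom genes placed per toy chromosome.
#' @param chrom_length optional fixed chromosome length (bp); an error if the
#'   genes plus gaps do not fit.
#' @param depth expected total reads per sample.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`); 0
#'   gives Poisson counts.
#' @param fraction_upregulated,fraction_unchanged fraction of target genes
#'   truly up, and truly unchanged; the remainder is repressed.
#' @param upregulated_log2fc true log2 fold change of upregulated genes.
#' @param repression_factor multiplicative effect on repressed genes in the
#'   treated condition (0.2 = 5-fold repression).
#' @param spikein_fraction share of each library from spike-in genes.
#' @param n_reps replicates per condition for count simulation.
#' @param timepoints pulse-chase timepoints in hours (must include 0).
#' @param pulse_reps replicates per timepoint.
#' @param n_stable number of designated stable transcripts (half-life
#'   infinite), mirroring the ribosomal-protein/Gapdh anchor set.
#' @param halflife_range range of true half-lives (h), sampled log-uniformly.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   noise on pulse-chase values.
#' @param distortion_range per-sample scale distortion range (uniform);
#'   timepoint-0 samples are undistorted so recovered scale factors are
#'   directly comparable to the truth.
#' @param pausing_range,readthrough_range,body_level_range ranges of true
#'   pausing index, readthrough index and body signal level for track
#'   simulation (log-uniform for pausing/body, uniform for readthrough).
#' @param track_noise_cv,track_bin multiplicative noise CV and bin width (bp)
#'   of simulated coverage tracks.
#' @param seed master seed (integer < 2^31).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_spikein = 200L,
                       gene_length_meanlog = log(8000), gene_length_sdlog = 1,
                       gene_length_min = 2500L, gene_length_max = 200000L,
                       intergenic_gap = 5000L, genes_per_chrom = 500L,
                       chrom_length = NULL,
                       depth = 2e6, dispersion = 0.05,
                       fraction_upregulated = 0.1, fraction_unchanged = 0.1,
                       upregulated_log2fc = 2, repression_factor = 0.2,
                       spikein_fraction = 0.1, n_reps = 3L,
                       timepoints = c(0, 1, 3, 12), pulse_reps = 2L,
                       n_stable = 7L, halflife_range = c(0.5, 24),
                       noise_cv = 0.1, distortion_range = c(0.7, 1.3),
                       pausing_range = c(2, 10), readthrough_range = c(0.05, 1),
                       body_level_range = c(1, 10),
                       track_noise_cv = 0.1, track_bin = 10L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$n_spikein >= 0,
            cfg$fraction_upregulated >= 0, cfg$fraction_upregulated < 1,
            cfg$fraction_unchanged >= 0,
            cfg$fraction_upregulated + cfg$fraction_unchanged <= 1,
            cfg$repression_factor > 0, cfg$depth > 0,
            cfg$dispersion >= 0, cfg$noise_cv >= 0,
            cfg$seed == round(cfg$seed), abs(cfg$seed) < 2^31)
  if (cfg$intergenic_gap < 2000) {
    stop("intergenic_gap must be >= 2000 bp so TES windows cannot collide")
  }
  if (any(cfg$timepoints < 0)) stop("timepoints must be non-negative")
  if (!0 %in% cfg$timepoints) stop("timepoints must include 0")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic sub-seed per simulation stage; keeps every derived seed in
# 32-bit range (products stay below 2^53 so doubles are exact).
sub_seed <- function(seed, stage) {
  (abs(seed) * 48271 + stage) %% 2147483647
}

#' Simulate a toy gene annotation
#'
#' Places genes sequentially, separated by at least `intergenic_gap`, on toy
#' target chromosomes (`chr1`, `chr2`, ...) and one spike-in chromosome
#' (`spike1`), with strands drawn at random (both always represented).
#' Lengths are lognormal, clamped to the configured range. The layout
#' guarantees that the +-2 kb TES windows and TSS bumps used downstream never
#' overlap a neighbouring gene.
#'
#' @param config a [sim_config()].
#' @return A [gene_annotation()] with a `seqlengths` attribute.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  n_all <- config$n_genes + config$n_spikein
  len <- round(stats::rlnorm(n_all, config$gene_length_meanlog,
                             config$gene_length_sdlog))
  len <- pmin(pmax(len, config$gene_length_min), config$gene_length_max)
  strand <- sample(c("+", "-"), n_all, replace = TRUE)
  if (n_all >= 2 && length(unique(strand)) == 1) {
    strand[n_all] <- setdiff(c("+", "-"), strand[1])
  }
  ids <- c(sprintf("gene%05d", seq_len(config$n_genes)),
           if (config$n_spikein > 0) sprintf("spike%04d", seq_len(config$n_spikein)))
  species <- rep(c("target", "spikein"), c(config$n_genes, config$n_spikein))
  chrom_of <- function(i, prefix, per_chrom) {
    paste0(prefix, (i - 1L) %/% per_chrom + 1L)
  }
  chrom <- c(chrom_of(seq_len(config$n_genes), "chr", config$genes_per_chrom),
             if (config$n_spikein > 0)
               chrom_of(seq_len(config$n_spikein), "spike", config$genes_per_chrom))
  start <- integer(n_all)
  gap <- as.integer(config$intergenic_gap)
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    pos <- gap
    for (i in idx) {
      start[i] <- pos
      pos <- pos + len[i] + gap
    }
    if (!is.null(config$chrom_length) && pos > config$chrom_length) {
      stop(sprintf("infeasible packing: %s needs %d bp but chrom_length is %d",
                   chr, pos, config$chrom_length))
    }
  }
  ends <- start + len
  sl_val <- vapply(split(ends + gap, chrom), max, numeric(1))
  if (!is.null(config$chrom_length)) sl_val[] <- config$chrom_length
  gene_annotation(ids, chrom, start, ends, strand,
                  species = species,
                  seqlengths = stats::setNames(as.integer(sl_val), names(sl_val)))
}

rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate a dual-species spike-in count matrix
#'
#' Counts are negative binomial with mean `depth * relative_abundance *
#' condition_effect`. Target genes are split into truly upregulated
#' (`2^upregulated_log2fc`), truly unchanged, and globally repressed
#' (`repression_factor`) sets; spike-in genes are untouched by condition, so
#' per-sample spike-in totals differ only through depth. Treated libraries
#' are *not* renormalized to constant depth: a genuine global repression
#' shrinks the target share of the library, which is exactly the regime where
#' spike-in-blind normalization misclassifies unchanged genes.
#'
#' @param annotation a [gene_annotation()] (from [simulate_annotation()]).
#' @param config a [sim_config()].
#' @param truth optional truth table from a previous call (same annotation):
#'   reuses the gene-effect assignment so an independent replicate experiment
#'   (e.g. a second degron construct) shares the same true up-set.
#' @param seed_offset added to the stage sub-seed; use a different offset per
#'   replicate experiment.
#' @return `list(counts = count_matrix, truth = data.frame)`; the truth
#'   carries `gene_id`, `species`, `group`
#'   (`up`/`unchanged`/`repressed`/`spikein`) and `true_log2fc`.
#' @export
simulate_counts <- function(annotation, config, truth = NULL, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  validate_gene_annotation(annotation)
  if (config$depth <= 0) stop("depth must be positive")
  is_spike <- annotation$species == "spikein"
  if (!any(is_spike)) stop("annotation has no spikein genes")
  n_target <- sum(!is_spike)

  set.seed(sub_seed(config$seed, 2L))
  if (is.null(truth)) {
    n_up <- round(config$fraction_upregulated * n_target)
    n_unch <- round(config$fraction_unchanged * n_target)
    grp <- rep("repressed", n_target)
    pick <- sample.int(n_target, n_up + n_unch)
    grp[pick[seq_len(n_up)]] <- "up"
    grp[pick[n_up + seq_len(n_unch)]] <- "unchanged"
    group <- character(nrow(annotation))
    group[!is_spike] <- grp
    group[is_spike] <- "spikein"
    lfc <- ifelse(group == "up", config$upregulated_log2fc,
                  ifelse(group == "repressed", log2(config$repression_factor), 0))
    truth <- data.frame(gene_id = annotation$gene_id,
                        species = annotation$species,
                        group = group, true_log2fc = lfc,
                        stringsAsFactors = FALSE)
  } else {
    if (!identical(truth$gene_id, annotation$gene_id)) {
      stop("truth table does not match annotation")
    }
  }
  set.seed(sub_seed(config$seed, 20L + seed_offset))
  w <- stats::rlnorm(nrow(annotation), 0, 1)
  a <- numeric(nrow(annotation))
  a[!is_spike] <- w[!is_spike] / sum(w[!is_spike]) * (1 - config$spikein_fraction)
  a[is_spike] <- w[is_spike] / sum(w[is_spike]) * config$spikein_fraction
  effect <- 2^truth$true_log2fc
  n_rep <- config$n_reps
  samples <- c(paste0("control_", seq_len(n_rep)), paste0("treated_", seq_len(n_rep)))
  mu <- cbind(
    matrix(rep(config$depth * a, n_rep), ncol = n_rep),
    matrix(rep(config$depth * a * effect, n_rep), ncol = n_rep)
  )
  cnt <- matrix(rnb(length(mu), as.vector(mu), config$dispersion),
                nrow = nrow(annotation),
                dimnames = list(annotation$gene_id, samples))
  list(
    counts = count_matrix(cnt, species = annotation$species,
                          lengths = annotation$end - annotation$start),
    truth = truth
  )
}

lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate 4sU pulse-chase time courses
#'
#' Each target gene decays from its baseline level with first-order kinetics:
#' the expected signal at time `t` is `E0 * exp(-k t)`, multiplied by a
#' per-sample scale distortion and lognormal noise of the configured CV. A
#' designated stable set (`n_stable` genes, drawn at high expression like the
#' ribosomal-protein anchors) has `k = 0`. Timepoint-0 samples carry
#' distortion 1; all other samples draw a distortion from
#' `distortion_range`, which stable-transcript scaling must undo.
#'
#' @param annotation a [gene_annotation()]; only target genes are simulated.
#' @param config a [sim_config()].
#' @param conditions named list; each element is `NULL` (half-lives as drawn)
#'   or `list(multiplier = m, genes = ids)` scaling the half-life of `genes`
#'   (all genes when `NULL`) by `m` in that condition.
#' @return `list(tpm, meta, truth)`: a TPM-scale matrix (target genes x
#'   samples), sample metadata (`sample_id`, `condition`, `timepoint_h`,
#'   `replicate`), and truth with per-gene per-condition `true_halflife`
#'   (hours, `Inf` for stable genes), `stable` flags and per-sample
#'   `distortion`.
#' @export
simulate_pulse_chase <- function(annotation, config,
                                 conditions = list(untreated = NULL)) {
  stopifnot(inherits(config, "sim_config"))
  validate_gene_annotation(annotation)
  if (any(config$timepoints < 0)) stop("negative timepoint")
  ann <- annotation[annotation$species == "target", , drop = FALSE]
  n <- nrow(ann)
  set.seed(sub_seed(config$seed, 3L))
  stable_idx <- sample.int(n, min(config$n_stable, n))
  stable <- ann$gene_id[stable_idx]
  e0 <- stats::rlnorm(n, log(20), 1.5)
  e0[stable_idx] <- stats::rlnorm(length(stable_idx), log(200), 0.3)
  hl <- exp(stats::runif(n, log(config$halflife_range[1]),
                         log(config$halflife_range[2])))
  hl[stable_idx] <- Inf

  tps <- sort(unique(config$timepoints))
  reps <- seq_len(config$pulse_reps)
  meta <- expand.grid(replicate = reps, timepoint_h = tps,
                      condition = names(conditions),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("condition", "timepoint_h", "replicate")]
  meta$sample_id <- sprintf("%s_t%g_r%d", meta$condition, meta$timepoint_h,
                            meta$replicate)
  distortion <- ifelse(meta$timepoint_h == 0, 1,
                       stats::runif(nrow(meta), config$distortion_range[1],
                                    config$distortion_range[2]))
  hl_cond <- matrix(rep(hl, length(conditions)), ncol = length(conditions),
                    dimnames = list(ann$gene_id, names(conditions)))
  for (cn in names(conditions)) {
    spec <- conditions[[cn]]
    if (!is.null(spec)) {
      genes <- if (is.null(spec$genes)) ann$gene_id else spec$genes
      hl_cond[genes, cn] <- hl_cond[genes, cn] * spec$multiplier
    }
  }
  k_cond <- log(2) / hl_cond  # Inf half-life -> k = 0
  tpm <- matrix(0, nrow = n, ncol = nrow(meta),
                dimnames = list(ann$gene_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    kj <- k_cond[, meta$condition[j]]
    expected <- e0 * exp(-kj * meta$timepoint_h[j]) * distortion[j]
    tpm[, j] <- expected * lognorm_noise(n, config$noise_cv)
  }
  truth_hl <- do.call(rbind, lapply(names(conditions), function(cn) {
    data.frame(gene_id = ann$gene_id, condition = cn,
               true_halflife = hl_cond[, cn], true_k = k_cond[, cn],
               stable = ann$gene_id %in% stable, baseline_level = e0,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(tpm = tpm, meta = meta,
       truth = list(halflife = truth_hl,
                    distortion = data.frame(sample_id = meta$sample_id,
                                            distortion = distortion,
                                            stringsAsFactors = FALSE),
                    stable_genes = stable))
}

# bins covering [start, end) at `bin` resolution with per-bin noisy values
noisy_bins <- function(start, end, level, bin, cv) {
  if (end <= start) {
    return(data.frame(start = integer(0), end = integer(0), value = numeric(0)))
  }
  edges <- seq(start, end, by = bin)
  if (edges[length(edges)] < end) edges <- c(edges, end)
  s <- edges[-length(edges)]
  e <- edges[-1]
  data.frame(start = s, end = e, value = level * lognorm_noise(length(s), cv))
}

#' Simulate stranded coverage tracks with known indices
#'
#' For every gene the sense-strand signal is: a TSS bump over -30..+300 bp of
#' the TSS at level `PI_g * b_g`, a uniform body at level `b_g` from +300 bp
#' of the TSS to the TES, and a post-TES tail over the 2 kb past the TES at
#' level `RI_g * b_g`, each with per-bin multiplicative lognormal noise. The
#' noise has mean 1, so the constructed pausing and readthrough indices equal
#' `PI_g` and `RI_g` in expectation and exactly at zero noise.
#'
#' @param annotation a [gene_annotation()]; only target genes get signal.
#' @param config a [sim_config()].
#' @return `list(tracks = list(plus, minus, combined), truth)` where truth
#'   has `gene_id`, `true_pausing`, `true_readthrough`, `body_level`. The
#'   `combined` track is the strand sum, usable as an unstranded occupancy
#'   track because simulated genes never overlap.
#' @export
simulate_tracks <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_gene_annotation(annotation)
  ann <- annotation[annotation$species == "target", , drop = FALSE]
  sl <- attr(annotation, "seqlengths")
  set.seed(sub_seed(config$seed, 4L))
  n <- nrow(ann)
  pi_true <- exp(stats::runif(n, log(config$pausing_range[1]),
                              log(config$pausing_range[2])))
  ri_true <- stats::runif(n, config$readthrough_range[1],
                          config$readthrough_range[2])
  body <- exp(stats::runif(n, log(config$body_level_range[1]),
                           log(config$body_level_range[2])))
  cv <- config$track_noise_cv
  bin <- config$track_bin
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- ann$start[i]; e <- ann$end[i]
    if (ann$strand[i] == "+") {
      parts <- rbind(
        noisy_bins(s - 30L, s + 300L, pi_true[i] * body[i], bin, cv),
        noisy_bins(s + 300L, e, body[i], bin, cv),
        noisy_bins(e, e + 2000L, ri_true[i] * body[i], bin, cv))
    } else {
      parts <- rbind(
        noisy_bins(s - 2000L, s, ri_true[i] * body[i], bin, cv),
        noisy_bins(s, e - 300L, body[i], bin, cv),
        noisy_bins(e - 300L, e + 30L, pi_true[i] * body[i], bin, cv))
    }
    parts$chrom <- ann$chrom[i]
    parts$strand <- ann$strand[i]
    segs[[i]] <- parts
  }
  segs <- do.call(rbind, segs)
  if (any(segs$start < 0)) stop("simulated window extends past chromosome start")
  build <- function(str) {
    d <- segs[segs$strand == str, , drop = FALSE]
    rles <- lapply(split(d, d$chrom), function(r) {
      r <- r[order(r$start), , drop = FALSE]
      rle_from_sorted_runs(r$start, r$end, r$value)
    })
    coverage_track(rles, strand = if (str == "+") "+" else "-")
  }
  plus <- build("+"); minus <- build("-")
  chroms <- unique(ann$chrom)
  comb <- lapply(chroms, function(chr) {
    p <- plus$rle[[chr]]; m <- minus$rle[[chr]]
    len <- max(length(p), length(m), if (!is.null(sl)) sl[[chr]] else 0L)
    pad <- function(x) {
      if (is.null(x)) return(S4Vectors::Rle(0, len))
      if (length(x) < len) c(x, S4Vectors::Rle(0, len - length(x))) else x
    }
    pad(p) + pad(m)
  })
  names(comb) <- chroms
  plus$rle <- plus$rle[intersect(chroms, names(plus$rle))]
  minus$rle <- minus$rle[intersect(chroms, names(minus$rle))]
  list(
    tracks = list(plus = plus, minus = minus,
                  combined = coverage_track(comb, strand = "unstranded")),
    truth = data.frame(gene_id = ann$gene_id, true_pausing = pi_true,
                       true_readthrough = ri_true, body_level = body,
                       stringsAsFactors = FALSE)
  )
}
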