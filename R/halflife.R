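#' Stable-transcript scaling of pulse-chase expression
#'
#' Rescales a pulse-chase TPM matrix so that designated stable transcripts
#' (the ribosomal-protein/Gapdh anchor set in the real experiment) are flat
#' across samples: the per-sample factor is
#' `c_j = geomean_stable(TPM_j) / ref`, where `ref` is the geometric mean of
#' the same quantity over the reference (timepoint 0) samples, and every
#' value is divided by `c_j`. Reference samples therefore get `c = 1` up to
#' their own noise, and in the noise-free limit the recovered factors equal
#' the simulated per-sample distortions exactly.
#'
#' Stable genes with a zero anywhere are dropped with a warning (the
#' geometric mean cannot carry them); if all are dropped it is an error.
#'
#' @param tpm numeric matrix, genes x samples (rownames = gene ids).
#' @param stable_genes character vector of stable transcript ids; all must
#'   be present in `tpm`.
#' @param reference_samples column names (or indices) of the timepoint-0
#'   reference samples.
#' @return `list(scale_factors, rescaled, stable_used)`.
#' @export
stable_gene_scaling <- function(tpm, stable_genes, reference_samples) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)))
  if (!length(stable_genes)) stop("stable gene set is empty")
  missing_ids <- setdiff(stable_genes, rownames(tpm))
  if (length(missing_ids)) {
    stop("stable genes absent from matrix: ", paste(missing_ids, collapse = ", "))
  }
  if (is.character(reference_samples)) {
    if (!all(reference_samples %in% colnames(tpm))) {
      stop("unknown reference samples")
    }
  }
  sub <- tpm[stable_genes, , drop = FALSE]
  bad <- apply(sub, 1, function(x) any(x <= 0))
  if (any(bad)) {
    warning("dropping stable gene(s) with non-positive values: ",
            paste(stable_genes[bad], collapse = ", "))
    sub <- sub[!bad, , drop = FALSE]
  }
  if (nrow(sub) == 0) stop("no usable stable genes (all dropped)")
  g <- exp(colMeans(log(sub)))
  ref <- exp(mean(log(g[reference_samples])))
  c_j <- g / ref
  list(scale_factors = c_j,
       rescaled = sweep(tpm, 2, c_j, "/"),
       stable_used = rownames(sub))
}

#' Expression filter on baseline samples
#'
#' Keeps genes whose mean TPM across the untreated timepoint-0 samples
#' exceeds `threshold` (strictly: `TPM > 0.2` is the study's convention, so
#' a gene at exactly the threshold is dropped).
#'
#' @param tpm numeric matrix, genes x samples.
#' @param reference_samples untreated timepoint-0 sample names or indices.
#' @param threshold TPM floor (default 0.2).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(tpm, reference_samples, threshold = 0.2) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)))
  if (!length(reference_samples)) stop("no timepoint-0 reference samples")
  ref <- tpm[, reference_samples, drop = FALSE]
  rownames(tpm)[rowMeans(ref) > threshold]
}

#' First-order decay fit for one gene
#'
#' Least-squares fit of `log(value) = log(A) - k t`. Replicate measurements
#' at the same timepoint are averaged on the log scale before fitting (so
#' each timepoint carries equal leverage); non-positive values are dropped
#' first and counted. Half-life is `ln(2)/k`; a fitted `k <= 0` is flagged
#' `nondecaying` with infinite half-life, and fewer than `min_points` usable
#' timepoints is flagged `insufficient_points`.
#'
#' @param times numeric vector of timepoints (hours).
#' @param values matched expression values (rescaled TPM).
#' @param min_points minimum usable timepoints (default 3).
#' @param average_replicates average log-values per timepoint first
#'   (default) or fit all points individually.
#' @param k_tol slopes with `k <= k_tol` (1/h) count as non-decaying; the
#'   default absorbs round-off on exactly flat series.
#' @return One-row data.frame: `k`, `halflife`, `intercept`, `rmse_log`,
#'   `n_points`, `n_dropped`, `flag` (`ok`, `nondecaying`,
#'   `insufficient_points`).
#' @export
fit_decay <- function(times, values, min_points = 3L, average_replicates = TRUE,
                      k_tol = 1e-10) {
  stopifnot(length(times) == length(values))
  keep <- is.finite(values) & values > 0 & is.finite(times)
  n_dropped <- sum(!keep)
  t_u <- times[keep]; v <- values[keep]
  if (average_replicates && length(t_u)) {
    lv <- tapply(log(v), t_u, mean)
    t_u <- as.numeric(names(lv))
    logv <- as.numeric(lv)
  } else {
    logv <- log(v)
  }
  out <- data.frame(k = NA_real_, halflife = NA_real_, intercept = NA_real_,
                    rmse_log = NA_real_, n_points = length(t_u),
                    n_dropped = n_dropped, flag = "insufficient_points",
                    stringsAsFactors = FALSE)
  if (length(t_u) < min_points || length(unique(t_u)) < 2) return(out)
  fit <- stats::lm.fit(cbind(1, t_u), logv)
  k <- -fit$coefficients[2]
  out$k <- as.numeric(k)
  out$intercept <- exp(fit$coefficients[1])
  out$rmse_log <- sqrt(mean(fit$residuals^2))
  if (k <= k_tol) {
    out$halflife <- Inf
    out$flag <- "nondecaying"
  } else {
    out$halflife <- log(2) / as.numeric(k)
    out$flag <- "ok"
  }
  out
}

#' Half-life table across conditions
#'
#' The full pulse-chase pipeline: optional spike-in size-factor
#' normalization, per-condition stable-transcript scaling (each condition's
#' own timepoint-0 samples as reference), the baseline TPM > `tpm_threshold`
#' expression filter (evaluated on the baseline condition's timepoint-0
#' samples), and a first-order decay fit per gene and condition. Genes
#' failing the filter appear with flag `filtered_low_expr` and no estimate.
#'
#' When more than one condition is present, a paired table of
#' `log2(halflife_condition / halflife_baseline)` is returned (NA when
#' either fit is missing or infinite).
#'
#' @param tpm numeric matrix, genes x samples.
#' @param meta data.frame with `sample_id`, `condition`, `timepoint_h` (and
#'   optionally `replicate`) matching `colnames(tpm)`.
#' @param stable_genes stable transcript ids for [stable_gene_scaling()].
#' @param size_factors optional per-sample spike-in size factors.
#' @param tpm_threshold baseline expression floor (default 0.2).
#' @param baseline_condition condition used for the filter and as the
#'   denominator of the paired comparison (default `"untreated"`, or the
#'   first condition present).
#' @param min_points passed to [fit_decay()].
#' @return `list(fits, delta, scale_factors)`: `fits` is a long data.frame
#'   (gene x condition), `delta` the paired log2 half-life table (NULL for a
#'   single condition), `scale_factors` the recovered per-sample scaling.
#' @export
halflife_table <- function(tpm, meta, stable_genes, size_factors = NULL,
                           tpm_threshold = 0.2,
                           baseline_condition = "untreated",
                           min_points = 3L) {
  stopifnot(is.matrix(tpm),
            all(c("sample_id", "condition", "timepoint_h") %in% names(meta)))
  if (!setequal(meta$sample_id, colnames(tpm))) {
    stop("meta sample_id does not match tpm columns")
  }
  meta <- meta[match(colnames(tpm), meta$sample_id), , drop = FALSE]
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(tpm), all(size_factors > 0))
    tpm <- sweep(tpm, 2, as.numeric(size_factors), "/")
  }
  conds <- unique(meta$condition)
  if (!baseline_condition %in% conds) baseline_condition <- conds[1]
  if (!any(meta$condition == baseline_condition & meta$timepoint_h == 0)) {
    stop("baseline condition has no timepoint-0 sample")
  }

  sf_all <- stats::setNames(rep(NA_real_, ncol(tpm)), colnames(tpm))
  rescaled <- tpm
  for (cn in conds) {
    cols <- meta$sample_id[meta$condition == cn]
    ref <- meta$sample_id[meta$condition == cn & meta$timepoint_h == 0]
    if (!length(ref)) stop("condition ", cn, " has no timepoint-0 sample")
    sc <- stable_gene_scaling(tpm[, cols, drop = FALSE], stable_genes, ref)
    rescaled[, cols] <- sc$rescaled
    sf_all[cols] <- sc$scale_factors
  }
  base_ref <- meta$sample_id[meta$condition == baseline_condition &
                               meta$timepoint_h == 0]
  kept <- filter_expressed(rescaled, base_ref, tpm_threshold)

  fits <- vector("list", length(conds))
  names(fits) <- conds
  for (cn in conds) {
    cols <- meta$sample_id[meta$condition == cn]
    tms <- meta$timepoint_h[match(cols, meta$sample_id)]
    sub <- rescaled[, cols, drop = FALSE]
    per_gene <- lapply(rownames(sub), function(g) {
      if (!g %in% kept) {
        data.frame(k = NA_real_, halflife = NA_real_, intercept = NA_real_,
                   rmse_log = NA_real_, n_points = 0L, n_dropped = 0L,
                   flag = "filtered_low_expr", stringsAsFactors = FALSE)
      } else {
        fit_decay(tms, sub[g, ], min_points = min_points)
      }
    })
    df <- do.call(rbind, per_gene)
    df <- cbind(data.frame(gene_id = rownames(sub), condition = cn,
                           stringsAsFactors = FALSE), df)
    fits[[cn]] <- df
  }
  fits <- do.call(rbind, c(fits, make.row.names = FALSE))

  delta <- NULL
  others <- setdiff(conds, baseline_condition)
  if (length(others)) {
    base <- fits[fits$condition == baseline_condition, ]
    delta <- data.frame(gene_id = base$gene_id,
                        halflife_baseline = base$halflife,
                        stringsAsFactors = FALSE)
    for (cn in others) {
      cur <- fits[fits$condition == cn, ]
      cur <- cur[match(delta$gene_id, cur$gene_id), ]
      d <- log2(cur$halflife / delta$halflife_baseline)
      d[!is.finite(d)] <- NA_real_
      delta[[paste0("halflife_", cn)]] <- cur$halflife
      delta[[paste0("delta_log2_", cn)]] <- d
    }
  }
  list(fits = fits, delta = delta, scale_factors = sf_all)
}
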