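#' Minimal negative-binomial Wald test for two groups
#'
#' A deliberately small two-group differential-expression test on spike-in
#' (or otherwise) normalized counts, modelled on the standard NB workflow but
#' without shrinkage: per-gene normalized counts `q_gj = N_gj / s_j`, group
#' means, method-of-moments dispersion on normalized counts (floored at
#' 1e-8), `log2FC = log2((mu_T + pc) / (mu_C + pc))` with pseudocount
#' `pc = 0.5`, a delta-method standard error from the NB variance
#' `mu + alpha * mu^2`, and a two-sided Wald p-value. The Wald statistic is
#' referred to a t distribution with `n_C + n_T - 2` degrees of freedom: with
#' few replicates the dispersion estimate is noisy and a normal reference is
#' anticonservative.
#'
#' Only target-species genes are tested; spike-in genes inform the size
#' factors, not the test.
#'
#' @param counts a [count_matrix()].
#' @param groups per-sample labels, coercible to a factor whose levels (in
#'   order) are control then treated; e.g. `c("control","control","treated",
#'   "treated")`.
#' @param size_factors positive per-sample size factors (e.g. from
#'   [spikein_size_factors()]).
#' @param dispersion `"per_gene"` (method-of-moments per gene) or `"common"`
#'   (one pooled dispersion, the median of per-gene estimates — steadier for
#'   tiny toy matrices).
#' @param pseudocount added to both group means inside the fold change.
#' @param dispersion_floor lower bound on the dispersion estimate.
#' @return A `de_result` data.frame: `gene_id`, `baseMeanC`, `baseMeanT`,
#'   `log2FC`, `SE`, `stat`, `pvalue`, `FDR` (Benjamini-Hochberg), `alpha`.
#' @export
nb_wald_test <- function(counts, groups, size_factors,
                         dispersion = c("per_gene", "common"),
                         pseudocount = 0.5, dispersion_floor = 1e-8) {
  stopifnot(inherits(counts, "count_matrix"))
  dispersion <- match.arg(dispersion)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (length(groups) != ncol(counts$counts)) {
    stop("groups must label every sample")
  }
  s <- as.numeric(size_factors)
  if (length(s) != ncol(counts$counts) || any(!is.finite(s)) || any(s <= 0)) {
    stop("size factors must be positive, one per sample")
  }
  lev <- levels(groups)
  iC <- which(groups == lev[1]); iT <- which(groups == lev[2])
  if (length(iC) < 2 || length(iT) < 2) {
    stop("need >= 2 replicates per group (variance unidentifiable otherwise)")
  }
  keep <- counts$species == "target"
  raw <- counts$counts[keep, , drop = FALSE]
  if (all(raw[, iC] == 0) || all(raw[, iT] == 0)) {
    stop("a group has all-zero counts for every gene")
  }
  q <- sweep(raw, 2, s, "/")
  muC <- rowMeans(q[, iC, drop = FALSE])
  muT <- rowMeans(q[, iT, drop = FALSE])
  vC <- apply(q[, iC, drop = FALSE], 1, stats::var)
  vT <- apply(q[, iT, drop = FALSE], 1, stats::var)

  # moments taken on the normalized scale only, so results depend on q alone
  # (scaling a sample's counts and size factor together changes nothing)
  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, NA_real_)
  aC <- mom(vC, muC); aT <- mom(vT, muT)
  wC <- length(iC) - 1L; wT <- length(iT) - 1L
  alpha_g <- ifelse(
    is.na(aC) & is.na(aT), NA_real_,
    (ifelse(is.na(aC), 0, wC * aC) + ifelse(is.na(aT), 0, wT * aT)) /
      (ifelse(is.na(aC), 0, wC) + ifelse(is.na(aT), 0, wT))
  )
  alpha_g <- pmax(alpha_g, dispersion_floor)
  if (dispersion == "common") {
    common <- stats::median(alpha_g, na.rm = TRUE)
    if (!is.finite(common)) common <- dispersion_floor
    alpha_g <- rep(max(common, dispersion_floor), length(alpha_g))
  }
  alpha_g[is.na(alpha_g)] <- dispersion_floor

  varC <- (muC + alpha_g * muC^2) / length(iC)
  varT <- (muT + alpha_g * muT^2) / length(iT)
  lfc <- log2((muT + pseudocount) / (muC + pseudocount))
  se <- sqrt(varT / (muT + pseudocount)^2 + varC / (muC + pseudocount)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  df <- length(iC) + length(iT) - 2L
  p <- 2 * stats::pt(-abs(stat), df = df)
  both_zero <- muC == 0 & muT == 0
  p[both_zero] <- 1; stat[both_zero] <- 0
  res <- data.frame(
    gene_id = rownames(raw), baseMeanC = muC, baseMeanT = muT,
    log2FC = lfc, SE = se, stat = stat, pvalue = p,
    FDR = bh_adjust(p), alpha = alpha_g,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("de_result", "data.frame")
  attr(res, "groups") <- stats::setNames(lev, c("control", "treated"))
  attr(res, "df") <- df
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]) with input validation.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differential-expression status
#'
#' Applies the study's significance convention — a 2-fold cutoff
#' (`|log2FC| >= 1`) and FDR < 0.05 — to a [nb_wald_test()] result. Genes
#' below an optional expression floor are labelled `low_expr` and excluded
#' from `up`/`down`.
#'
#' @param results a `de_result` data.frame.
#' @param lfc_threshold minimum `|log2FC|` (default 1, i.e. 2-fold).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param min_expr optional expression floor; requires `expr`.
#' @param expr optional expression matrix (e.g. RPKM, genes x samples); a
#'   gene passes the floor iff its maximum over samples exceeds `min_expr`.
#' @return The input with a `status` column in
#'   `{up, down, ns, low_expr}`.
#' @export
call_de <- function(results, lfc_threshold = 1, fdr_threshold = 0.05,
                    min_expr = NULL, expr = NULL) {
  stopifnot(inherits(results, "de_result"),
            lfc_threshold > 0, fdr_threshold > 0)
  status <- rep("ns", nrow(results))
  status[results$log2FC >= lfc_threshold & results$FDR < fdr_threshold] <- "up"
  status[results$log2FC <= -lfc_threshold & results$FDR < fdr_threshold] <- "down"
  if (!is.null(min_expr)) {
    if (is.null(expr)) stop("min_expr filtering needs an expression matrix")
    mx <- apply(expr[results$gene_id, , drop = FALSE], 1, max)
    status[mx <= min_expr] <- "low_expr"
  }
  results$status <- status
  results
}
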