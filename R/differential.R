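#' Counts-per-million normalization
#'
#' `cpm[u, s] = counts[u, s] * 1e6 / library_size[s]`.
#'
#' @param counts Non-negative integer matrix, units x samples.
#' @param lib_size Library sizes per sample; defaults to column sums. All
#'   must be positive.
#' @return Numeric matrix of cpm values, same dimensions.
#' @export
cpm_normalize <- function(counts, lib_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_size <= 0)) stop("library size must be positive for every sample")
  sweep(counts, 2, lib_size / 1e6, "/")
}

#' Expression filter on condition-mean cpm
#'
#' Keeps units whose mean cpm exceeds `min_cpm` in every condition
#' (the "expressed in all conditions" rule; default threshold 2 cpm).
#'
#' @param cpm Numeric cpm matrix, units x samples.
#' @param condition Factor/character of length `ncol(cpm)`.
#' @param min_cpm Threshold (strict `>`; default 2).
#' @return Logical vector over rows: `TRUE` = keep.
#' @export
filter_expressed <- function(cpm, condition, min_cpm = 2) {
  cpm <- as.matrix(cpm)
  if (nrow(cpm) == 0) return(logical(0))
  cond_means <- .group_means(cpm, condition)
  apply(cond_means > min_cpm, 1, all)
}

#' Minimum read-support filter
#'
#' Keeps units whose total count reaches `min_reads` in at least one
#' condition (default 5 mapped reads).
#'
#' @param counts Integer matrix, units x samples.
#' @param condition Factor/character of length `ncol(counts)`.
#' @param min_reads Threshold (default 5, `>=`).
#' @return Logical vector over rows: `TRUE` = keep.
#' @export
filter_min_reads <- function(counts, condition, min_reads = 5L) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0) return(logical(0))
  cond <- factor(condition)
  totals <- sapply(levels(cond), function(l) {
    rowSums(counts[, cond == l, drop = FALSE])
  })
  totals <- matrix(totals, nrow = nrow(counts))
  apply(totals >= min_reads, 1, any)
}

.group_means <- function(m, condition) {
  cond <- factor(condition)
  res <- sapply(levels(cond), function(l) {
    rowMeans(m[, cond == l, drop = FALSE])
  })
  matrix(res, nrow = nrow(m), dimnames = list(rownames(m), levels(cond)))
}

#' Differential count test (negative-binomial Wald approximation)
#'
#' Estimates per-unit log2 fold changes from condition-mean cpm with a
#' pseudo-count, and p-values from a Wald test on the log mean difference
#' of library-size-scaled counts, using a per-unit method-of-moments
#' negative-binomial dispersion floored at 0 (the Poisson limit) and a t
#' reference with `n1 + n2 - 2` degrees of freedom. This is a deliberately
#' simple, self-contained approximation of a generalized-linear-model
#' quasi-likelihood count test; see the methods vignette for its
#' calibration properties.
#'
#' @param counts Integer matrix, units x samples.
#' @param condition Factor/character of length `ncol(counts)`.
#' @param treated,control Condition labels of the contrast
#'   (`treated` vs `control`).
#' @param lib_size Library sizes; defaults to column sums.
#' @param prior_cpm Pseudo-count added to condition-mean cpm before the
#'   log ratio (default 0.5).
#' @return A `DiffTable` data.frame: `unit`, `log2fc`, `p`, `padj`,
#'   `cpm_control`, `cpm_treated`. `p` is `NA` when either group has fewer
#'   than 2 replicates.
#' @export
diff_test <- function(counts, condition, treated, control,
                      lib_size = colSums(counts), prior_cpm = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("'condition' must have one entry per sample")
  }
  if (!all(c(treated, control) %in% condition)) {
    stop("both contrast levels must appear in 'condition'")
  }
  if (treated == control) stop("contrast needs two distinct conditions")
  it <- which(condition == treated)
  ic <- which(condition == control)
  cpm <- cpm_normalize(counts, lib_size)
  mc <- rowMeans(cpm[, ic, drop = FALSE])
  mt <- rowMeans(cpm[, it, drop = FALSE])
  log2fc <- log2((mt + prior_cpm) / (mc + prior_cpm))

  p <- rep(NA_real_, nrow(counts))
  n1 <- length(ic); n2 <- length(it)
  if (n1 >= 2 && n2 >= 2) {
    # counts rescaled to the mean library depth so that group means and
    # variances are comparable across samples
    sc <- sweep(counts, 2, mean(lib_size) / lib_size, "*")
    y1 <- sc[, ic, drop = FALSE]
    y2 <- sc[, it, drop = FALSE]
    m1 <- rowMeans(y1); m2 <- rowMeans(y2)
    v1 <- .row_vars(y1); v2 <- .row_vars(y2)
    num <- (n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)
    den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
    phi <- pmax(0, num / pmax(den, 1e-12))
    eps <- 0.5
    delta <- log(m2 + eps) - log(m1 + eps)
    se <- sqrt((1 / pmax(m1, eps) + phi) / n1 + (1 / pmax(m2, eps) + phi) / n2)
    p <- 2 * stats::pt(-abs(delta / se), df = n1 + n2 - 2)
  }
  data.frame(
    unit = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
           else rownames(counts),
    log2fc = log2fc,
    p = p,
    padj = bh_adjust(p),
    cpm_control = mc,
    cpm_treated = mt,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

.row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1, order preserved. `NA` p-values stay `NA` and do not enter
#' the adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-condition usage fractions of poly(A) clusters
#'
#' For each gene and condition, the usage of a cluster is its summed count
#' divided by the gene's summed count over all clusters in that condition.
#'
#' @param df data.frame with columns `gene_id`, `cluster_id` and one count
#'   column per sample (or a `support` matrix).
#' @param counts Numeric matrix clusters x samples, aligned to rows of `df`.
#' @param condition Factor/character per sample.
#' @return Matrix clusters x conditions of usage fractions; `NaN` where a
#'   gene has zero counts in a condition.
#' @export
cluster_usage <- function(df, counts, condition) {
  counts <- as.matrix(counts)
  cond <- factor(condition)
  sums <- sapply(levels(cond), function(l) {
    rowSums(counts[, cond == l, drop = FALSE])
  })
  sums <- matrix(sums, nrow = nrow(counts), dimnames = list(NULL, levels(cond)))
  gene_tot <- apply(sums, 2, function(col) {
    stats::ave(col, df$gene_id, FUN = sum)
  })
  sums / gene_tot
}

#' Call alternative polyadenylation per gene
#'
#' A gene is called when it has at least `min_pacs` clusters and at least
#' one cluster that is both significant (`padj < padj_max`) and shows an
#' absolute usage-fraction change of at least `min_frac_change` between
#' conditions. The direction is keyed to the most distal qualifying
#' cluster in the direction of transcription: `lengthening` when it gains
#' usage in the treated condition, `shortening` when it loses usage.
#' Genes with zero total counts in a condition (undefined usage) are
#' skipped.
#'
#' @param df data.frame with columns `gene_id`, `pos`, `strand`, `padj`,
#'   `usage_control`, `usage_treated` (one row per cluster).
#' @param padj_max Significance cutoff (default 0.1, strict `<`).
#' @param min_frac_change Minimum absolute usage change (default 0.10).
#' @param min_pacs Minimum clusters per gene (default 2).
#' @return data.frame per gene: `gene_id`, `called`, `direction`
#'   (`lengthening`/`shortening`/`NA`), `n_pacs`.
#' @export
call_apa <- function(df, padj_max = 0.1, min_frac_change = 0.10, min_pacs = 2L) {
  need <- c("gene_id", "pos", "strand", "padj", "usage_control", "usage_treated")
  if (!all(need %in% names(df))) {
    stop("call_apa needs columns: ", paste(need, collapse = ", "))
  }
  res <- lapply(split(df, df$gene_id), function(g) {
    out <- data.frame(gene_id = g$gene_id[1], called = FALSE,
                      direction = NA_character_, n_pacs = nrow(g),
                      stringsAsFactors = FALSE)
    if (anyNA(g$usage_control) || anyNA(g$usage_treated) ||
        any(is.nan(g$usage_control)) || any(is.nan(g$usage_treated))) {
      message("gene ", g$gene_id[1], " skipped: usage undefined in a condition")
      return(out)
    }
    if (nrow(g) < min_pacs) return(out)
    dchange <- g$usage_treated - g$usage_control
    qual <- !is.na(g$padj) & g$padj < padj_max & abs(dchange) >= min_frac_change
    if (!any(qual)) return(out)
    gq <- g[qual, , drop = FALSE]
    distal <- if (gq$strand[1] == "-") which.min(gq$pos) else which.max(gq$pos)
    out$called <- TRUE
    out$direction <- if ((gq$usage_treated - gq$usage_control)[distal] > 0)
      "lengthening" else "shortening"
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
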