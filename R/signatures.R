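#' Per-gene Z-scores across samples
#'
#' Standardizes each gene's expression across samples:
#' `(x - mean) / sd`, using the sample (n-1) standard deviation. Genes
#' with zero variance are dropped with a warning.
#'
#' @param em Numeric matrix, genes x samples (>= 2 samples, unique gene
#'   row names).
#' @return Z-score matrix with the constant genes removed.
#' @export
zscore_by_gene <- function(em) {
  em <- as.matrix(em)
  if (ncol(em) < 2) stop("need at least 2 samples to standardize")
  if (anyDuplicated(rownames(em))) stop("duplicated gene ids in matrix")
  sds <- apply(em, 1, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- sum(sds == 0 | is.na(sds))
    warning(bad, " constant gene(s) dropped before Z-scoring")
    em <- em[sds > 0 & !is.na(sds), , drop = FALSE]
    sds <- sds[sds > 0 & !is.na(sds)]
  }
  (em - rowMeans(em)) / sds
}

#' Average Z-score of a gene set per sample
#'
#' The signature score of a sample is the unweighted mean of the Z-scores
#' of the set genes present in the matrix; set genes absent from the
#' matrix are dropped and reported in the provenance fields.
#'
#' @param z Z-score matrix from [zscore_by_gene()].
#' @param gs A `GeneSet` (see [gene_set()]) or character vector of gene
#'   ids.
#' @return A `SignatureScore`: list with `score` (named per-sample
#'   vector), `set_name`, `n_used`, `n_missing`.
#' @export
signature_score <- function(z, gs) {
  genes <- if (inherits(gs, "GeneSet")) gs$genes else unique(as.character(gs))
  name <- if (inherits(gs, "GeneSet")) gs$name else "geneset"
  present <- intersect(genes, rownames(z))
  if (length(present) == 0) stop("no gene of the set is present in the matrix")
  structure(list(
    score = colMeans(z[present, , drop = FALSE]),
    set_name = name,
    n_used = length(present),
    n_missing = length(genes) - length(present)
  ), class = "SignatureScore")
}

#' @export
print.SignatureScore <- function(x, ...) {
  cat("SignatureScore '", x$set_name, "': ", length(x$score),
      " samples (", x$n_used, " genes used, ", x$n_missing, " missing)\n",
      sep = "")
  invisible(x)
}

#' Correlate two per-sample score vectors
#'
#' The headline R is the Pearson correlation; the p-value comes from a
#' two-sided Spearman rank-correlation test (the convention used for
#' cohort signature-vs-driver comparisons).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: `pearson_r`, `spearman_rho`, `spearman_p`.
#' @export
correlate_scores <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the score vectors")
  }
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(
    pearson_r = stats::cor(x, y, method = "pearson"),
    spearman_rho = unname(sp$estimate),
    spearman_p = sp$p.value
  )
}

#' Compare signature scores between two groups
#'
#' Unpaired two-sided t-test (Welch by default; set `var_equal = TRUE`
#' for the pooled-variance test).
#'
#' @param scores A `SignatureScore` or numeric vector.
#' @param groups Factor/character with exactly two levels, aligned to the
#'   scores; each group needs n >= 2.
#' @param var_equal Use pooled variance (default `FALSE`).
#' @return List: `t`, `p`, `group_means` (named), `levels`. The t
#'   statistic is for `first level - second level`.
#' @export
compare_groups <- function(scores, groups, var_equal = FALSE) {
  v <- if (inherits(scores, "SignatureScore")) scores$score else scores
  g <- factor(groups)
  if (nlevels(g) != 2) stop("'groups' must have exactly two levels")
  if (any(table(g) < 2)) stop("each group needs at least 2 samples")
  tt <- stats::t.test(v[g == levels(g)[1]], v[g == levels(g)[2]],
                      var.equal = var_equal)
  list(
    t = unname(tt$statistic),
    p = tt$p.value,
    group_means = stats::setNames(tapply(v, g, mean), levels(g)),
    levels = levels(g)
  )
}

#' Read a genes-in-rows expression matrix from TSV
#'
#' First column = gene id, remaining columns = samples, header mandatory.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a genes-in-rows expression matrix as TSV
#'
#' @param m Numeric matrix with gene row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
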