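#' PAC-score: relative shift of poly(A)-site usage toward a region
#'
#' `pac_score = log2FC(region PAC counts) - log2FC(annotated 3' UTR PAC
#' counts)`, both from the same contrast. A positive score means cleavage
#' shifted toward the region (e.g. the 10-kb downstream window) relative
#' to the annotated 3' UTR; any pure-expression change common to both
#' regions cancels. Set `sign = -1` to flip the orientation for forensic
#' comparison with alternative conventions.
#'
#' @param lfc_region log2 fold change of PAC counts in the non-UTR region.
#' @param lfc_utr3 log2 fold change of PAC counts in the annotated 3' UTR.
#' @param sign Orientation multiplier, `+1` (default) or `-1`.
#' @return Numeric vector of scores; `NA` where either component is `NA`.
#' @export
pac_score <- function(lfc_region, lfc_utr3, sign = 1) {
  stopifnot(sign %in% c(-1, 1))
  sign * (lfc_region - lfc_utr3)
}

#' Build a PAC-score table for one region class
#'
#' Joins per-unit PAC-seq differential results (units `gene|region`) with
#' gene-level RNA-seq fold changes, computes the PAC-score of the given
#' region class against the `utr3` class, and labels quadrants. Only genes
#' quantifiable by all three metrics (region log2FC, utr3 log2FC,
#' expression log2FC) receive a score.
#'
#' @param pac_diff `DiffTable` from [diff_test()] on PAC counts with units
#'   named `gene|region_class`.
#' @param rna_diff `DiffTable` from [diff_test()] on gene-level RNA-seq
#'   counts (units are gene ids).
#' @param region_class One of `"intron"`, `"cds"`, `"downstream10k"`.
#' @return data.frame: `gene_id`, `region_class`, `lfc_region`,
#'   `lfc_utr3`, `pac_score`, `lfc_expr`, `quadrant`.
#' @export
pac_score_table <- function(pac_diff, rna_diff, region_class = "downstream10k") {
  parts <- strsplit(pac_diff$unit, "|", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  cls <- vapply(parts, `[`, "", 2L)
  reg <- pac_diff[cls == region_class, ]
  reg_gene <- gene[cls == region_class]
  utr <- pac_diff[cls == "utr3", ]
  utr_gene <- gene[cls == "utr3"]
  genes <- intersect(intersect(reg_gene, utr_gene), rna_diff$unit)
  df <- data.frame(
    gene_id = genes,
    region_class = rep(region_class, length(genes)),
    lfc_region = reg$log2fc[match(genes, reg_gene)],
    lfc_utr3 = utr$log2fc[match(genes, utr_gene)],
    lfc_expr = rna_diff$log2fc[match(genes, rna_diff$unit)],
    stringsAsFactors = FALSE
  )
  df$pac_score <- pac_score(df$lfc_region, df$lfc_utr3)
  df$quadrant <- classify_quadrants(df$pac_score, df$lfc_expr)
  df[, c("gene_id", "region_class", "lfc_region", "lfc_utr3",
         "pac_score", "lfc_expr", "quadrant")]
}

#' Classify genes into expression/usage quadrants
#'
#' Quadrant I: decreased expression, increased region usage
#' (`lfc_expr < 0`, `score > 0`); QII: both increased; QIII: increased
#' expression, decreased usage; QIV: both decreased. Exact zeros or
#' missing values are `unclassified`.
#'
#' @param score PAC-score vector.
#' @param lfc_expr RNA-seq log2 fold change vector.
#' @return Character vector of labels
#'   (`QI`, `QII`, `QIII`, `QIV`, `unclassified`).
#' @export
classify_quadrants <- function(score, lfc_expr) {
  q <- rep("unclassified", length(score))
  ok <- !is.na(score) & !is.na(lfc_expr) & score != 0 & lfc_expr != 0
  q[ok & score > 0 & lfc_expr < 0] <- "QI"
  q[ok & score > 0 & lfc_expr > 0] <- "QII"
  q[ok & score < 0 & lfc_expr > 0] <- "QIII"
  q[ok & score < 0 & lfc_expr < 0] <- "QIV"
  q
}

#' Summarize quadrant membership
#'
#' @param quadrant Character vector from [classify_quadrants()].
#' @return Named integer vector of counts over the five labels.
#' @export
quadrant_counts <- function(quadrant) {
  lv <- c("QI", "QII", "QIII", "QIV", "unclassified")
  tab <- table(factor(quadrant, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' Derive the quadrant-I (lengthened & downregulated) gene set
#'
#' A gene is included when it shows both a PAC-score above `pac_min`
#' (usage shift toward the region, typically the 10-kb downstream window)
#' and an expression log2FC below `lfc_max` in at least `min_contrasts`
#' of the supplied contrasts (strict inequalities).
#'
#' @param tables List of >= `min_contrasts` PAC-score tables from
#'   [pac_score_table()] (one per contrast / cell line).
#' @param pac_min PAC-score threshold (default 0.5).
#' @param lfc_max Expression log2FC threshold (default -0.25).
#' @param min_contrasts Minimum contrasts a gene must qualify in
#'   (default 2).
#' @param name Gene-set name.
#' @return A `GeneSet`: list with `name`, `genes`, `provenance`.
#' @export
derive_qi_geneset <- function(tables, pac_min = 0.5, lfc_max = -0.25,
                              min_contrasts = 2L,
                              name = "lengthened_down_QI") {
  if (length(tables) < min_contrasts) {
    stop("need at least ", min_contrasts, " contrast tables")
  }
  passes <- lapply(tables, function(t) {
    t$gene_id[!is.na(t$pac_score) & !is.na(t$lfc_expr) &
                t$pac_score > pac_min & t$lfc_expr < lfc_max]
  })
  genes <- sort(unique(unlist(passes)))
  n_pass <- vapply(genes, function(g) {
    sum(vapply(passes, function(p) g %in% p, logical(1)))
  }, 0L)
  gene_set(name, genes[n_pass >= min_contrasts],
           provenance = list(pac_min = pac_min, lfc_max = lfc_max,
                             min_contrasts = min_contrasts,
                             n_contrasts = length(tables)))
}

#' Construct a GeneSet object
#'
#' @param name Set name.
#' @param genes Character vector of member gene ids (de-duplicated).
#' @param provenance Non-empty list recording how the set was derived.
#' @return A `GeneSet` S3 object.
#' @export
gene_set <- function(name, genes, provenance) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(provenance), length(provenance) > 0)
  structure(list(name = name, genes = sort(unique(as.character(genes))),
                 provenance = provenance),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Derive up/down gene sets from extreme signed -log10 FDR
#'
#' Per table, the signed score of a gene is
#' `sign(log2FC) * (-log10 padj)` with `padj` floored at 1e-300. The `up`
#' set is the intersection across tables of genes with signed score above
#' `threshold`; the `down` set is the intersection of genes with signed
#' score below `-threshold`.
#'
#' @param de_tables List of >= 2 `DiffTable` data.frames.
#' @param threshold Signed-score cutoff (default 4).
#' @param name_prefix Prefix for the two set names.
#' @return List with `up` and `down` `GeneSet` objects.
#' @export
derive_extreme_fdr_genesets <- function(de_tables, threshold = 4,
                                        name_prefix = "knockdown") {
  stopifnot(length(de_tables) >= 2)
  signed <- lapply(de_tables, function(t) {
    s <- sign(t$log2fc) * (-log10(pmax(t$padj, 1e-300)))
    stats::setNames(s, t$unit)
  })
  pick <- function(cmp) {
    sets <- lapply(signed, function(s) names(s)[!is.na(s) & cmp(s)])
    Reduce(intersect, sets)
  }
  prov <- list(threshold = threshold, n_tables = length(de_tables))
  list(
    up = gene_set(paste0(name_prefix, "_UP"),
                  pick(function(s) s > threshold), prov),
    down = gene_set(paste0(name_prefix, "_DOWN"),
                    pick(function(s) s < -threshold), prov)
  )
}

#' Pre-ranked gene list from unadjusted p-values
#'
#' Ranking metric `sign(log2FC) * (-log10 p)` (p floored at 1e-300),
#' sorted descending so the most significantly up-regulated genes sit at
#' the top and the most significantly down-regulated at the bottom; ties
#' are broken lexicographically by gene id for determinism.
#'
#' @param de_table A `DiffTable` data.frame.
#' @return data.frame `gene`, `metric`, sorted for export with
#'   [write_rnk()].
#' @export
prerank_metric <- function(de_table) {
  ok <- !is.na(de_table$p) & !is.na(de_table$log2fc)
  t <- de_table[ok, ]
  metric <- sign(t$log2fc) * (-log10(pmax(t$p, 1e-300)))
  o <- order(-metric, t$unit)
  data.frame(gene = t$unit[o], metric = metric[o], stringsAsFactors = FALSE)
}

#' Write gene sets in GMT format
#'
#' @param sets A `GeneSet` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "pacscope", s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path.
#' @return Named list of `GeneSet` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gene_set(f[1], f[-(1:2)], provenance = list(source = path))
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write a pre-ranked list in RNK format
#'
#' @param ranked data.frame from [prerank_metric()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
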