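#' @title Region classes for poly(A)-site counting
#' @description
#' The genome is partitioned, per gene, into four stranded region classes:
#' the annotated 3' UTR extended 300 nt in the 3' direction (`utr3`), the
#' coding sequence (`cds`), the remainder of the gene body (`intron`), and
#' a 10-kb window downstream of the gene's 3' end (`downstream10k`).
#' A region set is represented as a `GRanges` with metadata columns
#' `gene_id` and `region_class`; intervals within one gene are disjoint and
#' share the gene's strand.
#' @name region-classes
NULL

.region_set <- function(grl, region_class) {
  gr <- unlist(grl, use.names = FALSE)
  if (length(gr) > 0) {
    gr$gene_id <- rep(names(grl), lengths(grl))
    names(gr) <- NULL
    gr$region_class <- region_class
  } else {
    gr$gene_id <- character(0)
    gr$region_class <- character(0)
  }
  sort(gr, ignore.strand = TRUE)
}

# GRangesList of per-gene merged features, one (possibly empty) element per
# gene id in `levels`
.by_gene <- function(gr, levels) {
  GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(gr),
                     factor(gr$gene_id, levels = levels))
  )
}

#' Build the extended 3' UTR region class
#'
#' Each annotated 3' UTR feature is extended by `extension_nt` bases in the
#' direction of transcription (to capture poly(A) sites just beyond the
#' annotated end), clipped to chromosome bounds, then unioned across the
#' transcripts of each gene.
#'
#' @param ann A `GenomeAnnotation` from [load_annotation()].
#' @param extension_nt 3'-ward extension in nucleotides (default 300).
#' @return A region-set `GRanges` (see [region-classes]) with
#'   `region_class = "utr3"`. Genes without an annotated 3' UTR are absent.
#' @export
build_utr3_regions <- function(ann, extension_nt = 300L) {
  u <- ann$utr3
  if (length(u) == 0) return(.region_set(GenomicRanges::GRangesList(), "utr3"))
  # out-of-bound ranges are expected here; they are clipped just below
  ext <- suppressWarnings(
    GenomicRanges::resize(u, GenomicRanges::width(u) + extension_nt, fix = "start")
  )
  ext <- .clip_to_chrom(ext)
  lev <- sort(unique(ext$gene_id))
  .region_set(.by_gene(ext, lev), "utr3")
}

#' Build the CDS region class
#'
#' Union of annotated CDS features across the transcripts of each gene.
#'
#' @inheritParams build_utr3_regions
#' @return A region-set `GRanges` with `region_class = "cds"`.
#' @export
build_cds_regions <- function(ann) {
  cds <- ann$cds
  if (length(cds) == 0) return(.region_set(GenomicRanges::GRangesList(), "cds"))
  lev <- sort(unique(cds$gene_id))
  .region_set(.by_gene(cds, lev), "cds")
}

#' Build the intron region class
#'
#' Per gene, the full gene span minus the merged CDS minus the gene's
#' extended 3' UTR intervals. Note that by this recipe 5' UTR exonic bases
#' remain in the `intron` class; the class is the "rest of the gene body"
#' once coding and 3'-UTR sequence are removed.
#'
#' @inheritParams build_utr3_regions
#' @param utr3 The extended 3' UTR region set from [build_utr3_regions()],
#'   built from the same annotation.
#' @return A region-set `GRanges` with `region_class = "intron"`.
#' @export
build_intron_regions <- function(ann, utr3) {
  genes <- ann$genes
  if (length(genes) == 0) return(.region_set(GenomicRanges::GRangesList(), "intron"))
  lev <- genes$gene_id
  spans <- GenomicRanges::granges(genes)
  names(spans) <- lev
  mask <- S4Vectors::pc(.by_gene(ann$cds, lev), .by_gene(utr3, lev))
  mask <- GenomicRanges::reduce(mask)
  res <- GenomicRanges::psetdiff(spans, mask)
  names(res) <- lev
  .region_set(res, "intron")
}

#' Build the 10-kb downstream region class
#'
#' Per gene, a window of `window_nt` bases starting at the gene's 3' end in
#' the direction of transcription, minus all same-strand exons and all
#' extended 3' UTR intervals of any gene (own or neighboring), clipped to
#' chromosome bounds. Opposite-strand features are not subtracted.
#'
#' @inheritParams build_intron_regions
#' @param window_nt Window length in nucleotides (default 10000).
#' @return A region-set `GRanges` with `region_class = "downstream10k"`.
#' @export
build_downstream_regions <- function(ann, utr3, window_nt = 10000L) {
  genes <- ann$genes
  if (length(genes) == 0) {
    return(.region_set(GenomicRanges::GRangesList(), "downstream10k"))
  }
  win <- suppressWarnings(
    GenomicRanges::flank(GenomicRanges::granges(genes), window_nt, start = FALSE)
  )
  win <- .clip_to_chrom(win)
  names(win) <- genes$gene_id
  mask <- GenomicRanges::reduce(c(GenomicRanges::granges(ann$exons),
                                  GenomicRanges::granges(utr3)))
  # strand-aware overlap keeps only same-strand mask pieces per window
  hits <- GenomicRanges::findOverlaps(win, mask)
  mlist <- IRanges::extractList(mask, methods::as(hits, "List"))
  res <- GenomicRanges::psetdiff(win, mlist)
  names(res) <- genes$gene_id
  .region_set(res, "downstream10k")
}

#' Build all four region classes at once
#'
#' @inheritParams build_utr3_regions
#' @param window_nt Downstream window length (default 10000).
#' @return Named list of region-set `GRanges`:
#'   `utr3`, `cds`, `intron`, `downstream10k`.
#' @export
build_all_regions <- function(ann, extension_nt = 300L, window_nt = 10000L) {
  utr3 <- build_utr3_regions(ann, extension_nt)
  list(
    utr3 = utr3,
    cds = build_cds_regions(ann),
    intron = build_intron_regions(ann, utr3),
    downstream10k = build_downstream_regions(ann, utr3, window_nt)
  )
}

.clip_to_chrom <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(sl))) return(gr)
  n_out <- sum(GenomicRanges::start(gr) < 1 |
                 GenomicRanges::end(gr) > sl[as.character(GenomeInfoDb::seqnames(gr))],
               na.rm = TRUE)
  if (n_out > 0) message(n_out, " interval(s) clipped at chromosome bounds")
  GenomicRanges::trim(gr)
}

#' Write a region set as BED6
#'
#' Lines are `chrom  start  end  gene_id|region_class  0  strand`,
#' 0-based half-open, sorted by chromosome then start. A header comment
#' records the column layout; [read_regions_bed()] round-trips the file.
#'
#' @param rs A region-set `GRanges` (see [region-classes]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6: chrom start end gene_id|region_class score strand", con)
  if (length(rs) > 0) {
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(rs)),
      start = GenomicRanges::start(rs) - 1L,
      end = GenomicRanges::end(rs),
      name = paste0(rs$gene_id, "|", rs$region_class),
      score = 0L,
      strand = as.character(BiocGenerics::strand(rs))
    )
    df <- df[order(df$chrom, df$start), ]
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a region-set BED6 written by [write_regions_bed()]
#'
#' @param path Path to the BED file.
#' @return A region-set `GRanges`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$gene_id <- character(0)
    gr$region_class <- character(0)
    return(gr)
  }
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score", "strand"))
  parts <- strsplit(df$name, "|", fixed = TRUE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  gr$gene_id <- vapply(parts, `[`, "", 1L)
  gr$region_class <- vapply(parts, `[`, "", 2L)
  sort(gr, ignore.strand = TRUE)
}
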