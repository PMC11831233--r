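# Independent brute-force oracles used to cross-check the interval algebra,
# the read assignment, and the multiple-testing adjustment.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# --- toy GTF construction -------------------------------------------------

gtf_line <- function(chrom, type, start, end, strand, gene, tx = NULL,
                     biotype = "protein_coding", tag = NULL) {
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', gene, biotype)
  if (!is.null(tx)) attrs <- sprintf('%s transcript_id "%s";', attrs, tx)
  if (!is.null(tag)) attrs <- sprintf('%s tag "%s";', attrs, tag)
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

write_toy_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

# a single-transcript gene with explicit feature coordinates (1-based)
toy_gene_lines <- function(gene, chrom, strand, span, exons, cds, utr3,
                           biotype = "protein_coding", tag = NULL) {
  tx <- paste0(gene, ".t1")
  c(gtf_line(chrom, "gene", span[1], span[2], strand, gene, biotype = biotype),
    gtf_line(chrom, "transcript", span[1], span[2], strand, gene, tx,
             biotype = biotype, tag = tag),
    unlist(lapply(exons, function(e) gtf_line(chrom, "exon", e[1], e[2],
                                              strand, gene, tx, biotype, tag))),
    unlist(lapply(cds, function(e) gtf_line(chrom, "CDS", e[1], e[2],
                                            strand, gene, tx, biotype, tag))),
    unlist(lapply(utr3, function(e) gtf_line(chrom, "three_prime_utr", e[1], e[2],
                                             strand, gene, tx, biotype, tag))))
}

# --- per-base region classification oracle --------------------------------

# Classifies every relevant base by looping over the textual rules, with no
# interval algebra: extended 3' UTR bases, CDS bases, gene-span-minus-both
# for introns, and the downstream window minus all same-strand exon and
# extended-3'UTR bases.
oracle_region_bases <- function(ann, extension_nt = 300, window_nt = 10000,
                                chrom_len = NULL) {
  to_df <- function(gr) {
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
               end = end(gr), strand = as.character(strand(gr)),
               gene = gr$gene_id, stringsAsFactors = FALSE)
  }
  genes <- to_df(ann$genes)
  exons <- to_df(ann$exons)
  cds <- to_df(ann$cds)
  utr <- to_df(ann$utr3)
  L <- function(chrom) if (is.null(chrom_len)) Inf else chrom_len[[chrom]]
  # extend each 3' UTR feature 3'-ward, clipped
  utr$ext_start <- ifelse(utr$strand == "+", utr$start,
                          pmax(1, utr$start - extension_nt))
  utr$ext_end <- ifelse(utr$strand == "+",
                        pmin(vapply(utr$chrom, L, 0), utr$end + extension_nt),
                        utr$end)
  expand <- function(df, s = "start", e = "end") {
    if (nrow(df) == 0) return(integer(0))
    unlist(lapply(seq_len(nrow(df)), function(i) df[[s]][i]:df[[e]][i]))
  }
  # global same-strand mask intervals (exons + extended 3' UTRs of ALL genes)
  mask <- rbind(
    data.frame(chrom = exons$chrom, start = exons$start, end = exons$end,
               strand = exons$strand),
    data.frame(chrom = utr$chrom, start = utr$ext_start, end = utr$ext_end,
               strand = utr$strand)
  )
  res <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gu <- utr[utr$gene == g$gene, , drop = FALSE]
    gc <- cds[cds$gene == g$gene, , drop = FALSE]
    utr3_b <- unique(expand(gu, "ext_start", "ext_end"))
    cds_b <- unique(expand(gc))
    span_b <- g$start:g$end
    intron_b <- setdiff(setdiff(span_b, cds_b), utr3_b)
    w <- if (g$strand == "+") {
      (g$end + 1):min(L(g$chrom), g$end + window_nt)
    } else {
      max(1, g$start - window_nt):(g$start - 1)
    }
    near <- mask[mask$strand == g$strand & mask$chrom == g$chrom &
                   mask$start <= max(w) & mask$end >= min(w), , drop = FALSE]
    ds_b <- setdiff(w, unique(expand(near)))
    res[[g$gene]] <- list(utr3 = sort(utr3_b), cds = sort(cds_b),
                          intron = sort(intron_b), downstream10k = sort(ds_b))
  }
  res
}

# expand one region set to per-gene sorted base vectors
region_set_bases <- function(rs) {
  if (length(rs) == 0) return(list())
  bases <- lapply(split(seq_along(rs), rs$gene_id), function(i) {
    sort(unlist(lapply(i, function(j) start(rs)[j]:end(rs)[j])))
  })
  bases
}

# check oracle vs algebra for every gene and class; returns number of
# disagreeing (gene, class) pairs
compare_regions_to_oracle <- function(regions, oracle) {
  mismatches <- 0L
  for (cls in names(regions)) {
    got <- region_set_bases(regions[[cls]])
    for (g in names(oracle)) {
      want <- oracle[[g]][[cls]]
      have <- if (g %in% names(got)) got[[g]] else integer(0)
      if (!identical(as.integer(want), as.integer(have))) {
        mismatches <- mismatches + 1L
      }
    }
  }
  mismatches
}

# number of (gene, class-pair) disjointness violations by per-base scan
count_disjoint_violations <- function(regions) {
  bases <- lapply(regions, region_set_bases)
  genes <- unique(unlist(lapply(bases, names)))
  cls <- names(regions)
  bad <- 0L
  for (g in genes) {
    for (i in seq_along(cls)) {
      for (j in seq_along(cls)) {
        if (j <= i) next
        a <- bases[[cls[i]]][[g]]
        b <- bases[[cls[j]]][[g]]
        if (!is.null(a) && !is.null(b) && length(intersect(a, b)) > 0) {
          bad <- bad + 1L
        }
      }
    }
  }
  bad
}

subset_region <- function(rs, gene) rs[rs$gene_id == gene]

# --- naive read/site assignment oracle ------------------------------------

# Per region class: for every interval, find sites whose position lies
# inside with matching strand; sites hitting >1 gene in a class are
# dropped. Independent of findOverlaps-based counting.
oracle_count_by_feature <- function(sites, regions, sense_stranded = TRUE) {
  supp <- sites$support
  if (!is.matrix(supp)) supp <- matrix(supp, ncol = 1,
                                       dimnames = list(NULL, "sample1"))
  gene_ids <- sort(unique(unlist(lapply(regions, function(r) r$gene_id))))
  classes <- names(regions)
  samples <- colnames(supp)
  counts <- array(0L, dim = c(length(gene_ids), length(classes), length(samples)),
                  dimnames = list(gene_ids, classes, samples))
  pos <- start(sites)
  schrom <- as.character(seqnames(sites))
  sstrand <- as.character(strand(sites))
  for (cls in classes) {
    reg <- regions[[cls]]
    gene_hits <- vector("list", length(sites))
    for (k in seq_along(reg)) {
      ok <- schrom == as.character(seqnames(reg))[k] &
        pos >= start(reg)[k] & pos <= end(reg)[k]
      if (sense_stranded) ok <- ok & sstrand == as.character(strand(reg))[k]
      for (s_i in which(ok)) {
        gene_hits[[s_i]] <- union(gene_hits[[s_i]], reg$gene_id[k])
      }
    }
    for (s_i in seq_along(sites)) {
      gh <- gene_hits[[s_i]]
      if (length(gh) == 1) {
        counts[gh, cls, ] <- counts[gh, cls, ] + supp[s_i, ]
      }
    }
  }
  counts
}

# --- step-up Benjamini-Hochberg by direct enumeration ---------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
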