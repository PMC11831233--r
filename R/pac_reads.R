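#' Detect and trim the 3' poly(A) tail of a raw read
#'
#' The tail is the longest suffix of the read that ends at its 3' terminus,
#' starts at an A, and contains at most `max_mismatch` non-A characters
#' (allowing for sequencing error inside the tail). A read passes the tail filter when
#' the number of A's in that suffix is at least `min_a` (default 25, the
#' minimum used when calling genuine poly(A)-derived reads). The insert is
#' the read minus the tail; reads whose tail consumes the whole read are
#' flagged by an empty insert and are expected to be discarded by callers.
#'
#' @param read_seq Character vector of read sequences over `A,C,G,T,N`.
#' @param min_a Minimum number of A's required in the tail (default 25).
#' @param max_mismatch Maximum non-A characters tolerated in the tail
#'   (default 2).
#' @return A data.frame with columns `insert`, `a_count`, `passes`.
#' @export
trim_polya <- function(read_seq, min_a = 25L, max_mismatch = 2L) {
  if (length(read_seq) == 0) {
    return(data.frame(insert = character(0), a_count = integer(0),
                      passes = logical(0)))
  }
  if (any(!nzchar(read_seq)) || anyNA(read_seq)) stop("empty read sequence")
  res <- lapply(strsplit(read_seq, "", fixed = TRUE), function(ch) {
    n <- length(ch)
    non_a <- rev(cumsum(rev(ch) != "A"))          # non-A count in suffix i..n
    suff <- which(non_a <= max_mismatch)          # candidate suffix starts
    if (length(suff) == 0) {
      c(tail_start = n + 1L, a_count = 0L)
    } else {
      s <- min(suff)
      while (s <= n && ch[s] != "A") s <- s + 1L  # a tail starts at an A
      c(tail_start = s,
        a_count = if (s > n) 0L else sum(ch[s:n] == "A"))
    }
  })
  tail_start <- vapply(res, `[[`, 0L, "tail_start")
  a_count <- vapply(res, `[[`, 0L, "a_count")
  data.frame(
    insert = substr(read_seq, 1L, tail_start - 1L),
    a_count = as.integer(a_count),
    passes = a_count >= min_a,
    stringsAsFactors = FALSE
  )
}

#' 3'-most aligned base of stranded alignments
#'
#' Collapses aligned spans to the single base that marks the cleavage
#' position: the alignment end for `+` strand reads, the alignment start
#' for `-` strand reads. Soft-clipped bases are assumed to have been
#' excluded from the spans already.
#'
#' @param gr `GRanges` of aligned spans with strand `+` or `-`.
#' @return `GRanges` of width-1 positions, metadata columns preserved.
#' @export
three_prime_pos <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) stop("unstranded alignment: strand must be '+' or '-'")
  GenomicRanges::resize(gr, width = 1L, fix = "end")
}

#' Filter candidate poly(A) sites for genomic internal priming
#'
#' A site is discarded when the genomic sequence immediately 3' of the
#' site, read on the transcript sense strand, contains more than `max_a`
#' A's in `window_nt` bases (default: more than 12 A in 20 nt). Such
#' A-rich tracts can prime the oligo(dT) reverse-transcription step and
#' mimic a poly(A) tail. For `-` strand sites the window lies at lower
#' `+`-strand coordinates and plus-strand T's are counted. Windows running
#' past a chromosome end are truncated (with a message).
#'
#' @param sites Width-1 `GRanges` of candidate sites.
#' @param genome Named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param window_nt Window length (default 20).
#' @param max_a Maximum tolerated A count (default 12); sites with
#'   `count > max_a` are removed.
#' @return Logical vector: `TRUE` for sites to keep.
#' @export
internal_priming_filter <- function(sites, genome, window_nt = 20L, max_a = 12L) {
  stopifnot(methods::is(sites, "GRanges"))
  if (length(sites) == 0) return(logical(0))
  chrom <- as.character(GenomeInfoDb::seqnames(sites))
  if (any(!chrom %in% names(genome))) {
    stop("site chromosome absent from genome: ",
         paste(setdiff(chrom, names(genome)), collapse = ", "))
  }
  st <- as.character(BiocGenerics::strand(sites))
  pos <- GenomicRanges::start(sites)
  clen <- stats::setNames(Biostrings::width(genome), names(genome))[chrom]
  from <- ifelse(st == "+", pos + 1L, pos - window_nt)
  to <- ifelse(st == "+", pos + window_nt, pos - 1L)
  trunc <- sum(from < 1L | to > clen)
  if (trunc > 0) message(trunc, " internal-priming window(s) truncated at chromosome end")
  from <- pmax(from, 1L)
  to <- pmin(to, clen)
  counts <- integer(length(sites))
  base <- ifelse(st == "+", "A", "T")   # sense-strand A
  for (ch in unique(chrom)) {
    i <- which(chrom == ch & to >= from)
    if (length(i) == 0) next
    v <- Biostrings::extractAt(genome[[ch]], IRanges::IRanges(from[i], to[i]))
    freq <- Biostrings::letterFrequency(v, c("A", "T"))
    counts[i] <- ifelse(base[i] == "A", freq[, "A"], freq[, "T"])
  }
  counts <= max_a
}

#' Cluster nearby poly(A) sites
#'
#' Single-linkage clustering of sites on the same chromosome and strand:
#' two sites belong to the same cluster when their positions differ by at
#' most `max_gap` (directly or through intermediate members). The cluster
#' representative is the member with the highest total support, ties broken
#' toward the most distal position in the direction of transcription.
#' Cluster support is the column sum of member supports.
#'
#' @param sites Width-1 `GRanges` with a metadata matrix column `support`
#'   (sites x samples) or a plain numeric `support` vector.
#' @param max_gap Maximum intra-cluster gap in nucleotides (default 25).
#' @return Width-1 `GRanges` at the representative positions with columns
#'   `support` (summed), `n_members`, `cluster_start`, `cluster_end`.
#' @export
cluster_sites <- function(sites, max_gap = 25L) {
  stopifnot(methods::is(sites, "GRanges"))
  if (length(sites) == 0) return(sites)
  supp <- .support_matrix(sites)
  key <- paste(GenomeInfoDb::seqnames(sites), BiocGenerics::strand(sites))
  out <- list()
  for (k in unique(key)) {
    i <- which(key == k)
    o <- i[order(GenomicRanges::start(sites)[i])]
    pos <- GenomicRanges::start(sites)[o]
    cl <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (c_id in unique(cl)) {
      m <- o[cl == c_id]
      msupp <- supp[m, , drop = FALSE]
      tot <- rowSums(msupp)
      minus <- as.character(BiocGenerics::strand(sites)[m[1]]) == "-"
      mpos <- GenomicRanges::start(sites)[m]
      # highest support; ties to the most distal (3'-most) position
      best <- which(tot == max(tot))
      best <- if (minus) best[which.min(mpos[best])] else best[which.max(mpos[best])]
      rep_gr <- GenomicRanges::granges(sites[m[best]])
      S4Vectors::mcols(rep_gr) <- S4Vectors::DataFrame(
        support = I(matrix(colSums(msupp), nrow = 1,
                           dimnames = list(NULL, colnames(msupp)))),
        n_members = length(m),
        cluster_start = min(mpos),
        cluster_end = max(mpos)
      )
      out[[length(out) + 1L]] <- rep_gr
    }
  }
  res <- suppressWarnings(do.call(c, out))
  sort(res, ignore.strand = TRUE)
}

.support_matrix <- function(sites) {
  supp <- sites$support
  if (is.null(supp)) stop("sites must carry a 'support' metadata column")
  if (is.matrix(supp)) supp else matrix(supp, ncol = 1,
                                        dimnames = list(NULL, "sample1"))
}

#' Count poly(A) sites into gene x region-class x sample tensor
#'
#' Each site (or cluster) is assigned by its position falling inside a
#' region interval; assignment is strand-specific by default, mirroring
#' counting of a same-stranded 3'-end library with the 3'-most base as the
#' assignment point. Within one region class, a site overlapping intervals
#' of more than one gene is ambiguous and discarded (counted in
#' `ambiguous`). The same site may be counted in different region classes
#' of different genes only if the classes genuinely overlap.
#'
#' @param sites Width-1 `GRanges` with `support` matrix column
#'   (sites x samples).
#' @param regions Named list of the four region sets from
#'   [build_all_regions()].
#' @param sense_stranded Require strand match (default `TRUE`).
#' @return A `FeatureCounts` object: list with `counts` (3-d array gene x
#'   region_class x sample), `library_sizes` (total retained support per
#'   sample), `ambiguous` and `assigned` per region class.
#' @export
count_by_feature <- function(sites, regions, sense_stranded = TRUE) {
  stopifnot(methods::is(sites, "GRanges"), is.list(regions))
  supp <- .support_matrix(sites)
  samples <- colnames(supp)
  gene_ids <- sort(unique(unlist(lapply(regions, function(r) r$gene_id))))
  classes <- names(regions)
  counts <- array(0L, dim = c(length(gene_ids), length(classes), length(samples)),
                  dimnames = list(gene_ids, classes, samples))
  ambiguous <- stats::setNames(integer(length(classes)), classes)
  assigned <- stats::setNames(integer(length(classes)), classes)
  for (cls in classes) {
    reg <- regions[[cls]]
    if (length(reg) == 0 || length(sites) == 0) next
    hits <- GenomicRanges::findOverlaps(sites, reg,
                                        ignore.strand = !sense_stranded)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits)
    g <- reg$gene_id[S4Vectors::subjectHits(hits)]
    # per site: unique gene set within this class
    ngene <- vapply(split(g, q), function(x) length(unique(x)), 0L)
    amb_sites <- as.integer(names(ngene)[ngene > 1])
    ambiguous[cls] <- length(amb_sites)
    ok <- !(q %in% amb_sites)
    if (!any(ok)) next
    qa <- q[ok]; ga <- g[ok]
    dd <- !duplicated(paste(qa, ga))   # one count per site/gene pair
    qa <- qa[dd]; ga <- ga[dd]
    for (s in seq_along(samples)) {
      add <- tapply(supp[qa, s], ga, sum)
      counts[names(add), cls, s] <- counts[names(add), cls, s] + as.integer(add)
    }
    assigned[cls] <- length(unique(qa))
  }
  structure(list(
    counts = counts,
    library_sizes = colSums(supp),
    ambiguous = ambiguous,
    assigned = assigned
  ), class = "FeatureCounts")
}

#' @export
print.FeatureCounts <- function(x, ...) {
  d <- dim(x$counts)
  cat("FeatureCounts:", d[1], "genes x", d[2], "region classes x",
      d[3], "samples; library sizes:",
      paste(x$library_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a FeatureCounts tensor to a unit x sample count matrix
#'
#' Units are `gene_id|region_class`; rows with zero counts everywhere are
#' kept so that filters can see them.
#'
#' @param fc A `FeatureCounts` object.
#' @return Integer matrix with rownames `gene|class`.
#' @export
feature_counts_matrix <- function(fc) {
  stopifnot(inherits(fc, "FeatureCounts"))
  d <- dim(fc$counts)
  m <- matrix(aperm(fc$counts, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  rownames(m) <- as.vector(outer(dimnames(fc$counts)[[2]],
                                 dimnames(fc$counts)[[1]],
                                 function(cl, g) paste0(g, "|", cl)))
  colnames(m) <- dimnames(fc$counts)[[3]]
  m
}

#' Scan a sequence for poly(A)-signal hexamers
#'
#' Finds all (possibly overlapping) exact occurrences of the given motifs;
#' the canonical poly(A) signal is AAUAAA, searched here in DNA form
#' `AATAAA`.
#'
#' @param seq A single character string over `A,C,G,T,N`.
#' @param motifs Character vector of DNA motifs (default `"AATAAA"`).
#' @return Sorted integer vector of 0-based match start positions.
#' @export
scan_pas_hexamer <- function(seq, motifs = "AATAAA") {
  stopifnot(is.character(seq), length(seq) == 1L)
  subject <- Biostrings::DNAString(seq)
  hits <- unlist(lapply(motifs, function(m) {
    BiocGenerics::start(Biostrings::matchPattern(m, subject))
  }))
  sort(unique(as.integer(hits))) - 1L
}

#' Read 3'-end sites from a BED file
#'
#' Expects BED6 with one line per (site, sample): `chrom start end name
#' score strand` where `name` is the sample id and `score` the read
#' support at that position. Width must be 1 (`end == start + 1`).
#'
#' @param path BED path.
#' @return Width-1 `GRanges` with a `support` matrix column (sites x
#'   samples), positions aggregated across duplicate lines.
#' @export
read_pac_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no records in ", path)
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "sample",
                                        "support", "strand"))
  if (any(df$end - df$start != 1L)) stop("3'-end BED must have width-1 records")
  pac_sites(df$chrom, df$start + 1L, df$strand, df$sample, df$support)
}

#' Assemble a site-level GRanges from per-(site, sample) support records
#'
#' @param chrom,pos,strand Site coordinates (1-based position).
#' @param sample Sample id per record.
#' @param support Read support per record.
#' @return Width-1 `GRanges` with `support` matrix column.
#' @export
pac_sites <- function(chrom, pos, strand, sample, support) {
  key <- paste(chrom, pos, strand, sep = "\r")
  ukey <- unique(key)
  samples <- sort(unique(sample))
  agg <- tapply(support,
                list(factor(key, levels = ukey),
                     factor(sample, levels = samples)),
                sum)
  agg[is.na(agg)] <- 0
  supp <- matrix(as.integer(agg), nrow = length(ukey),
                 dimnames = list(NULL, samples))
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  gr <- GenomicRanges::GRanges(parts[, 1],
                               IRanges::IRanges(as.integer(parts[, 2]), width = 1L),
                               strand = parts[, 3])
  gr$support <- supp
  sort_i <- order(as.character(GenomeInfoDb::seqnames(gr)),
                  GenomicRanges::start(gr))
  gr[sort_i]
}

#' Write 3'-end sites as BED6 (inverse of [read_pac_bed()])
#'
#' @param sites Width-1 `GRanges` with `support` matrix column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pac_bed <- function(sites, path) {
  supp <- .support_matrix(sites)
  rows <- list()
  for (s in colnames(supp)) {
    nz <- which(supp[, s] > 0)
    if (length(nz) == 0) next
    rows[[s]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(sites))[nz],
      start = GenomicRanges::start(sites)[nz] - 1L,
      end = GenomicRanges::start(sites)[nz],
      sample = s,
      support = supp[nz, s],
      strand = as.character(BiocGenerics::strand(sites))[nz]
    )
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$sample), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned 3'-end reads from a BAM file into site-level support
#'
#' Requires the `GenomicAlignments` package. Alignments are collapsed to
#' their 3'-most aligned base (soft clips ignored) and aggregated into a
#' one-sample support column.
#'
#' @param path BAM path (indexed or small enough to scan).
#' @param sample Sample id used for the support column.
#' @return Width-1 `GRanges` with a one-column `support` matrix.
#' @export
read_pac_bam <- function(path, sample = "sample1") {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("read_pac_bam requires the GenomicAlignments package")
  }
  aln <- GenomicAlignments::readGAlignments(path)
  gr <- three_prime_pos(GenomicRanges::granges(aln))
  pac_sites(as.character(GenomeInfoDb::seqnames(gr)),
            GenomicRanges::start(gr),
            as.character(BiocGenerics::strand(gr)),
            rep(sample, length(gr)),
            rep(1L, length(gr)))
}
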