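#' Load a gene annotation from a GTF file
#'
#' Reads an Ensembl-dialect GTF and returns a `GenomeAnnotation` object:
#' a list of `GRanges` for genes, transcripts, exons, CDS and annotated
#' 3' UTRs, restricted to the requested gene biotypes and with transcripts
#' carrying any excluded tag (by default `retained_intron`) removed.
#' Features of dropped transcripts are dropped with them.
#'
#' @param gtf_path Path to a GTF file with `gene_id`/`transcript_id`
#'   attributes and feature types `gene`, `transcript`, `exon`, `CDS`,
#'   `three_prime_utr`.
#' @param biotypes Gene biotypes to keep (default `"protein_coding"`).
#' @param excluded_tags Transcript tags that cause a transcript to be
#'   dropped (default `"retained_intron"`).
#' @param fai Optional path to a FASTA index (`.fai`); when given,
#'   chromosome lengths are attached so downstream region construction can
#'   clip windows at chromosome ends.
#' @return A `GenomeAnnotation`: a list with elements `genes`,
#'   `transcripts`, `exons`, `cds`, `utr3` (all `GRanges`, 1-based
#'   GRanges coordinates internally; BED export converts to 0-based).
#' @export
load_annotation <- function(gtf_path,
                            biotypes = "protein_coding",
                            excluded_tags = "retained_intron",
                            fai = NULL) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  .validate_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (!all(c("type", "gene_id") %in% names(S4Vectors::mcols(gr)))) {
    stop("GTF lacks mandatory type/gene_id attributes: ", gtf_path)
  }
  if (!is.null(fai)) {
    sl <- read_fai(fai)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }

  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (!is.null(genes$gene_biotype)) {
    genes <- genes[genes$gene_biotype %in% biotypes]
  }
  keep_genes <- unique(genes$gene_id)

  tx <- gr[type == "transcript"]
  if (length(tx) > 0 && any(!tx$gene_id %in% gr$gene_id[type == "gene"])) {
    bad <- unique(tx$transcript_id[!tx$gene_id %in% gr$gene_id[type == "gene"]])
    stop("transcript(s) reference unknown gene: ", paste(bad, collapse = ", "))
  }
  tx <- tx[tx$gene_id %in% keep_genes]
  if (length(excluded_tags) > 0 && "tag" %in% names(S4Vectors::mcols(tx))) {
    tag <- tx$tag
    drop <- if (methods::is(tag, "CharacterList")) {
      vapply(tag, function(t) any(t %in% excluded_tags), logical(1))
    } else {
      !is.na(tag) & tag %in% excluded_tags
    }
    tx <- tx[!drop]
  }
  keep_tx <- unique(tx$transcript_id)

  pick <- function(what) {
    f <- gr[type == what]
    f <- f[!is.na(f$transcript_id) & f$transcript_id %in% keep_tx]
    S4Vectors::mcols(f) <- S4Vectors::mcols(f)[, c("gene_id", "transcript_id"), drop = FALSE]
    f
  }
  ann <- structure(list(
    genes = genes,
    transcripts = tx,
    exons = pick("exon"),
    cds = pick("CDS"),
    utr3 = pick("three_prime_utr")
  ), class = "GenomeAnnotation")
  .validate_annotation(ann)
  ann
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$genes), "genes,",
      length(x$transcripts), "transcripts,",
      length(x$exons), "exons,", length(x$cds), "CDS,",
      length(x$utr3), "3'UTR features\n")
  invisible(x)
}

#' Read a FASTA index (.fai) into a named vector of chromosome lengths
#'
#' @param path Path to a samtools-style `.fai` file (columns: name, length,
#'   offset, linebases, linewidth).
#' @return Named integer vector of sequence lengths.
#' @export
read_fai <- function(path) {
  if (!file.exists(path)) stop("FASTA index not found: ", path)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

#' Write a FASTA index for a DNAStringSet
#'
#' Convenience used by the simulator and tests: writes `<path>` as FASTA
#' and a matching `<path>.fai`.
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_with_index <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  n <- Biostrings::width(seqs)
  # offsets for fixed-width FASTA records written above
  hdr <- nchar(names(seqs)) + 2L      # ">name\n"
  body <- n + ceiling(n / 80)         # sequence plus newlines
  off <- cumsum(c(0, utils::head(hdr + body, -1))) + hdr
  fai <- data.frame(names(seqs), n, off, 80L, 81L)
  utils::write.table(fai, paste0(path, ".fai"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# cheap structural scan so that malformed lines fail with a line number
# rather than an opaque parser error
.validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  data <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[data], "\t", fixed = TRUE))
  bad <- data[nf < 9L]
  if (length(bad) > 0) {
    stop("malformed GTF line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields, got ", nf[which(data == bad[1])], ")")
  }
  invisible(TRUE)
}

.validate_annotation <- function(ann) {
  gene_strand <- stats::setNames(as.character(BiocGenerics::strand(ann$genes)),
                                 ann$genes$gene_id)
  gene_chrom <- stats::setNames(as.character(GenomeInfoDb::seqnames(ann$genes)),
                                ann$genes$gene_id)
  for (what in c("transcripts", "exons", "cds", "utr3")) {
    f <- ann[[what]]
    if (length(f) == 0) next
    ok <- as.character(BiocGenerics::strand(f)) == gene_strand[f$gene_id] &
      as.character(GenomeInfoDb::seqnames(f)) == gene_chrom[f$gene_id]
    if (any(!ok, na.rm = TRUE) || anyNA(ok)) {
      stop(what, " features disagree with their gene's chromosome/strand")
    }
  }
  # exons of one transcript must not overlap each other
  if (length(ann$exons) > 1) {
    byx <- S4Vectors::split(ann$exons, ann$exons$transcript_id)
    if (any(!vapply(byx, GenomicRanges::isDisjoint, logical(1)))) {
      stop("overlapping exons within a transcript")
    }
  }
  invisible(TRUE)
}
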