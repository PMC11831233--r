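#' Merge a set of intervals on one chromosome and strand
#'
#' Computes the minimal sorted disjoint cover of the union of the input
#' intervals. Touching intervals (e.g. `[1,10]` followed by `[11,20]` in
#' 1-based closed coordinates) are merged into one.
#'
#' @param gr A [GenomicRanges::GRanges] whose ranges all lie on the same
#'   chromosome and strand. Strand must be `+` or `-`.
#' @return A `GRanges` with sorted, disjoint ranges covering the same bases.
#' @export
merge_intervals <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  if (length(gr) == 0L) return(gr)
  .check_single_space(gr)
  sort(GenomicRanges::reduce(gr))
}

#' Subtract one merged interval set from another
#'
#' Set difference `a \ b` with the same semantics as `bedtools subtract`:
#' every base of `a` covered by `b` is removed and the remainder is returned
#' as disjoint intervals. Both inputs must already be merged (disjoint);
#' callers should apply [merge_intervals()] first.
#'
#' @param a,b `GRanges` on the same chromosome and strand; each must be
#'   disjoint. Zero-length `b` is a no-op.
#' @return A `GRanges` holding `a` minus `b`; may be empty.
#' @export
subtract_intervals <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  if (length(a) == 0L) return(a)
  .check_single_space(a)
  if (length(b) > 0L) {
    .check_single_space(b)
    if (as.character(GenomeInfoDb::seqnames(a)[1]) !=
        as.character(GenomeInfoDb::seqnames(b)[1]) ||
        as.character(BiocGenerics::strand(a)[1]) !=
        as.character(BiocGenerics::strand(b)[1])) {
      stop("'a' and 'b' must be on the same chromosome and strand")
    }
  }
  if (GenomicRanges::isDisjoint(a) == FALSE || length(GenomicRanges::reduce(a)) != length(a)) {
    stop("'a' must be merged (disjoint, non-touching) before subtraction")
  }
  if (length(b) > 0L &&
      (GenomicRanges::isDisjoint(b) == FALSE || length(GenomicRanges::reduce(b)) != length(b))) {
    stop("'b' must be merged (disjoint, non-touching) before subtraction")
  }
  if (length(b) == 0L) return(sort(a))
  sort(GenomicRanges::setdiff(a, b))
}

# error unless all ranges share one seqname and one of strand +/-
.check_single_space <- function(gr) {
  sn <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  st <- unique(as.character(BiocGenerics::strand(gr)))
  if (length(sn) != 1L) stop("intervals span multiple chromosomes: ", paste(sn, collapse = ", "))
  if (length(st) != 1L || !st %in% c("+", "-")) {
    stop("intervals must share a single strand ('+' or '-')")
  }
  invisible(TRUE)
}
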