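test_that("GTF loading filters biotypes and excluded transcript tags", {
  lines <- c(
    toy_gene_lines("GA", "chr1", "+", c(1001, 3000),
                   exons = list(c(1001, 1500), c(2001, 3000)),
                   cds = list(c(1101, 1500), c(2001, 2400)),
                   utr3 = list(c(2401, 3000))),
    # second transcript of GA tagged retained_intron -> dropped
    gtf_line("chr1", "transcript", 1001, 3000, "+", "GA", "GA.t2",
             tag = "retained_intron"),
    gtf_line("chr1", "exon", 1001, 3000, "+", "GA", "GA.t2",
             tag = "retained_intron"),
    toy_gene_lines("GB", "chr1", "-", c(5001, 6000),
                   exons = list(c(5001, 6000)), cds = list(c(5301, 5800)),
                   utr3 = list(c(5001, 5300)), biotype = "lincRNA")
  )
  ann <- load_annotation(write_toy_gtf(lines))
  expect_equal(ann$genes$gene_id, "GA")
  expect_equal(ann$transcripts$transcript_id, "GA.t1")
  expect_equal(length(ann$exons), 2L)   # retained_intron exon dropped
  # lincRNA kept when requested
  ann2 <- load_annotation(write_toy_gtf(lines),
                          biotypes = c("protein_coding", "lincRNA"))
  expect_setequal(ann2$genes$gene_id, c("GA", "GB"))
})

test_that("GTF coordinates convert to 0-based half-open on BED export", {
  # exon at 1..100 (1-based inclusive) must export as [0, 100)
  lines <- toy_gene_lines("G1", "chr1", "+", c(1, 100),
                          exons = list(c(1, 100)), cds = list(c(1, 60)),
                          utr3 = list(c(61, 100)))
  ann <- load_annotation(write_toy_gtf(lines))
  rs <- build_cds_regions(ann)
  path <- tempfile(fileext = ".bed")
  write_regions_bed(rs, path)
  fields <- strsplit(grep("^#", readLines(path), value = TRUE, invert = TRUE),
                     "\t")[[1]]
  expect_equal(as.integer(fields[2]), 0L)
  expect_equal(as.integer(fields[3]), 60L)
})

test_that("malformed GTF lines fail with the line number", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "gene", 1, 10, "+", "G1"),
               "chr1\tonly\tthree"), path)
  expect_error(load_annotation(path), "line 2")
})

test_that("merge_intervals produces the minimal disjoint cover", {
  gr <- function(...) {
    m <- do.call(rbind, list(...))
    GenomicRanges::GRanges("chr1", IRanges::IRanges(m[, 1], m[, 2]), strand = "+")
  }
  # 0-based [0,10),[5,20) -> [0,20): 1-based [1,10],[6,20] -> [1,20]
  expect_equal(as.data.frame(merge_intervals(gr(c(1, 10), c(6, 20))))[, 2:3],
               data.frame(start = 1L, end = 20L))
  # touching intervals merge
  expect_equal(length(merge_intervals(gr(c(1, 10), c(11, 20)))), 1L)
  # empty in, empty out; idempotence
  empty <- GenomicRanges::GRanges()
  expect_equal(length(merge_intervals(empty)), 0L)
  m <- merge_intervals(gr(c(1, 10), c(30, 40), c(8, 12)))
  expect_identical(merge_intervals(m), m)
  # mixed strand is an error
  mixed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5), c(3, 9)),
                                  strand = c("+", "-"))
  expect_error(merge_intervals(mixed), "strand")
})

test_that("subtract_intervals has bedtools-subtract semantics", {
  g <- function(s, e, st = "+") {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), strand = st)
  }
  # [0,100) minus [40,60) -> [0,40),[60,100)
  r <- subtract_intervals(g(1, 100), g(41, 60))
  expect_equal(GenomicRanges::start(r), c(1L, 61L))
  expect_equal(GenomicRanges::end(r), c(40L, 100L))
  # non-overlapping subtrahend is a no-op; self-subtraction empties
  expect_equal(length(subtract_intervals(g(1, 100), g(201, 300))), 1L)
  expect_equal(length(subtract_intervals(g(1, 100), g(1, 100))), 0L)
  # subtract(a, empty) = a
  expect_equal(length(subtract_intervals(g(1, 100), GenomicRanges::GRanges())), 1L)
  # unmerged input rejected
  expect_error(subtract_intervals(c(g(1, 10), g(5, 20)), g(1, 2)), "merged")
})

test_that("3' UTR extension is strand-aware and clipped at chromosome ends", {
  # + strand UTR [900,1000) 0-based = [901,1000] extends to [901,1300]
  lines <- c(
    toy_gene_lines("GP", "chr1", "+", c(101, 1000),
                   exons = list(c(101, 1000)), cds = list(c(101, 900)),
                   utr3 = list(c(901, 1000))),
    toy_gene_lines("GM", "chr2", "-", c(101, 1000),
                   exons = list(c(101, 1000)), cds = list(c(301, 900)),
                   utr3 = list(c(101, 200)))
  )
  path <- write_toy_gtf(lines)
  fai <- tempfile(fileext = ".fai")
  write.table(data.frame(c("chr1", "chr2"), c(20000L, 20000L), c(10L, 10L),
                         80L, 81L),
              fai, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  ann <- load_annotation(path, fai = fai)
  u <- build_utr3_regions(ann)
  up <- u[u$gene_id == "GP"]
  expect_equal(c(GenomicRanges::start(up), GenomicRanges::end(up)),
               c(901L, 1300L))
  # - strand extension goes to lower coordinates, clipped at base 1
  um <- u[u$gene_id == "GM"]
  expect_equal(c(GenomicRanges::start(um), GenomicRanges::end(um)),
               c(1L, 200L))
})

test_that("intron construction matches the per-base recipe", {
  # gene [1,1000], CDS [101,400] u [501,700], extended utr3 [701,1300]
  # -> intron [1,100] u [401,500]
  lines <- toy_gene_lines("G1", "chr1", "+", c(1, 1000),
                          exons = list(c(1, 400), c(501, 1000)),
                          cds = list(c(101, 400), c(501, 700)),
                          utr3 = list(c(701, 1000)))
  ann <- load_annotation(write_toy_gtf(lines))
  u <- build_utr3_regions(ann)
  ri <- build_intron_regions(ann, u)
  expect_equal(GenomicRanges::start(ri), c(1L, 401L))
  expect_equal(GenomicRanges::end(ri), c(100L, 500L))
  # gene fully covered by CDS + utr3 -> absent from intron set
  lines2 <- toy_gene_lines("G2", "chr1", "+", c(1, 1000),
                           exons = list(c(1, 1000)), cds = list(c(1, 700)),
                           utr3 = list(c(701, 1000)))
  ann2 <- load_annotation(write_toy_gtf(lines2))
  ri2 <- build_intron_regions(ann2, build_utr3_regions(ann2))
  expect_equal(length(ri2), 0L)
  # gene with no CDS: span minus extended utr3
  lines3 <- c(gtf_line("chr1", "gene", 1, 1000, "+", "G3"),
              gtf_line("chr1", "transcript", 1, 1000, "+", "G3", "G3.t1"),
              gtf_line("chr1", "exon", 1, 1000, "+", "G3", "G3.t1"),
              gtf_line("chr1", "three_prime_utr", 801, 1000, "+", "G3", "G3.t1"))
  ann3 <- load_annotation(write_toy_gtf(lines3))
  ri3 <- build_intron_regions(ann3, build_utr3_regions(ann3))
  expect_equal(c(GenomicRanges::start(ri3), GenomicRanges::end(ri3)),
               c(1L, 800L))
})

test_that("downstream windows subtract same-strand features only", {
  mk <- function(neighbor_strand = NULL) {
    lines <- toy_gene_lines("G1", "chr1", "+", c(1, 2000),
                            exons = list(c(1, 2000)), cds = list(c(101, 1700)),
                            utr3 = list(c(1701, 2000)))
    if (!is.null(neighbor_strand)) {
      lines <- c(lines,
                 toy_gene_lines("G2", "chr1", neighbor_strand, c(2501, 2600),
                                exons = list(c(2501, 2600)),
                                cds = list(c(2501, 2580)),
                                utr3 = list(c(2581, 2600))))
    }
    ann <- load_annotation(write_toy_gtf(lines))
    u <- build_utr3_regions(ann)
    build_downstream_regions(ann, u, window_nt = 10000L)
  }
  # isolated gene ending at 2000 with extended utr3 to 2300 -> [2301, 12000]
  d0 <- mk()
  expect_equal(c(GenomicRanges::start(d0), GenomicRanges::end(d0)),
               c(2301L, 12000L))
  # same-strand neighbor exon [2501,2600] (plus its extended utr3 to 2900)
  # carved out of G1's window
  dp1 <- subset_region(mk("+"), "G1")
  expect_true(all(GenomicRanges::end(dp1) < 2501 |
                    GenomicRanges::start(dp1) > 2900))
  expect_equal(sum(GenomicRanges::width(dp1)), 12000L - 2300L - 400L)
  # opposite-strand neighbor leaves the window unchanged
  dm1 <- subset_region(mk("-"), "G1")
  expect_equal(sum(GenomicRanges::width(dm1)), 12000L - 2300L)
})

test_that("region BED round-trips and empty sets write a header-only file", {
  lines <- toy_gene_lines("G1", "chr1", "-", c(1001, 3000),
                          exons = list(c(1001, 1500), c(2001, 3000)),
                          cds = list(c(1201, 1500), c(2001, 2400)),
                          utr3 = list(c(1001, 1200)))
  ann <- load_annotation(write_toy_gtf(lines))
  rs <- build_utr3_regions(ann)
  path <- tempfile(fileext = ".bed")
  write_regions_bed(rs, path)
  back <- read_regions_bed(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(rs))
  expect_equal(as.character(BiocGenerics::strand(back)),
               as.character(BiocGenerics::strand(rs)))
  expect_equal(back$gene_id, rs$gene_id)
  expect_equal(back$region_class, rs$region_class)
  # empty set writes a header-only file that reads back empty
  empty <- rs[0]
  p2 <- tempfile(fileext = ".bed")
  write_regions_bed(empty, p2)
  expect_true(grepl("^#", readLines(p2)[1]))
  expect_equal(length(readLines(p2)), 1L)
  expect_equal(length(read_regions_bed(p2)), 0L)
})

test_that("interval algebra matches the per-base oracle on simulated genes", {
  cfg <- sim_config(seed = 42, n_genes = 150)
  sim <- simulate_annotation(cfg, sequence = FALSE)
  path <- write_toy_gtf(sim$gtf_lines)
  ann <- load_annotation(path)
  regions <- build_all_regions(ann)
  oracle <- oracle_region_bases(ann, chrom_len = as.list(sim$chrom_lengths))
  expect_equal(compare_regions_to_oracle(regions, oracle), 0L)
  expect_equal(count_disjoint_violations(regions), 0L)
})
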