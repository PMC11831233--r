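test_that("poly(A)-tail detection enforces the 25-A boundary", {
  r <- trim_polya(paste0("GATTACA", strrep("A", 30)))
  # tail = "ACA" + 30 A (one tolerated mismatch): 32 A in the suffix
  expect_equal(r$a_count, 32L)
  expect_true(r$passes)
  expect_equal(r$insert, "GATT")
  # 24 A fails, 25 passes (boundary of the >= 25 A rule)
  expect_false(trim_polya(paste0("GCGGCGTC", strrep("A", 24)))$passes)
  expect_true(trim_polya(paste0("GCGGCGTC", strrep("A", 25)))$passes)
  # tail-only read: passes with an empty insert (caller discards)
  allA <- trim_polya(strrep("A", 25))
  expect_true(allA$passes)
  expect_equal(allA$insert, "")
  # tolerated mismatches inside the tail
  r2 <- trim_polya(paste0("GCGC", strrep("A", 20), "G", strrep("A", 10)),
                   max_mismatch = 2)
  expect_equal(r2$a_count, 30L)
  expect_true(r2$passes)
  expect_error(trim_polya(""), "empty")
  # every passing read has a_count >= min_a (property over random reads)
  set.seed(5)
  reads <- vapply(1:200, function(i) {
    paste0(paste(sample(c("C", "G", "T"), 30, TRUE), collapse = ""),
           strrep("A", sample(0:40, 1)))
  }, "")
  tp <- trim_polya(reads)
  expect_true(all(tp$a_count[tp$passes] >= 25))
})

test_that("the 3'-most aligned base depends on strand", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 101, 8),
                                                        c(150, 150, 8)),
                               strand = c("+", "-", "+"))
  pos <- GenomicRanges::start(three_prime_pos(gr))
  expect_equal(pos, c(150L, 101L, 8L))  # 0-based: 149, 100, 7
  un <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5), strand = "*")
  expect_error(three_prime_pos(un), "strand")
})

test_that("internal-priming filter counts sense-strand A in the window", {
  # + strand site at 50; downstream 20-mer has 13 A -> removed
  seq13 <- paste0(strrep("C", 50), paste(rep(c("A", "A", "A", "A", "A", "A",
                                               "A", "A", "A", "A", "A", "A",
                                               "A", "C", "C", "C", "C", "C",
                                               "C", "C"), 1), collapse = ""),
                  strrep("G", 30))
  genome <- Biostrings::DNAStringSet(c(chrT = seq13))
  site <- GenomicRanges::GRanges("chrT", IRanges::IRanges(50, 50), strand = "+")
  expect_false(internal_priming_filter(site, genome))
  # exactly 12 A -> kept (strict > 12 rule)
  seq12 <- paste0(strrep("C", 50), strrep("A", 12), strrep("C", 8),
                  strrep("G", 30))
  expect_true(internal_priming_filter(
    site, Biostrings::DNAStringSet(c(chrT = seq12))))
  # - strand site: sense-strand A = plus-strand T upstream; 15 T -> removed
  seqm <- paste0(strrep("C", 30), strrep("T", 15), strrep("C", 5),
                 strrep("G", 30))
  sitem <- GenomicRanges::GRanges("chrT", IRanges::IRanges(51, 51), strand = "-")
  genm <- Biostrings::DNAStringSet(c(chrT = seqm))
  expect_false(internal_priming_filter(sitem, genm))
  # reverse-complement oracle: count A in the revcomp of the window
  win <- substr(seqm, 31, 50)
  rc <- reverse_complement(win)
  expect_true(sum(strsplit(rc, "")[[1]] == "A") > 12)
})

test_that("site clustering is single-linkage with support conservation", {
  mk <- function(pos, supp, strand = "+") {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                                 strand = strand)
    gr$support <- matrix(supp, ncol = 1, dimnames = list(NULL, "s1"))
    gr
  }
  # gap 5 -> one cluster, summed support
  c1 <- cluster_sites(mk(c(100, 105), c(3, 4)))
  expect_equal(length(c1), 1L)
  expect_equal(as.integer(c1$support), 7L)
  # gap 30 -> two clusters
  expect_equal(length(cluster_sites(mk(c(100, 130), c(1, 1)))), 2L)
  # chained linkage: 100-120-140 all joined through 120
  expect_equal(length(cluster_sites(mk(c(100, 120, 140), c(1, 1, 1)))), 1L)
  # representative: highest support, ties to the 3'-most position
  r <- cluster_sites(mk(c(100, 110), c(5, 5)))
  expect_equal(GenomicRanges::start(r), 110L)
  rm_ <- cluster_sites(mk(c(100, 110), c(5, 5), strand = "-"))
  expect_equal(GenomicRanges::start(rm_), 100L)
})

test_that("feature counting is stranded and drops cross-gene ambiguity", {
  regions <- list(
    utr3 = {
      g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 500),
                                                           c(200, 600)),
                                  strand = "+")
      g$gene_id <- c("G1", "G2"); g$region_class <- "utr3"; g
    },
    downstream10k = {
      g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(201, 551),
                                                           c(560, 900)),
                                  strand = "+")
      g$gene_id <- c("G1", "G2"); g$region_class <- "downstream10k"; g
    }
  )
  mk <- function(pos, strand) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                                 strand = strand)
    gr$support <- matrix(rep(2L, length(pos)), ncol = 1,
                         dimnames = list(NULL, "s1"))
    gr
  }
  fc <- count_by_feature(mk(150, "+"), regions)
  expect_equal(fc$counts["G1", "utr3", "s1"], 2L)
  # antisense site not counted
  fc2 <- count_by_feature(mk(150, "-"), regions)
  expect_equal(sum(fc2$counts), 0L)
  expect_equal(unname(fc2$library_sizes), 2)
  # site in the overlap of two genes' downstream regions: ambiguous
  fc3 <- count_by_feature(mk(555, "+"), regions)
  expect_equal(sum(fc3$counts[, "downstream10k", ]), 0L)
  expect_equal(unname(fc3$ambiguous["downstream10k"]), 1L)
})

test_that("hexamer scan finds overlapping AATAAA matches", {
  # the reverse complement of the 25-mer poly(A)-mask morpholino contains
  # exactly one AATAAA (the signal the oligo covers)
  pam <- gpi_pam_morpholinos()[["canonical_pas_25mer"]]
  hits <- scan_pas_hexamer(reverse_complement(pam))
  expect_equal(length(hits), 1L)
  # enumeration oracle over all 6-mer windows
  rc <- reverse_complement(pam)
  wins <- vapply(1:(nchar(rc) - 5), function(i) substr(rc, i, i + 5), "")
  expect_equal(which(wins == "AATAAA") - 1L, hits)
  expect_equal(length(scan_pas_hexamer("AAAAAA")), 0L)
  expect_equal(scan_pas_hexamer("AATAAATAAA"), c(0L, 4L))
})

test_that("site BED I/O round-trips support matrices", {
  sites <- pac_sites(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(100L, 250L, 7L),
                     strand = c("+", "-", "+"),
                     sample = c("a", "a", "b"),
                     support = c(3L, 2L, 9L))
  expect_equal(dim(sites$support), c(3L, 2L))
  path <- tempfile(fileext = ".bed")
  write_pac_bed(sites, path)
  back <- read_pac_bed(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(sites))
  expect_equal(back$support, sites$support)
})

test_that("BAM ingestion matches direct site construction", {
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:1000",
           paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0,
                 strrep("C", 50), "*", sep = "\t"),
           paste("r2", 16, "chr1", 201, 60, "40M", "*", 0, 0,
                 strrep("C", 40), "*", sep = "\t"))
  sam_path <- tempfile(fileext = ".sam")
  writeLines(sam, sam_path)
  bam_path <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE)
  sites <- read_pac_bam(bam_path, sample = "s1")
  # r1: + strand 50M from 101 -> 3' end 150; r2: - strand -> 3' end 201
  expect_equal(GenomicRanges::start(sites), c(150L, 201L))
  expect_equal(as.character(BiocGenerics::strand(sites)), c("+", "-"))
  expect_equal(as.integer(sites$support), c(1L, 1L))
})

test_that("assignment agrees with a naive per-site oracle on simulated data", {
  cfg <- sim_config(seed = 9, n_genes = 30)
  sim <- simulate_annotation(cfg)
  ann <- load_annotation(write_toy_gtf(sim$gtf_lines))
  regions <- build_all_regions(ann)
  pac <- simulate_pac_experiment(cfg, sim, 1)
  keep <- internal_priming_filter(pac$sites, sim$genome)
  sites <- pac$sites[keep]
  fc <- count_by_feature(sites, regions)
  expect_equal(fc$counts, oracle_count_by_feature(sites, regions))
  # strand flip on a single-strand-per-gene layout zeroes everything
  flipped <- sites
  BiocGenerics::strand(flipped) <- ifelse(
    as.character(BiocGenerics::strand(sites)) == "+", "-", "+")
  expect_equal(sum(count_by_feature(flipped, regions)$counts), 0L)
  # conservation through clustering
  cl <- cluster_sites(sites)
  expect_equal(colSums(do.call(rbind, list(cl$support))),
               colSums(sites$support))
})
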