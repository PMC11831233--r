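test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 77, n_genes = 15)
  s1 <- simulate_annotation(cfg)
  s2 <- simulate_annotation(cfg)
  expect_identical(s1$gtf_lines, s2$gtf_lines)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  p1 <- simulate_pac_experiment(cfg, s1, 1)
  p2 <- simulate_pac_experiment(cfg, s1, 1)
  expect_identical(p1$sites$support, p2$sites$support)
  r1 <- simulate_rnaseq(cfg, s1, 2)
  r2 <- simulate_rnaseq(cfg, s1, 2)
  expect_identical(r1$counts, r2$counts)
  # different substreams give different draws
  p3 <- simulate_pac_experiment(cfg, s1, 2)
  expect_false(identical(p1$sites$support, p3$sites$support))
})

test_that("truth manifest usage fractions sum to 1 and scores ignore lfc", {
  cfg <- sim_config(seed = 13, n_genes = 30)
  sim <- simulate_annotation(cfg, sequence = FALSE)
  tr <- sim$truth
  for (cond in c("control", "treated")) {
    tot <- tr[[paste0("pi_utr3_", cond)]] + tr[[paste0("pi_intron_", cond)]] +
      tr[[paste0("pi_downstream10k_", cond)]]
    expect_equal(tot, rep(1, nrow(tr)))
  }
  # expected PAC-score is a function of the usage fractions only:
  # recomputing it after perturbing the expression column changes nothing
  score_from_pi <- function(t) {
    log2(t$pi_downstream10k_treated / t$pi_downstream10k_control) -
      log2(t$pi_utr3_treated / t$pi_utr3_control)
  }
  tr2 <- tr
  tr2$lfc_expr <- tr2$lfc_expr + rnorm(nrow(tr2))
  expect_equal(score_from_pi(tr2), tr$expected_pac_score_downstream10k)
  # intended quadrant consistent with planted signs
  qi <- tr$class == "qi"
  expect_true(all(tr$intended_quadrant[qi] == "QI"))
})

test_that("planted genomic context drives the internal-priming filter", {
  cfg <- sim_config(seed = 19, n_genes = 25)
  sim <- simulate_annotation(cfg)
  tr <- sim$truth
  count_downstream_a <- function(pos, strand) {
    s <- sim$genome[[1]]
    if (strand == "+") {
      w <- as.character(Biostrings::subseq(s, pos + 1, pos + 20))
      sum(strsplit(w, "")[[1]] == "A")
    } else {
      w <- as.character(Biostrings::subseq(s, pos - 20, pos - 1))
      sum(strsplit(w, "")[[1]] == "T")
    }
  }
  # every true site scans <= 12 A, every decoy > 12 A (by construction)
  for (i in seq_len(nrow(tr))) {
    for (p in c(tr$utr3_site[i], tr$intron_site[i], tr$ds_site[i])) {
      expect_lte(count_downstream_a(p, tr$strand[i]), 12)
    }
    expect_gt(count_downstream_a(tr$decoy_pos[i], tr$strand[i]), 12)
  }
  # hexamer planted upstream of each true site (sense strand)
  s <- sim$genome[[1]]
  for (i in seq_len(min(5, nrow(tr)))) {
    p <- tr$utr3_site[i]
    ctx <- if (tr$strand[i] == "+") {
      as.character(Biostrings::subseq(s, p - 30, p))
    } else {
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(s, p, p + 30)))
    }
    expect_length(scan_pas_hexamer(ctx), 1)
  }
})

test_that("site frequencies track the configured usage fractions", {
  cfg <- sim_config(seed = 23, n_genes = 12, depth = 50000, decoy_rate = 0,
                    jitter_sd = 0.01, jitter_max = 1L)
  sim <- simulate_annotation(cfg, sequence = FALSE)
  pac <- simulate_pac_experiment(cfg, sim, 1)
  ctrl <- pac$design$sample[pac$design$condition == "control"]
  supp <- rowSums(pac$sites$support[, ctrl, drop = FALSE])
  pos <- GenomicRanges::start(pac$sites)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    at <- function(p) sum(supp[abs(pos - p) <= 1])
    tot <- at(tr$utr3_site) + at(tr$intron_site) + at(tr$ds_site)
    emp <- c(at(tr$utr3_site), at(tr$intron_site), at(tr$ds_site)) / tot
    expect_lt(max(abs(emp - c(tr$pi_utr3_control, tr$pi_intron_control,
                              tr$pi_downstream10k_control))), 0.02)
  }
})

test_that("emitted raw reads all pass the poly(A)-tail filter", {
  cfg <- sim_config(seed = 29, n_genes = 5, depth = 30)
  sim <- simulate_annotation(cfg)
  pac <- simulate_pac_experiment(cfg, sim, 1)
  fq <- tempfile(fileext = ".fastq")
  simulate_pac_fastq(cfg, sim, pac$sites, pac$design$sample[1], fq)
  lines <- readLines(fq)
  seqs <- lines[seq(2, length(lines), by = 4)]
  expect_gt(length(seqs), 10)
  tp <- trim_polya(seqs)
  expect_true(all(tp$passes))
  expect_true(all(nchar(tp$insert) > 0))
})

test_that("RNA-seq counts carry the planted expression fold changes", {
  cfg <- sim_config(seed = 31, n_genes = 60, rnaseq_depth = 2000)
  sim <- simulate_annotation(cfg, sequence = FALSE)
  rna <- simulate_rnaseq(cfg, sim, 1)
  kd <- rna$design$condition == "knockdown"
  est <- log2(rowMeans(rna$counts[, kd]) / rowMeans(rna$counts[, !kd]))
  qi <- sim$truth$class == "qi"
  expect_equal(mean(est[qi]), cfg$qi_lfc, tolerance = 0.1)
  nul <- sim$truth$class == "null"
  expect_lt(abs(mean(est[nul] - sim$truth$lfc_expr[nul])), 0.1)
})

test_that("written annotation artifacts are consistent and loadable", {
  cfg <- sim_config(seed = 37, n_genes = 8)
  sim <- simulate_annotation(cfg)
  d <- tempfile()
  paths <- write_sim_annotation(sim, d)
  expect_true(all(file.exists(unlist(paths))))
  # FASTA index agrees with the sequence lengths
  fai <- read_fai(paste0(paths$fasta, ".fai"))
  expect_equal(unname(fai), unname(Biostrings::width(sim$genome)))
  # index offsets resolve: sequence read back identical
  back <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(as.character(back[[1]]), as.character(sim$genome[[1]]))
  ann <- load_annotation(paths$gtf, fai = paste0(paths$fasta, ".fai"))
  expect_equal(length(ann$genes), 8L)
  truth_back <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth_back$gene_id, sim$truth$gene_id)
})
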