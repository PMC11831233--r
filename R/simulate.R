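#' Simulation configuration
#'
#' Assembles the configuration driving the synthetic-data generator. The
#' generated study mirrors a 3'-end sequencing knockdown experiment: per
#' cell line, 3 replicates each of a control shRNA and two knockdown
#' shRNAs, with paired gene-level RNA-seq counts whose expression changes
#' are coupled to the planted poly(A)-usage shifts. Genes fall into three
#' classes: `qi` genes (usage shift toward the downstream window plus an
#' expression decrease, the signature of activated intergenic cleavage
#' with transcript destabilization), `q3` genes (the reciprocal pattern),
#' and `null` genes (no usage shift, expression log2FC drawn from a
#' narrow null distribution).
#'
#' @param seed Master seed; every stochastic output is reproducible from
#'   `(config, seed)` via labeled RNG substreams.
#' @param n_genes Number of genes.
#' @param n_cell_lines Number of independent cell-line experiments
#'   (contrasts).
#' @param frac_qi,frac_q3 Fractions of genes in the `qi` / `q3` classes.
#' @param replicates Replicates per shRNA condition.
#' @param depth Mean PAC-seq reads per gene per sample.
#' @param dispersion Negative-binomial dispersion of per-gene read totals.
#' @param qi_lfc,q3_lfc Expression log2FC planted for `qi` / `q3` genes.
#' @param null_lfc_sd SD of the null genes' expression log2FC.
#' @param pi_null,pi_qi_treated,pi_q3_control,pi_q3_treated Usage
#'   fractions over the (utr3, intron, downstream) sites; `pi_null` is
#'   also the control-condition layout of `qi` genes.
#' @param jitter_sd,jitter_max Cleavage-position jitter: discretized
#'   normal SD (nt) truncated at `+/- jitter_max`.
#' @param decoy_rate Expected internal-priming decoy reads per gene, as a
#'   fraction of the gene's expected depth.
#' @param tail_min,tail_extra_mean Poly(A)-tail length law for emitted raw
#'   reads: `tail_min + Poisson(tail_extra_mean)`.
#' @param extension_nt,window_nt Region-construction parameters the
#'   simulated layout respects.
#' @param rnaseq_depth,rnaseq_dispersion Gene-level RNA-seq mean counts
#'   and dispersion.
#' @param decay_times,decay_n_genes,decay_ct_sd,decay_ref_ct,decay_slope
#'   Actinomycin-D time-course settings: sampling times (h), number of
#'   genes, Gaussian Ct noise SD, reference Ct at 100%, standard-curve
#'   slope.
#' @param cohort_n,cohort_rho,cohort_background Cohort simulation: number
#'   of samples, driver-gene correlation of set genes, number of
#'   independent background genes.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 80L,
                       n_cell_lines = 3L,
                       frac_qi = 0.25,
                       frac_q3 = 0.10,
                       replicates = 3L,
                       depth = 2000,
                       dispersion = 0.1,
                       qi_lfc = -1,
                       q3_lfc = 0.5,
                       null_lfc_sd = 0.15,
                       pi_null = c(utr3 = 0.70, intron = 0.15, downstream10k = 0.15),
                       pi_qi_treated = c(utr3 = 0.35, intron = 0.15, downstream10k = 0.50),
                       pi_q3_control = c(utr3 = 0.60, intron = 0.15, downstream10k = 0.25),
                       pi_q3_treated = c(utr3 = 0.80, intron = 0.15, downstream10k = 0.05),
                       jitter_sd = 3,
                       jitter_max = 10L,
                       decoy_rate = 0.05,
                       tail_min = 25L,
                       tail_extra_mean = 10,
                       extension_nt = 300L,
                       window_nt = 10000L,
                       rnaseq_depth = 500,
                       rnaseq_dispersion = 0.05,
                       decay_times = c(6, 12, 18, 24),
                       decay_n_genes = 20L,
                       decay_ct_sd = 0.1,
                       decay_ref_ct = 20,
                       decay_slope = -1 / log10(2),
                       cohort_n = 500L,
                       cohort_rho = 0.6,
                       cohort_background = 200L) {
  cfg <- as.list(environment())
  for (p in list(cfg$pi_null, cfg$pi_qi_treated, cfg$pi_q3_control,
                 cfg$pi_q3_treated)) {
    stopifnot(abs(sum(p) - 1) < 1e-9, all(p >= 0))
  }
  stopifnot(cfg$tail_min >= 25L, cfg$seed == as.integer(cfg$seed))
  structure(cfg, class = "SimulationConfig")
}

# deterministic substream seed below 2^31 from a master seed and a label
substream_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  as.integer((as.numeric(master) * 1000003 + h * 7919) %% 2147483629)
}

# evaluate expr under a labeled substream, restoring the caller's RNG state
with_substream <- function(master, label, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(substream_seed(master, label))
  expr
}

# per-gene geometry in transcription-direction offsets (0-based within gene)
.gene_geometry <- function() {
  list(utr5 = 100L, cds1 = 300L, intron = 1000L, cds2 = 400L, utr3 = 500L,
       ds_site_offset = 4000L, decoy_offset = 2000L, gene_len = 2300L)
}

#' Simulate a genome annotation with planted poly(A) sites
#'
#' Lays out `n_genes` single-transcript protein-coding genes on one
#' chromosome, spaced so that no gene's 10-kb downstream window reaches a
#' neighbor. Each gene carries three true poly(A) sites (in the annotated
#' 3' UTR, mid-intron, and 4 kb downstream of the gene end) plus one
#' recorded internal-priming decoy position 2 kb downstream. In the
#' emitted genome sequence an `AATAAA` hexamer is planted ~25 nt upstream
#' of every true site, the 20 nt downstream of every true site contain no
#' sense-strand A (so genuine sites always survive the internal-priming
#' filter), and the 20 nt downstream of every decoy are all sense-strand
#' A (so decoys are always removed by it, never by tail length).
#'
#' @param cfg A `SimulationConfig` from [sim_config()].
#' @param sequence Generate the genome sequence (default `TRUE`; set
#'   `FALSE` when only coordinates are needed).
#' @return A `PacSim` list: `truth` (per-gene manifest data.frame),
#'   `gtf_lines`, `chrom_lengths`, `genome` (a `DNAStringSet` or `NULL`),
#'   `config`.
#' @export
simulate_annotation <- function(cfg, sequence = TRUE) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  g <- .gene_geometry()
  n <- cfg$n_genes
  slot <- g$gene_len + cfg$window_nt + 2L * 1000L + g$ds_site_offset
  chrom <- "chr1"
  chrom_len <- n * slot + 1000L
  truth <- with_substream(cfg$seed, "annotation", {
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_qi <- round(cfg$frac_qi * n)
    n_q3 <- round(cfg$frac_q3 * n)
    class <- sample(c(rep("qi", n_qi), rep("q3", n_q3),
                      rep("null", n - n_qi - n_q3)))
    lfc <- ifelse(class == "qi", cfg$qi_lfc,
                  ifelse(class == "q3", cfg$q3_lfc,
                         stats::rnorm(n, 0, cfg$null_lfc_sd)))
    slot_start <- (seq_len(n) - 1L) * slot + 1L
    gene_start <- ifelse(strand == "+", slot_start + 1000L,
                         slot_start + slot - 1000L - g$gene_len)
    gene_end <- gene_start + g$gene_len - 1L
    data.frame(gene_id = sprintf("G%04d", seq_len(n)),
               chrom = chrom, strand = strand,
               gene_start = as.integer(gene_start),
               gene_end = as.integer(gene_end),
               class = class, lfc_expr = lfc,
               stringsAsFactors = FALSE)
  })
  # site positions (genomic, 1-based) in transcription direction
  plus <- truth$strand == "+"
  tx_pos <- function(offset) {
    ifelse(plus, truth$gene_start + offset, truth$gene_end - offset)
  }
  truth$utr3_site <- as.integer(tx_pos(g$gene_len - 100L - 1L))
  truth$intron_site <- as.integer(tx_pos(g$utr5 + g$cds1 + 500L - 1L))
  truth$ds_site <- as.integer(tx_pos(g$gene_len - 1L + g$ds_site_offset))
  truth$decoy_pos <- as.integer(tx_pos(g$gene_len - 1L + g$decoy_offset))

  # usage fractions per condition
  pick_pi <- function(cls, cond) {
    if (cls == "qi") {
      if (cond == "control") cfg$pi_null else cfg$pi_qi_treated
    } else if (cls == "q3") {
      if (cond == "control") cfg$pi_q3_control else cfg$pi_q3_treated
    } else cfg$pi_null
  }
  for (cond in c("control", "treated")) {
    for (site in c("utr3", "intron", "downstream10k")) {
      truth[[paste0("pi_", site, "_", cond)]] <- vapply(truth$class, function(cl) {
        pick_pi(cl, cond)[[site]]
      }, 0)
    }
  }
  truth$expected_pac_score_downstream10k <-
    log2(truth$pi_downstream10k_treated / truth$pi_downstream10k_control) -
    log2(truth$pi_utr3_treated / truth$pi_utr3_control)
  truth$expected_pac_score_intron <-
    log2(truth$pi_intron_treated / truth$pi_intron_control) -
    log2(truth$pi_utr3_treated / truth$pi_utr3_control)
  truth$intended_quadrant <- classify_quadrants(
    truth$expected_pac_score_downstream10k, truth$lfc_expr)
  truth$intended_quadrant[truth$class == "null"] <- "unclassified"

  sim <- structure(list(
    truth = truth,
    gtf_lines = .sim_gtf_lines(truth, g),
    chrom_lengths = stats::setNames(chrom_len, chrom),
    genome = NULL,
    config = cfg
  ), class = "PacSim")
  if (sequence) sim$genome <- .sim_genome(sim)
  sim
}

#' @export
print.PacSim <- function(x, ...) {
  cat("PacSim:", nrow(x$truth), "genes on",
      length(x$chrom_lengths), "chromosome(s);",
      sum(x$truth$class == "qi"), "QI /",
      sum(x$truth$class == "q3"), "Q3 /",
      sum(x$truth$class == "null"), "null\n")
  invisible(x)
}

.sim_gtf_lines <- function(truth, g) {
  attr_str <- function(gid, tid = NULL) {
    s <- sprintf('gene_id "%s"; gene_biotype "protein_coding";', gid)
    if (!is.null(tid)) s <- sprintf('%s transcript_id "%s";', s, tid)
    s
  }
  lines <- character(0)
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    plus <- r$strand == "+"
    # transcription-direction offsets -> genomic [start, end]
    feat <- function(from, to) {   # 0-based offsets within gene, inclusive
      if (plus) c(r$gene_start + from, r$gene_start + to)
      else c(r$gene_end - to, r$gene_end - from)
    }
    e1 <- feat(0L, g$utr5 + g$cds1 - 1L)
    c1 <- feat(g$utr5, g$utr5 + g$cds1 - 1L)
    e2 <- feat(g$utr5 + g$cds1 + g$intron, g$gene_len - 1L)
    c2 <- feat(g$utr5 + g$cds1 + g$intron,
               g$utr5 + g$cds1 + g$intron + g$cds2 - 1L)
    u3 <- feat(g$gene_len - g$utr3, g$gene_len - 1L)
    tid <- paste0(r$gene_id, ".t1")
    row <- function(type, se, attrs) {
      paste(r$chrom, "sim", type, min(se), max(se), ".", r$strand, ".",
            attrs, sep = "\t")
    }
    lines <- c(lines,
               row("gene", c(r$gene_start, r$gene_end), attr_str(r$gene_id)),
               row("transcript", c(r$gene_start, r$gene_end),
                   attr_str(r$gene_id, tid)),
               row("exon", e1, attr_str(r$gene_id, tid)),
               row("exon", e2, attr_str(r$gene_id, tid)),
               row("CDS", c1, attr_str(r$gene_id, tid)),
               row("CDS", c2, attr_str(r$gene_id, tid)),
               row("three_prime_utr", u3, attr_str(r$gene_id, tid)))
  }
  lines
}

# build the chromosome sequence with planted hexamers, A-free windows
# downstream of true sites, and A-rich tracts downstream of decoys
.sim_genome <- function(sim) {
  truth <- sim$truth
  cfg <- sim$config
  len <- sim$chrom_lengths[[1]]
  base <- with_substream(cfg$seed, "genome", {
    sample(c("A", "C", "G", "T"), len, replace = TRUE,
           prob = c(0.2, 0.3, 0.3, 0.2))
  })
  safe_plus <- strsplit("CGTCGGTCGCTGCGTCCGTC", "")[[1]]   # no A
  safe_minus <- strsplit("GACGGACCGAGCAGACGACG", "")[[1]]  # no T
  stamp <- function(at, chars) {
    ok <- at >= 1 & at <= len
    base[at[ok]] <<- chars[ok]
  }
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    plus <- r$strand == "+"
    for (site in c(r$utr3_site, r$intron_site, r$ds_site)) {
      if (plus) {
        stamp(site - 25L + 0:5, strsplit("AATAAA", "")[[1]])
        stamp(site + 1:20, safe_plus)
      } else {
        stamp(site + 20L + 0:5, strsplit("TTTATT", "")[[1]])
        stamp(site - 20:1, rev(safe_minus))
      }
    }
    if (plus) stamp(r$decoy_pos + 1:20, rep("A", 20))
    else stamp(r$decoy_pos - 20:1, rep("T", 20))
  }
  seqs <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seqs) <- names(sim$chrom_lengths)
  seqs
}

#' Write simulated annotation artifacts to a directory
#'
#' Emits `genes.gtf`, `genome.fa` (+ `.fai`) and `truth.json` (the
#' machine-readable truth manifest).
#'
#' @param sim A `PacSim` from [simulate_annotation()] (with sequence).
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_sim_annotation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir, "genes.gtf")
  writeLines(sim$gtf_lines, gtf)
  fa <- NULL
  if (!is.null(sim$genome)) {
    fa <- file.path(dir, "genome.fa")
    write_fasta_with_index(sim$genome, fa)
  }
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth, digits = NA)
  list(gtf = gtf, fasta = fa, truth = truth)
}

.sim_design <- function(cfg) {
  cond <- c("shCTRL", "shKD1", "shKD2")
  data.frame(
    sample = paste0(rep(cond, each = cfg$replicates), "_r",
                    rep(seq_len(cfg$replicates), times = length(cond))),
    shrna = rep(cond, each = cfg$replicates),
    condition = rep(c("control", "knockdown", "knockdown"),
                    each = cfg$replicates),
    stringsAsFactors = FALSE
  )
}

#' Simulate a PAC-seq experiment for one cell line
#'
#' Per sample, each gene's read total is negative-binomial around the
#' configured depth (scaled by the gene's expression fold change in the
#' knockdown samples); reads are assigned to the gene's three true sites
#' multinomially by the condition's usage fractions, with the cleavage
#' position jittered by a discretized truncated normal. Internal-priming
#' decoy reads are added at each gene's recorded decoy position at the
#' configured rate (their 3' ends are never jittered: priming occurs at
#' the genomic A-tract itself).
#'
#' @param cfg A `SimulationConfig`.
#' @param sim A `PacSim` from [simulate_annotation()].
#' @param cell_line Integer label selecting the RNG substream, so that
#'   each cell line is an independent experiment.
#' @return List: `sites` (width-1 `GRanges`, `support` matrix sites x
#'   samples), `design` (sample/shrna/condition data.frame).
#' @export
simulate_pac_experiment <- function(cfg, sim, cell_line = 1L) {
  stopifnot(inherits(sim, "PacSim"))
  truth <- sim$truth
  design <- .sim_design(cfg)
  offs <- -cfg$jitter_max:cfg$jitter_max
  jprob <- stats::dnorm(offs, 0, cfg$jitter_sd)
  jprob <- jprob / sum(jprob)
  chrom <- truth$chrom[1]
  recs <- with_substream(cfg$seed, paste0("pac_cell_line_", cell_line), {
    out <- vector("list", nrow(design))
    for (s in seq_len(nrow(design))) {
      kd <- design$condition[s] == "knockdown"
      cond <- if (kd) "treated" else "control"
      mu <- cfg$depth * (if (kd) 2^truth$lfc_expr else rep(1, nrow(truth)))
      totals <- stats::rnbinom(nrow(truth), mu = mu, size = 1 / cfg$dispersion)
      pi_mat <- cbind(truth[[paste0("pi_utr3_", cond)]],
                      truth[[paste0("pi_intron_", cond)]],
                      truth[[paste0("pi_downstream10k_", cond)]])
      site_pos <- cbind(truth$utr3_site, truth$intron_site, truth$ds_site)
      pos_list <- supp_list <- vector("list", nrow(truth))
      n_dec <- stats::rpois(nrow(truth), cfg$decoy_rate * mu)
      for (i in seq_len(nrow(truth))) {
        cnt <- if (totals[i] > 0) {
          stats::rmultinom(1, totals[i], pi_mat[i, ])[, 1]
        } else c(0L, 0L, 0L)
        pos <- supp <- integer(0)
        for (k in 1:3) {
          if (cnt[k] == 0) next
          jt <- stats::rmultinom(1, cnt[k], jprob)[, 1]
          nz <- which(jt > 0)
          pos <- c(pos, site_pos[i, k] + offs[nz])
          supp <- c(supp, jt[nz])
        }
        if (n_dec[i] > 0) {
          pos <- c(pos, truth$decoy_pos[i])
          supp <- c(supp, n_dec[i])
        }
        pos_list[[i]] <- pos
        supp_list[[i]] <- supp
      }
      gi <- rep(seq_len(nrow(truth)), lengths(pos_list))
      out[[s]] <- data.frame(
        pos = unlist(pos_list), support = unlist(supp_list),
        strand = truth$strand[gi], sample = design$sample[s],
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  sites <- pac_sites(rep(chrom, nrow(recs)), recs$pos, recs$strand,
                     recs$sample, recs$support)
  # make sure every design sample has a support column even if empty
  missing <- setdiff(design$sample, colnames(sites$support))
  if (length(missing) > 0) {
    supp <- cbind(sites$support,
                  matrix(0L, nrow = length(sites), ncol = length(missing),
                         dimnames = list(NULL, missing)))
    sites$support <- supp[, sort(colnames(supp)), drop = FALSE]
  }
  list(sites = sites, design = design)
}

#' Emit raw PAC-seq reads as FASTQ for one sample
#'
#' Expands site-level support into individual reads: each read is the
#' sense-strand genomic insert ending at the site position followed by a
#' synthetic poly(A) tail of length `tail_min + Poisson(tail_extra_mean)`
#' (so every emitted read passes the tail filter; internal-priming decoys
#' are removable only by the genomic-context filter).
#'
#' @param cfg A `SimulationConfig`.
#' @param sim A `PacSim` with genome sequence.
#' @param sites Width-1 `GRanges` with `support` matrix.
#' @param sample Sample (support column) to emit.
#' @param path Output FASTQ path.
#' @param insert_len Genomic insert length (default 50).
#' @return `path`, invisibly.
#' @export
simulate_pac_fastq <- function(cfg, sim, sites, sample, path, insert_len = 50L) {
  stopifnot(!is.null(sim$genome))
  supp <- .support_matrix(sites)[, sample]
  idx <- rep(which(supp > 0), supp[supp > 0])
  pos <- GenomicRanges::start(sites)[idx]
  st <- as.character(BiocGenerics::strand(sites))[idx]
  chrom <- as.character(GenomeInfoDb::seqnames(sites))[idx]
  reads <- with_substream(cfg$seed, paste0("fastq_", sample), {
    tails <- cfg$tail_min + stats::rpois(length(idx), cfg$tail_extra_mean)
    vapply(seq_along(idx), function(i) {
      chr_seq <- sim$genome[[chrom[i]]]
      if (st[i] == "+") {
        from <- max(1L, pos[i] - insert_len + 1L)
        ins <- as.character(Biostrings::subseq(chr_seq, from, pos[i]))
      } else {
        to <- min(length(chr_seq), pos[i] + insert_len - 1L)
        ins <- as.character(Biostrings::reverseComplement(
          Biostrings::subseq(chr_seq, pos[i], to)))
      }
      paste0(ins, strrep("A", tails[i]))
    }, "")
  })
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@read", i, "_", sample),
                 reads[i], "+",
                 strrep("I", nchar(reads[i]))), con)
  }
  invisible(path)
}

#' Simulate a gene-level RNA-seq count matrix for one cell line
#'
#' Counts are negative-binomial with mean `rnaseq_depth * 2^lfc` in the
#' knockdown samples and `rnaseq_depth` in the controls, using each
#' gene's planted expression log2FC.
#'
#' @inheritParams simulate_pac_experiment
#' @return List: `counts` (gene x sample integer matrix), `design`.
#' @export
simulate_rnaseq <- function(cfg, sim, cell_line = 1L) {
  truth <- sim$truth
  design <- .sim_design(cfg)
  counts <- with_substream(cfg$seed, paste0("rnaseq_cell_line_", cell_line), {
    m <- sapply(seq_len(nrow(design)), function(s) {
      kd <- design$condition[s] == "knockdown"
      mu <- cfg$rnaseq_depth * (if (kd) 2^truth$lfc_expr else rep(1, nrow(truth)))
      stats::rnbinom(nrow(truth), mu = mu, size = 1 / cfg$rnaseq_dispersion)
    })
    dimnames(m) <- list(truth$gene_id, design$sample)
    m
  })
  list(counts = counts, design = design)
}

#' Simulate actinomycin-D decay time courses as qPCR Ct tables
#'
#' Per gene, percent remaining follows `100 * exp(-K * (t - t0))` at the
#' configured time points (t0 = first time point), converted to Ct via a
#' standard curve (`Ct = ref_ct + slope * log10(pct / 100)`) with
#' Gaussian Ct noise. A noise-free dilution-series table for fitting the
#' standard curve is included.
#'
#' @param cfg A `SimulationConfig`.
#' @return List: `ct` (data.frame gene/time_h/ct), `curve` (data.frame
#'   ct/log10_quantity), `ref_ct`, `truth` (gene/K/t_half).
#' @export
simulate_decay <- function(cfg) {
  t0 <- min(cfg$decay_times)
  with_substream(cfg$seed, "decay", {
    K <- stats::rlnorm(cfg$decay_n_genes, log(log(2) / 8), 0.4)
    genes <- sprintf("D%03d", seq_len(cfg$decay_n_genes))
    grid <- expand.grid(gene = genes, time_h = cfg$decay_times,
                        stringsAsFactors = FALSE)
    pct <- 100 * exp(-K[match(grid$gene, genes)] * (grid$time_h - t0))
    ct <- cfg$decay_ref_ct + cfg$decay_slope * log10(pct / 100) +
      stats::rnorm(nrow(grid), 0, cfg$decay_ct_sd)
    dil <- 10^-(0:3 * log10(2))     # 2-fold dilution series
    list(
      ct = data.frame(grid, ct = ct),
      curve = data.frame(ct = cfg$decay_ref_ct + cfg$decay_slope * log10(dil),
                         log10_quantity = log10(dil)),
      ref_ct = cfg$decay_ref_ct,
      truth = data.frame(gene = genes, K = K, t_half = log(2) / K,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a cohort expression matrix with a driver-correlated gene set
#'
#' The driver gene is standard normal across samples; each gene-set
#' member equals `rho * driver + sqrt(1 - rho^2) * noise`; background
#' genes are independent standard normals.
#'
#' @param cfg A `SimulationConfig`.
#' @param gs A `GeneSet` (>= 2 genes) whose members are generated as
#'   driver-correlated.
#' @param driver Name of the driver gene row (default `"DRIVER"`).
#' @return List: `expr` (genes x samples matrix), `driver`, `rho`.
#' @export
simulate_cohort <- function(cfg, gs, driver = "DRIVER") {
  genes <- if (inherits(gs, "GeneSet")) gs$genes else as.character(gs)
  stopifnot(length(genes) >= 2)
  rho <- cfg$cohort_rho
  if (rho < -1 || rho > 1) stop("cohort_rho must lie in [-1, 1]")
  with_substream(cfg$seed, "cohort", {
    n <- cfg$cohort_n
    drv <- stats::rnorm(n)
    set_m <- t(vapply(genes, function(g) {
      rho * drv + sqrt(1 - rho^2) * stats::rnorm(n)
    }, numeric(n)))
    bg <- matrix(stats::rnorm(cfg$cohort_background * n),
                 nrow = cfg$cohort_background,
                 dimnames = list(sprintf("BG%04d", seq_len(cfg$cohort_background)),
                                 NULL))
    expr <- rbind(matrix(drv, nrow = 1, dimnames = list(driver, NULL)),
                  set_m, bg)
    colnames(expr) <- sprintf("S%04d", seq_len(n))
    list(expr = expr, driver = driver, rho = rho)
  })
}
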