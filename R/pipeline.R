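#' Default analysis parameters
#'
#' The literal default parameter set of the pipeline: 300-nt 3' UTR
#' extension, 10-kb downstream window, >= 25 A tail, internal-priming
#' removal at > 12 A per 20 nt, 25-nt cluster gap, > 2 cpm expression
#' filter, >= 5 mapped reads, APA padj < 0.1 with >= 10% usage change,
#' and the quadrant-I gene-set thresholds (PAC-score > 0.5, expression
#' log2FC < -0.25, >= 2 contrasts).
#'
#' @return Named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(
    extension_nt = 300L,
    window_nt = 10000L,
    min_a = 25L,
    ip_window = 20L,
    ip_max_a = 12L,
    cluster_gap = 25L,
    min_cpm = 2,
    min_reads = 5L,
    padj_max = 0.1,
    min_frac_change = 0.10,
    pac_min = 0.5,
    lfc_max = -0.25,
    min_contrasts = 2L,
    prior_cpm = 0.5
  )
}

#' Assemble a pipeline configuration
#'
#' @param gtf,fasta Paths to the annotation GTF and genome FASTA (a
#'   `<fasta>.fai` index must sit beside the FASTA).
#' @param contrasts List of per-contrast lists, each with `name`,
#'   `pac_bed` (3'-end site BED, see [read_pac_bed()]), `rna_counts`
#'   (gene x sample TSV) and `design` (TSV with columns
#'   `sample`/`condition`, conditions `control` and `knockdown`).
#' @param out_dir Output directory.
#' @param params Parameter list (defaults from
#'   [default_pipeline_params()]; entries given here override).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(gtf, fasta, contrasts, out_dir,
                            params = list()) {
  p <- utils::modifyList(default_pipeline_params(), params)
  structure(list(gtf = gtf, fasta = fasta, contrasts = contrasts,
                 out_dir = out_dir, params = p),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Checks that every input file exists, parameters lie in sane ranges,
#' and each contrast design names both conditions with replication. All
#' violations are collected and reported together.
#'
#' @param cfg A `PipelineConfig`.
#' @return The config, invisibly, when valid; otherwise an error listing
#'   every violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)
  for (f in c(cfg$gtf, cfg$fasta, paste0(cfg$fasta, ".fai"))) {
    if (!file.exists(f)) note(paste("missing file:", f))
  }
  p <- cfg$params
  pos <- c("extension_nt", "window_nt", "min_a", "ip_window", "cluster_gap",
           "min_reads", "min_cpm")
  for (k in pos) if (!is.numeric(p[[k]]) || p[[k]] <= 0) {
    note(paste0("parameter '", k, "' must be positive"))
  }
  if (p$ip_max_a < 0 || p$ip_max_a > p$ip_window) {
    note("parameter 'ip_max_a' must lie in [0, ip_window]")
  }
  if (p$padj_max <= 0 || p$padj_max > 1) note("parameter 'padj_max' must be in (0, 1]")
  if (p$min_frac_change < 0 || p$min_frac_change > 1) {
    note("parameter 'min_frac_change' must be in [0, 1]")
  }
  if (length(cfg$contrasts) < p$min_contrasts) {
    note(sprintf("need >= %d contrasts, got %d", p$min_contrasts,
                 length(cfg$contrasts)))
  }
  for (ct in cfg$contrasts) {
    for (f in c(ct$pac_bed, ct$rna_counts, ct$design)) {
      if (is.null(f) || !file.exists(f)) {
        note(paste0("contrast '", ct$name, "': missing file: ",
                    if (is.null(f)) "(unset)" else f))
      }
    }
    if (!is.null(ct$design) && file.exists(ct$design)) {
      d <- utils::read.table(ct$design, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      if (!all(c("sample", "condition") %in% names(d))) {
        note(paste0("contrast '", ct$name,
                    "': design needs 'sample' and 'condition' columns"))
      } else if (!all(c("control", "knockdown") %in% d$condition)) {
        note(paste0("contrast '", ct$name,
                    "': design must contain 'control' and 'knockdown' samples"))
      }
    }
  }
  if (length(bad) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(bad, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' Quantify filtered, clustered 3'-end sites into region classes
#'
#' One call covering the quantification stage: remove internal-priming
#' artifacts by genomic context, cluster the surviving sites, and count
#' clusters into the four region classes.
#'
#' @param sites Width-1 `GRanges` with `support` matrix.
#' @param genome Named `DNAStringSet`.
#' @param regions Named region-set list from [build_all_regions()].
#' @param ip_window,ip_max_a Internal-priming filter parameters.
#' @param cluster_gap Cluster gap (nt).
#' @return List: `feature_counts`, `clusters`, `sites_kept`,
#'   `n_sites_removed`.
#' @export
quantify_pac <- function(sites, genome, regions,
                         ip_window = 20L, ip_max_a = 12L, cluster_gap = 25L) {
  keep <- internal_priming_filter(sites, genome, ip_window, ip_max_a)
  kept <- sites[keep]
  clusters <- cluster_sites(kept, max_gap = cluster_gap)
  list(
    feature_counts = count_by_feature(clusters, regions),
    clusters = clusters,
    sites_kept = kept,
    n_sites_removed = sum(!keep)
  )
}

#' Differential analysis of one contrast
#'
#' Applies the expression and read-support filters to the gene x region
#' PAC count matrix and the gene-level RNA-seq matrix, runs the
#' differential test (knockdown vs control) on both, and builds
#' PAC-score tables for the three non-UTR region classes.
#'
#' @param fc A `FeatureCounts` from [quantify_pac()].
#' @param pac_design data.frame `sample`/`condition` for the PAC samples.
#' @param rna_counts Gene x sample integer matrix.
#' @param rna_design data.frame `sample`/`condition` for RNA samples.
#' @param params Parameter list (see [default_pipeline_params()]).
#' @return List: `pac_diff`, `rna_diff`, `scores` (named list of
#'   PAC-score tables for `intron`, `cds`, `downstream10k`).
#' @export
analyze_contrast <- function(fc, pac_design, rna_counts, rna_design,
                             params = default_pipeline_params()) {
  m <- feature_counts_matrix(fc)
  m <- m[, pac_design$sample, drop = FALSE]
  cond <- pac_design$condition
  keep <- filter_min_reads(m, cond, params$min_reads) &
    filter_expressed(cpm_normalize(m, fc$library_sizes[pac_design$sample]),
                     cond, params$min_cpm)
  pac_diff <- diff_test(m[keep, , drop = FALSE], cond,
                        treated = "knockdown", control = "control",
                        lib_size = fc$library_sizes[pac_design$sample],
                        prior_cpm = params$prior_cpm)

  rna_counts <- as.matrix(rna_counts)[, rna_design$sample, drop = FALSE]
  rcond <- rna_design$condition
  rkeep <- filter_expressed(cpm_normalize(rna_counts), rcond, params$min_cpm) &
    filter_min_reads(rna_counts, rcond, params$min_reads)
  rna_diff <- diff_test(rna_counts[rkeep, , drop = FALSE], rcond,
                        treated = "knockdown", control = "control",
                        prior_cpm = params$prior_cpm)
  scores <- lapply(stats::setNames(nm = c("intron", "cds", "downstream10k")),
                   function(cls) pac_score_table(pac_diff, rna_diff, cls))
  list(pac_diff = pac_diff, rna_diff = rna_diff, scores = scores)
}

#' Run the full pipeline on a validated configuration
#'
#' Stages: partition (region construction from the GTF), quantify
#' (internal-priming filter, clustering, region counting per contrast),
#' diff (PAC and RNA differential tables), integrate (PAC-scores,
#' quadrant summaries, quadrant-I gene set across contrasts). All tables
#' are written under `out_dir` with the configuration hash in a header
#' comment; a `provenance.json` records parameters and stage status.
#' The pipeline is deterministic: re-running the same configuration
#' reproduces identical tables.
#'
#' @param cfg A `PipelineConfig` (validated with [validate_config()]).
#' @return List: `regions`, `contrasts` (per-contrast results),
#'   `qi_set`, `quadrant_summary`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  prov <- list(package = "pacscope",
               version = as.character(utils::packageVersion("pacscope")),
               config_hash = hash, params = p, stages = list())
  emit_prov <- function() {
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      prov$stages[[name]] <<- list(status = "failed",
                                   error = conditionMessage(e))
      emit_prov()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    prov$stages[[name]] <<- list(status = "ok")
    res
  }

  regions <- stage("partition", {
    ann <- load_annotation(cfg$gtf, fai = paste0(cfg$fasta, ".fai"))
    r <- build_all_regions(ann, p$extension_nt, p$window_nt)
    for (cls in names(r)) {
      write_regions_bed(r[[cls]], file.path(cfg$out_dir,
                                            paste0("regions_", cls, ".bed")))
    }
    r
  })
  genome <- stage("genome", {
    g <- Biostrings::readDNAStringSet(cfg$fasta)
    names(g) <- sub("\\s.*", "", names(g))
    g
  })

  results <- list()
  for (ct in cfg$contrasts) {
    results[[ct$name]] <- stage(paste0("contrast_", ct$name), {
      sites <- read_pac_bed(ct$pac_bed)
      q <- quantify_pac(sites, genome, regions,
                        p$ip_window, p$ip_max_a, p$cluster_gap)
      design <- utils::read.table(ct$design, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      rna <- read_count_tsv(ct$rna_counts)
      res <- analyze_contrast(q$feature_counts, design, rna, design, p)
      .write_tsv(res$pac_diff, file.path(cfg$out_dir,
                                         paste0(ct$name, "_pac_diff.tsv")), hash)
      .write_tsv(res$rna_diff, file.path(cfg$out_dir,
                                         paste0(ct$name, "_rna_diff.tsv")), hash)
      .write_tsv(res$scores$downstream10k,
                 file.path(cfg$out_dir, paste0(ct$name, "_pac_scores.tsv")), hash)
      res
    })
  }

  integ <- stage("integrate", {
    tabs <- lapply(results, function(r) r$scores$downstream10k)
    qi <- derive_qi_geneset(tabs, p$pac_min, p$lfc_max, p$min_contrasts)
    write_gmt(qi, file.path(cfg$out_dir, "genesets.gmt"))
    qsum <- lapply(results, function(r) {
      lapply(r$scores, function(s) as.list(quadrant_counts(s$quadrant)))
    })
    jsonlite::write_json(qsum, file.path(cfg$out_dir, "quadrant_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(qi_set = qi, quadrant_summary = qsum)
  })
  emit_prov()
  list(regions = regions, contrasts = results, qi_set = integ$qi_set,
       quadrant_summary = integ$quadrant_summary, out_dir = cfg$out_dir)
}

#' Read a gene x sample count TSV (genes in rows, header mandatory)
#'
#' @param path TSV path; first column = unit id.
#' @return Integer matrix.
#' @export
read_count_tsv <- function(path) {
  m <- read_expression_tsv(path)
  storage.mode(m) <- "integer"
  m
}

#' Write a unit x sample count matrix as TSV
#'
#' @param m Matrix with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(m, path) {
  write_expression_tsv(m, path)
}

#' Stable short hash of a pipeline configuration
#'
#' A small rolling hash over the deparsed parameters and input paths;
#' written into every output table's header comment so outputs can be
#' matched to the configuration that produced them.
#'
#' @param cfg A `PipelineConfig`.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[c("gtf", "fasta", "params")]), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pacscope config=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
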