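# One-shot orchestration of the analysis stages with config validation,
# structured logging and a reproducibility manifest.

.PIPELINE_KEYS <- c("fasta", "gff3", "sam", "query_fasta", "out_dir",
                    "min_level", "min_depth", "min_total_length", "min_anchor",
                    "min_ir_length", "minor_fraction", "min_het_depth", "seed")

.PIPELINE_DEFAULTS <- list(min_level = 0.05, min_depth = 20L,
                           min_total_length = 8L, min_anchor = 1L,
                           min_ir_length = 500L, minor_fraction = 0.01,
                           min_het_depth = 1000L, seed = 1L)

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path. Unknown keys are errors (this
#' protects against silently ignored threshold typos); missing thresholds
#' take their documented defaults.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(.PIPELINE_DEFAULTS)) {
    if (is.null(config[[k]])) config[[k]] <- .PIPELINE_DEFAULTS[[k]]
  }
  if (is.null(config$fasta)) stop("config requires 'fasta'")
  if (is.null(config$out_dir)) stop("config requires 'out_dir'")
  with(config, {
    stopifnot(min_level >= 0, min_level <= 1, min_depth >= 1,
              min_total_length >= 1, min_anchor >= 0,
              minor_fraction >= 0, minor_fraction < 0.5)
  })
  structure(config, class = "pipeline_config")
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed [E_", toupper(name), "]: ",
         conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[chloroslip] stage=%s elapsed=%.2fs rows=%s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  if (is.data.frame(res)) nrow(res) else length(res)))
  res
}

#' Run the full analysis pipeline
#'
#' Executes, in order: SSR detection, quadripartite structure resolution,
#' pileup construction, editing-site calling (Table-style TSV), per-SSR
#' slippage tallies with the frequency-vs-length regression, codon-level
#' annotation of called editing sites, and -- when a second genome is given --
#' plastome comparison with variant calling and heteroplasmy assessment. All
#' outputs are written under `out_dir` together with a manifest recording the
#' package version, seed, thresholds and input checksums. Identical config
#' and inputs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] (list or YAML path).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_full_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  genome <- .stage("read_genome", read_plastome(cfg$fasta))
  genes <- if (!is.null(cfg$gff3)) {
    .stage("read_genes", read_gene_models(cfg$gff3))
  } else NULL
  genome$genes <- genes

  ssrs <- .stage("ssr", find_ssrs(genome$seq,
                                  min_total_length = cfg$min_total_length))
  write_ssr_tsv(ssrs, out("ssr.tsv"))

  partition <- .stage("structure", detect_inverted_repeats(
    genome$seq, min_ir_length = cfg$min_ir_length))
  write_partition_json(partition, out("structure.json"))

  results <- list(genome = genome, ssrs = ssrs, partition = partition)

  if (!is.null(cfg$sam)) {
    aln <- .stage("read_sam", read_sam(cfg$sam))
    pileup <- .stage("pileup", build_pileup(aln, genome))
    write_pileup_tsv(pileup, out("pileup.tsv"))

    calls <- .stage("edit", call_editing_sites(
      pileup, genome, genes, min_level = cfg$min_level,
      min_depth = cfg$min_depth))
    annotations <- if (nrow(calls$sites)) {
      do.call(rbind, lapply(seq_len(nrow(calls$sites)), function(i) {
        s <- calls$sites[i, ]
        g <- if (s$gene == "intergenic") NULL else gene_model(genes, s$gene)
        ann <- annotate_editing_site(s, g, genome)
        ann$level_percent <- round(100 * s$level, 2)
        ann
      }))
    } else {
      data.frame()
    }
    utils::write.table(annotations, out("editing_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    tally <- .stage("slip_tally", scan_ssr_indels(
      aln, ssrs, genome, min_anchor = cfg$min_anchor))
    freqs <- compute_ts_frequencies(tally, ssrs)
    write_slippage_tsv(freqs, out("slippage.tsv"))
    regression <- tryCatch(regress_frequency_on_length(freqs),
                           error = function(e) NULL)
    if (!is.null(regression)) {
      write_regression_json(regression, out("regression.json"))
    }
    results <- c(results, list(pileup = pileup, editing = calls,
                               editing_table = annotations,
                               slippage = freqs, regression = regression))
    if (nrow(calls$sites) == 0L) {
      writeLines("no editing sites called", out("EMPTY_editing"))
    }
  }

  if (!is.null(cfg$query_fasta)) {
    query <- .stage("read_query", read_plastome(cfg$query_fasta))
    alnp <- .stage("align", align_plastomes(genome, query))
    variants <- .stage("variants", call_variants(alnp))
    write_vcf(variants, genome, out("variants.vcf"))
    utils::write.table(variants, out("variants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$variants <- variants
    if (!is.null(results$pileup)) {
      het <- .stage("heteroplasmy", assess_heteroplasmy(
        variants, results$pileup, min_depth = cfg$min_het_depth,
        minor_fraction = cfg$minor_fraction))
      jsonlite::write_json(
        list(verdict = het$verdict, note = het$note,
             per_variant = het$per_variant),
        out("heteroplasmy.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE, dataframe = "rows")
      results$heteroplasmy <- het
    }
  }

  inputs <- Filter(Negate(is.null),
                   list(fasta = cfg$fasta, gff3 = cfg$gff3, sam = cfg$sam,
                        query_fasta = cfg$query_fasta))
  manifest <- list(
    package = "chloroslip",
    version = as.character(utils::packageVersion("chloroslip")),
    seed = cfg$seed,
    thresholds = cfg[intersect(names(cfg), names(.PIPELINE_DEFAULTS))],
    input_md5 = as.list(tools::md5sum(unlist(inputs))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(results)
}
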