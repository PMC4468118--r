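#' Configuration for a synthetic quadripartite plastome
#'
#' Describes a toy circular plastome: quadripartite region sizes, SSR runs to
#' plant, protein-coding genes to plant, per-gene C-to-U editing levels, and
#' the transcriptional-slippage and sequencing-error model used by
#' [simulate_reads()]. Defaults emulate the conditions reported for
#' chloroplast transcriptomes: mononucleotide SSRs of 8-16 bp, editing levels
#' mostly high, per-read slippage probability increasing linearly with SSR
#' length within the observed 0-74% range, and a uniform substitution error
#' rate typical of Illumina data.
#'
#' @param ir_length,lsc_length,ssc_length Region sizes in bp
#'   (`lsc_length >= ssc_length`); total genome length is
#'   `lsc + ssc + 2 * ir`.
#' @param ssr_spec `data.frame` with columns `motif_base` (single base, or a
#'   two-base motif for a dinucleotide repeat), `run_length` (total bp,
#'   >= 8), `count`, and optionally `region` (`"lsc"` or `"ssc"`, default
#'   `"lsc"`).
#' @param gene_spec `data.frame` with columns `name`, `strand` (`+`/`-`),
#'   `cds_length` (bp, divisible by 3, >= 9, includes the stop codon), and
#'   optionally `region`.
#' @param editing_spec `data.frame` with columns `gene` and `level` (fraction
#'   in \[0,1\]); one C-to-U site is planted per row, at codon position 2 of a
#'   serine/proline-like C codon inside that gene.
#' @param slip_model Function mapping SSR total length (bp) to the per-read
#'   probability of one slippage indel for reads spanning the run.
#' @param insertion_fraction Fraction of slippage indels that are insertions.
#' @param error_rate Per-base substitution error rate for simulated reads.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `plastome_config`.
#' @export
plastome_config <- function(ir_length = 1000L, lsc_length = 4000L,
                            ssc_length = 2000L,
                            ssr_spec = data.frame(motif_base = "A",
                                                  run_length = 9L, count = 1L),
                            gene_spec = data.frame(name = "geneA", strand = "+",
                                                   cds_length = 300L),
                            editing_spec = NULL,
                            slip_model = function(L) pmin(0.05 * (L - 7), 0.9),
                            insertion_fraction = 0.5,
                            error_rate = 0.001,
                            seed = 1L) {
  total <- lsc_length + ssc_length + 2L * ir_length
  stopifnot(lsc_length >= ssc_length, ir_length > 0L)
  if (!is.null(ssr_spec) && nrow(ssr_spec)) {
    if (is.null(ssr_spec$region)) ssr_spec$region <- "lsc"
    if (any(ssr_spec$run_length < 8L)) stop("planted SSR runs must be >= 8 bp")
    if (!all(ssr_spec$region %in% c("lsc", "ssc"))) {
      stop("SSRs can be planted in 'lsc' or 'ssc' only")
    }
  }
  if (!is.null(gene_spec) && nrow(gene_spec)) {
    if (is.null(gene_spec$region)) gene_spec$region <- "lsc"
    if (any(gene_spec$cds_length %% 3L != 0L | gene_spec$cds_length < 9L)) {
      stop("gene cds_length must be divisible by 3 and >= 9")
    }
    if (!all(gene_spec$region %in% c("lsc", "ssc"))) {
      stop("genes can be planted in 'lsc' or 'ssc' only")
    }
  }
  if (!is.null(editing_spec) && nrow(editing_spec)) {
    stopifnot(all(editing_spec$level >= 0 & editing_spec$level <= 1),
              all(editing_spec$gene %in% gene_spec$name))
  }
  stopifnot(insertion_fraction >= 0, insertion_fraction <= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(total_length = total, ir_length = as.integer(ir_length),
                 lsc_length = as.integer(lsc_length),
                 ssc_length = as.integer(ssc_length),
                 ssr_spec = ssr_spec, gene_spec = gene_spec,
                 editing_spec = editing_spec, slip_model = slip_model,
                 insertion_fraction = insertion_fraction,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "plastome_config")
}

## random CDS of n bp: ATG + sense codons + TAA, free of runs >= 8
.random_cds <- function(n) {
  n_mid <- n %/% 3L - 2L
  sense <- setdiff(names(.GENETIC_CODE_11), c("TAA", "TAG", "TGA"))
  repeat {
    cds <- paste0("ATG", paste(sample(sense, n_mid, replace = TRUE),
                               collapse = ""), "TAA")
    bad <- find_ssrs(cds, min_total_length = 8L, circular = FALSE)
    if (nrow(bad) == 0L) return(cds)
    ## re-draw the codon at the middle of the first offending run
    codon_i <- ((bad$start[1L] + bad$total_length[1L] %/% 2L - 1L) %/% 3L) + 1L
    codon_i <- min(max(codon_i, 2L), n %/% 3L - 1L)
    cds <- str_sub_replace(cds, 3L * (codon_i - 1L) + 1L, sample(sense, 1L))
  }
}

## break every mono/di run >= 8 in a linear sequence by point substitution
.clean_runs <- function(s, min_len = 8L) {
  for (iter in 1:200) {
    loci <- find_ssrs(s, min_total_length = min_len, circular = FALSE)
    if (nrow(loci) == 0L) return(s)
    for (r in seq_len(nrow(loci))) {
      at <- loci$start[r] + loci$total_length[r] %/% 2L
      nb <- c(substr(s, at - 1L, at - 1L), substr(s, at, at),
              substr(s, at + 1L, at + 1L))
      repl <- setdiff(BASES, nb)[1L]
      s <- str_sub_replace(s, at, repl)
    }
  }
  stop("failed to remove background repeats")
}

## sample a start for a feature of length len inside [lo, hi], avoiding
## occupied intervals (2-bp buffer); occupied is a 2-column matrix
.place_feature <- function(lo, hi, len, occupied, region, what) {
  if (hi - lo + 1L < len) {
    stop("infeasible packing: ", what, " of ", len, " bp exceeds region ", region)
  }
  for (try in 1:1000) {
    s <- .sample1(seq.int(lo, hi - len + 1L))
    e <- s + len - 1L
    if (nrow(occupied) == 0L ||
        all(e < occupied[, 1L] - 2L | s > occupied[, 2L] + 2L)) {
      return(s)
    }
  }
  stop("infeasible packing: could not place ", what, " in region ", region,
       " (SSRs + genes exceed region capacity)")
}

#' Build a synthetic annotated plastome with a known truth table
#'
#' Generates a circular quadripartite genome in which IRb is the exact
#' reverse complement of IRa, plants the configured SSR runs (with flanking
#' bases forced off the run base) and protein-coding genes in the single-copy
#' regions, and plants one C-to-U editing site per `editing_spec` row. The
#' background is scrubbed so that no mononucleotide or dinucleotide run of
#' 8 bp or more exists other than the planted ones, which makes the returned
#' truth table exhaustive.
#'
#' @param config A [plastome_config()].
#' @return A list with elements `plastome` (an `annotated_plastome` whose
#'   `ssrs` table is the [find_ssrs()] scan of the finished genome) and
#'   `truth` (class `truth_table`: `editing_truth` with `position`, `strand`,
#'   `gene`, `true_level`; `slippage_truth` with `ssr_id`, `true_indel_prob`,
#'   `insertion_fraction`; and `error_rate`).
#' @export
build_plastome <- function(config) {
  stopifnot(inherits(config, "plastome_config"))
  set.seed(config$seed)
  lsc <- config$lsc_length; ir <- config$ir_length; ssc <- config$ssc_length
  L <- config$total_length
  region_bounds <- list(lsc = c(1L, lsc),
                        ssc = c(lsc + ir + 1L, lsc + ir + ssc))

  core_len <- lsc + ir + ssc
  core <- .clean_runs(random_dna(core_len))

  occupied <- matrix(integer(), ncol = 2L)
  genes <- NULL
  if (!is.null(config$gene_spec) && nrow(config$gene_spec)) {
    gs <- config$gene_spec
    rows <- vector("list", nrow(gs))
    for (i in seq_len(nrow(gs))) {
      b <- region_bounds[[gs$region[i]]]
      len <- gs$cds_length[i]
      s <- .place_feature(b[1L], b[2L], len, occupied, gs$region[i],
                          paste0("gene ", gs$name[i]))
      cds <- .random_cds(len)
      if (gs$strand[i] == "-") cds <- revcomp(cds)
      core <- str_sub_replace(core, s, cds)
      occupied <- rbind(occupied, c(s, s + len - 1L))
      rows[[i]] <- data.frame(name = gs$name[i], strand = gs$strand[i],
                              start = s, end = s + len - 1L,
                              stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
  }

  planted <- NULL
  if (!is.null(config$ssr_spec) && nrow(config$ssr_spec)) {
    sp <- config$ssr_spec
    rows <- list()
    for (i in seq_len(nrow(sp))) {
      motif <- sp$motif_base[i]
      for (j in seq_len(sp$count[i])) {
        b <- region_bounds[[sp$region[i]]]
        len <- sp$run_length[i]
        if (nchar(motif) == 2L) len <- 2L * (len %/% 2L)
        s <- .place_feature(b[1L], b[2L], len, occupied, sp$region[i],
                            paste0(motif, "-run"))
        run <- paste(rep(motif, ceiling(len / nchar(motif))), collapse = "")
        run <- substr(run, 1L, len)
        core <- str_sub_replace(core, s, run)
        ## force flanks off the run base so the planted length is exact
        for (fl in c(s - 1L, s + len)) {
          if (fl >= 1L && fl <= core_len) {
            required <- c(substr(run, 1L, 1L), substr(run, nchar(run), nchar(run)))
            neighbors <- c(substr(core, fl - 1L, fl - 1L),
                           substr(core, fl + 1L, fl + 1L))
            cand <- setdiff(BASES, c(required, neighbors))
            if (!length(cand)) cand <- setdiff(BASES, required)
            core <- str_sub_replace(core, fl, cand[1L])
          }
        }
        occupied <- rbind(occupied, c(s, s + len - 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motif, start = s, end = s + len - 1L, total_length = len,
          stringsAsFactors = FALSE)
      }
    }
    planted <- do.call(rbind, rows)
  }

  ## mirror IRa into IRb and scrub accidental loci created at junctions or by
  ## planting, without touching planted features
  protected <- occupied
  assemble <- function(core) {
    ira_seq <- substr(core, lsc + 1L, lsc + ir)
    paste0(core, revcomp(ira_seq))
  }
  ## the IR pair must not be extendable into the single-copy regions: if the
  ## first base of the SSC complements its last base, the maximal
  ## reverse-complement pair would grow one base past the planted IR
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  is_protected <- function(p) {
    nrow(protected) > 0L && any(p >= protected[, 1L] & p <= protected[, 2L])
  }
  ssc_first <- lsc + ir + 1L
  if (substr(core, ssc_first, ssc_first) ==
      comp1(substr(core, core_len, core_len))) {
    fix_at <- if (!is_protected(ssc_first)) ssc_first else core_len
    other <- if (fix_at == ssc_first) core_len else ssc_first
    required <- c(substr(core, fix_at, fix_at),
                  comp1(substr(core, other, other)))
    neighbors <- c(substr(core, fix_at - 1L, fix_at - 1L),
                   substr(core, fix_at + 1L, fix_at + 1L))
    pick <- setdiff(BASES, c(required, neighbors))
    if (!length(pick)) pick <- setdiff(BASES, required)
    core <- str_sub_replace(core, fix_at, pick[1L])
  }
  genome <- assemble(core)
  is_planted <- function(loci) {
    if (is.null(planted) || nrow(loci) == 0L) return(rep(FALSE, nrow(loci)))
    paste(loci$start, loci$total_length, loci$motif) %in%
      paste(planted$start, planted$total_length, planted$motif)
  }
  for (iter in 1:50) {
    loci <- find_ssrs(genome, min_total_length = 8L, circular = TRUE)
    extra <- loci[!is_planted(loci), , drop = FALSE]
    if (nrow(extra) == 0L) break
    for (r in seq_len(nrow(extra))) {
      pos <- (seq.int(extra$start[r], extra$start[r] + extra$total_length[r] - 1L) - 1L) %% L + 1L
      ## mutate in single-copy/IRa coordinates; map IRb back onto IRa
      ## (IRb offset t mirrors IRa position lsc + ir + 1 - t)
      pos <- ifelse(pos > core_len, lsc + ir + 1L - (pos - core_len), pos)
      free <- pos[!vapply(pos, function(p) {
        nrow(protected) > 0L && any(p >= protected[, 1L] & p <= protected[, 2L])
      }, logical(1L))]
      if (length(free) == 0L) next
      at <- free[(length(free) + 1L) %/% 2L]
      nb <- c(substr(core, at - 1L, at - 1L), substr(core, at, at),
              substr(core, at + 1L, at + 1L), substr(core, at + 2L, at + 2L))
      cand <- setdiff(BASES, nb)
      ## at most three constraints can be honored with a 4-letter alphabet
      if (!length(cand)) cand <- setdiff(BASES, nb[1:3])
      core <- str_sub_replace(core, at, cand[1L])
    }
    genome <- assemble(core)
  }
  loci <- find_ssrs(genome, min_total_length = 8L, circular = TRUE)
  if ((is.null(planted) && nrow(loci) > 0L) ||
      (!is.null(planted) && !all(is_planted(loci)))) {
    stop("failed to scrub accidental SSRs from the synthetic genome")
  }
  stopifnot(nchar(genome) == L)

  ## plant editing truth: one C (transcript strand) at codon position 2
  editing <- data.frame(position = integer(), strand = character(),
                        gene = character(), true_level = numeric())
  if (!is.null(config$editing_spec) && nrow(config$editing_spec)) {
    es <- config$editing_spec
    used <- integer()
    rows <- vector("list", nrow(es))
    for (i in seq_len(nrow(es))) {
      g <- genes[genes$name == es$gene[i], , drop = FALSE][1L, ]
      cds <- substr(genome, g$start, g$end)
      if (g$strand == "-") cds <- revcomp(cds)
      offs <- which(strsplit(cds, "")[[1]] == "C")
      offs <- offs[offs %% 3L == 2L & offs > 3L & offs <= nchar(cds) - 3L]
      gpos <- if (g$strand == "+") g$start + offs - 1L else g$end - offs + 1L
      keep <- !(gpos %in% used)
      if (!is.null(planted) && nrow(planted)) {
        keep <- keep & !vapply(gpos, function(p) {
          any(p >= planted$start - 2L & p <= planted$end + 2L)
        }, logical(1L))
      }
      if (!any(keep)) stop("no plantable editing position in gene ", g$name)
      pick <- .sample1(which(keep))
      used <- c(used, gpos[pick])
      rows[[i]] <- data.frame(position = gpos[pick], strand = g$strand,
                              gene = g$name, true_level = es$level[i],
                              stringsAsFactors = FALSE)
    }
    editing <- do.call(rbind, rows)
  }

  slippage <- data.frame(ssr_id = character(), true_indel_prob = numeric(),
                         insertion_fraction = numeric())
  if (nrow(loci)) {
    slippage <- data.frame(ssr_id = loci$ssr_id,
                           true_indel_prob = config$slip_model(loci$total_length),
                           insertion_fraction = config$insertion_fraction,
                           stringsAsFactors = FALSE)
  }

  partition <- structure(list(
    found = TRUE, ira = c(lsc + 1L, lsc + ir),
    irb = c(core_len + 1L, L), lsc = c(1L, lsc),
    ssc = c(lsc + ir + 1L, core_len), ir_length = ir,
    lsc_length = lsc, ssc_length = ssc), class = "quadripartite")

  list(
    plastome = annotated_plastome(genome, name = "synthetic_plastome",
                                  genes = genes, ssrs = loci,
                                  partition = partition),
    truth = structure(list(editing_truth = editing, slippage_truth = slippage,
                           error_rate = config$error_rate),
                      class = "truth_table")
  )
}

#' Write a truth table to TSV files
#'
#' @param truth A `truth_table` from [build_plastome()].
#' @param dir Output directory (created if needed); writes
#'   `editing_truth.tsv` and `slippage_truth.tsv`.
#' @export
write_truth_table <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$editing_truth, file.path(dir, "editing_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$slippage_truth, file.path(dir, "slippage_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
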