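## micro-gene around a single codon, mirroring annotate_codon_changes
micro_site <- function(codon_rna, cpos, strand = "+") {
  codon <- chartr("U", "T", codon_rna)
  t <- paste0("ATG", codon, "TAA")
  pad <- "GCGCA"
  genome <- paste0(pad, if (strand == "-") revcomp(t) else t, pad)
  g0 <- nchar(pad) + 1L
  gene <- list(name = "g", strand = strand,
               cds = data.frame(start = g0, end = g0 + 8L),
               span = c(g0, g0 + 8L))
  off <- 3L + cpos
  pos <- if (strand == "+") g0 + off - 1L else (g0 + 8L) - off + 1L
  list(site = list(position = pos), gene = gene, genome = genome)
}

test_that("codon-level annotation reproduces canonical editing outcomes", {
  cases <- list(
    list("UCA", 2L, "UUA", "S", "L", "nonsynonymous"),
    list("UCC", 3L, "UCU", "S", "S", "synonymous"),
    list("ACG", 2L, "AUG", "T", "M", "nonsynonymous"),
    list("CAA", 1L, "UAA", "Q", "*", "stop_gain"),
    list("CAU", 1L, "UAU", "H", "Y", "nonsynonymous"))
  for (strand in c("+", "-")) {
    for (cs in cases) {
      m <- micro_site(cs[[1]], cs[[2]], strand)
      ann <- annotate_editing_site(m$site, m$gene, m$genome)
      expect_equal(ann$codon_to, cs[[3]])
      expect_equal(ann$codon_position, cs[[2]])
      expect_equal(ann$aa_from, cs[[4]])
      expect_equal(ann$aa_to, cs[[5]])
      expect_equal(ann$effect, cs[[6]], info = paste(cs[[1]], strand))
    }
  }
})

test_that("ACG edited at position 2 of codon 1 is a start gain", {
  genome <- paste0("GCGCA", "ACG", "AAA", "TAA", "GCGCA")
  gene <- list(name = "g", strand = "+",
               cds = data.frame(start = 6L, end = 14L), span = c(6L, 14L))
  ann <- annotate_editing_site(list(position = 7L), gene, genome)
  expect_equal(ann$effect, "start_gain")
  expect_equal(ann$codon_to, "AUG")
})

test_that("annotation agrees with an independent translation oracle over all codons", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (codon in codons) {
    for (cpos in 1:3) {
      if (substr(codon, cpos, cpos) != "C") next
      m <- micro_site(chartr("T", "U", codon), cpos)
      ann <- annotate_editing_site(m$site, m$gene, m$genome)
      edited <- codon
      substr(edited, cpos, cpos) <- "T"
      expect_equal(ann$aa_from, oracle_translate(codon))
      expect_equal(ann$aa_to, oracle_translate(edited))
      expect_equal(ann$codon_to, chartr("T", "U", edited))
    }
  }
})

test_that("sites outside the CDS produce structured non-coding annotations", {
  m <- micro_site("UCA", 2L)
  outside <- annotate_editing_site(list(position = 2L), m$gene, m$genome)
  expect_equal(outside$effect, "non_coding")
  spacer <- annotate_editing_site(list(position = 2L), NULL, m$genome)
  expect_equal(spacer$gene, "intergenic")
  expect_equal(spacer$effect, "non_coding")
})

test_that("effect summaries count codon positions and effect classes", {
  empty <- summarize_editing_effects(
    annotate_codon_changes(data.frame(gene = character(),
                                      strand = character(),
                                      codon_from = character(),
                                      codon_position = integer())))
  expect_equal(empty$n_sites, 0L)
  expect_equal(unname(empty$codon_position), c(0L, 0L, 0L))

  rows <- data.frame(gene = c("a", "b", "c"), strand = c("+", "-", "+"),
                     codon_from = c("UCA", "CAU", "UCC"),
                     codon_position = c(2L, 1L, 3L))
  s <- summarize_editing_effects(annotate_codon_changes(rows))
  expect_equal(s$codon_position, c(`1` = 1L, `2` = 1L, `3` = 1L))
  expect_equal(s$effect[["synonymous"]], 1L)
  expect_equal(s$effect[["nonsynonymous"]], 2L)
})

test_that("psbF-analog frameshifts give the expected variant proteins", {
  g <- read_plastome(extdata("psbF_operon_synthetic.fa"))
  genes <- read_gene_models(extdata("psbF_operon_synthetic.gff3"))
  psbF <- gene_model(genes, "psbF")
  edit <- data.frame(position = 107L, strand = "+")

  ref <- predict_indel_consequence(psbF, g, list(position = NA, type = "none"),
                                   apply_editing = edit, gene_models = genes)
  expect_equal(ref$protein_length, 39L)
  expect_equal(ref$shared_n_terminal, 39L)

  ins <- predict_indel_consequence(psbF, g,
                                   list(position = 98L, type = "insertion",
                                        base = "T"),
                                   apply_editing = edit, gene_models = genes)
  expect_equal(ins$protein_length, 42L)
  expect_equal(ins$shared_n_terminal, 27L)
  expect_false(ins$stops_in_gene)
  expect_true(is.na(ins$fusion_partner))

  del <- predict_indel_consequence(psbF, g,
                                   list(position = 98L, type = "deletion"),
                                   apply_editing = edit, gene_models = genes)
  expect_equal(del$protein_length, 85L)
  expect_equal(del$fusion_partner, "psbL")
})

test_that("an insertion plus a deletion in the same run restores the reference", {
  g <- read_plastome(extdata("psbF_operon_synthetic.fa"))
  genes <- read_gene_models(extdata("psbF_operon_synthetic.gff3"))
  psbF <- gene_model(genes, "psbF")
  edit <- data.frame(position = 107L, strand = "+")
  ## apply the insertion to the sequence, then delete within the same run
  mut <- g
  mut$seq <- paste0(substr(g$seq, 1, 97), "T", substr(g$seq, 98, nchar(g$seq)))
  mut$length <- nchar(mut$seq)
  shifted_genes <- genes
  shifted_genes$start <- ifelse(genes$start > 98L, genes$start + 1L, genes$start)
  shifted_genes$end <- ifelse(genes$end >= 98L, genes$end + 1L, genes$end)
  psbF_shift <- gene_model(shifted_genes, "psbF")
  back <- predict_indel_consequence(psbF_shift, mut,
                                    list(position = 100L, type = "deletion"),
                                    apply_editing = data.frame(position = 108L,
                                                               strand = "+"),
                                    gene_models = shifted_genes)
  ref0 <- predict_indel_consequence(psbF, g, list(position = NA, type = "none"),
                                    apply_editing = edit, gene_models = genes)
  expect_equal(back$protein_length, 39L)
  expect_equal(back$protein, ref0$protein)   # net-zero frame shift
})

test_that("random toy genes match the naive mutate-splice-translate oracle", {
  set.seed(81)
  sense <- setdiff(names(Biostrings::getGeneticCode("11")), c("TAA", "TAG", "TGA"))
  sense <- chartr("U", "T", sense)
  for (rep in 1:50) {
    n_codons <- sample(8:20, 1)
    cds <- paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                               collapse = ""), "TAA")
    ## the run of interleaved stops halts read-through in every frame, so
    ## the oracle and the bounded scanner always see the same stop
    genome <- paste0(random_dna(20), cds, "TTAATTAATTAA", random_dna(60))
    gene <- list(name = "t", strand = "+",
                 cds = data.frame(start = 21L, end = 20L + nchar(cds)),
                 span = c(21L, 20L + nchar(cds)))
    p <- sample(seq.int(24L, 20L + nchar(cds) - 4L), 1)
    type <- sample(c("insertion", "deletion"), 1)
    indel <- list(position = p, type = type, base = sample(c("A", "C", "G", "T"), 1))
    got <- predict_indel_consequence(gene, genome, indel, max_scan = 120L)
    exp <- oracle_indel_consequence(genome, gene, indel)
    expect_equal(got$protein_length, exp$protein_length,
                 info = paste(rep, type, p))
    expect_equal(got$shared_n_terminal, exp$shared_n_terminal)
    expect_equal(got$protein, exp$protein)
  }
})

test_that("minus-strand annotation equals the reverse-complemented plus-strand gene", {
  for (codon in c("UCG", "UCA", "CCU", "ACA", "GCU", "CGA")) {
    cpos <- regexpr("C", chartr("U", "T", codon), fixed = TRUE)[1]
    m <- micro_site(codon, cpos, "+")
    L <- nchar(m$genome)
    genome_rc <- revcomp(m$genome)
    gene_rc <- list(name = "g", strand = "-",
                    cds = data.frame(start = L - m$gene$cds$end + 1L,
                                     end = L - m$gene$cds$start + 1L),
                    span = c(L - m$gene$span[2] + 1L, L - m$gene$span[1] + 1L))
    pos_rc <- L - m$site$position + 1L
    a <- annotate_editing_site(m$site, m$gene, m$genome)
    b <- annotate_editing_site(list(position = pos_rc), gene_rc, genome_rc)
    expect_equal(a$codon_from, b$codon_from)
    expect_equal(a$codon_to, b$codon_to)
    expect_equal(a$aa_from, b$aa_from)
    expect_equal(a$effect, b$effect)
  }
})

test_that("clone classification is definitional and round-trips all six classes", {
  ref <- paste0(strrep("GAC", 8), "CCT", strrep("T", 9), "C", "TGGA",
                strrep("ACG", 4))
  run_start <- 28L; run_end <- 36L; edit_pos <- 37L

  expect_equal(classify_clone_sequence(
    chloroslip:::str_sub_replace(ref, edit_pos, "T"),
    ref, edit_pos, run_start, run_end)$class, "edited|no-indel")
  expect_equal(classify_clone_sequence(ref, ref, edit_pos, run_start,
                                       run_end)$class, "unedited|no-indel")
  ## the sixth observed class: unedited C with a nearby U deletion
  del <- paste0(substr(ref, 1, run_start - 1L),
                substr(ref, run_start + 1L, nchar(ref)))
  expect_equal(classify_clone_sequence(del, ref, edit_pos, run_start,
                                       run_end)$class, "unedited|U-del")

  counts <- stats::setNames(rep(10L, 6L), CLONE_CLASSES)
  clones <- simulate_clone_set(counts, ref, edit_pos, run_start, run_end,
                               seed = 2L)
  summ <- summarize_clone_classes(clones, ref, edit_pos, run_start, run_end)
  expect_equal(summ$count[match(CLONE_CLASSES, summ$class)], rep(10L, 6L))

  ## run-length change of 2 is "other"; unknown labels error
  dbl <- paste0(substr(ref, 1, run_start - 1L), "TT",
                substr(ref, run_start, nchar(ref)))
  expect_equal(classify_clone_sequence(dbl, ref, edit_pos, run_start,
                                       run_end)$class, "other")
  expect_error(simulate_clone_set(c(`weird` = 1L), ref, edit_pos, run_start,
                                  run_end), "unknown clone class")
})
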