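## minimal hand-built alignment rows
mk_aln <- function(pos, cigar, seq, rname = "ref", mapq = 60L, flag = 0L) {
  structure(data.frame(qname = sprintf("r%02d", seq_along(pos)), flag = flag,
                       rname = rname, pos = pos, mapq = mapq, cigar = cigar,
                       seq = seq, qual = "*", strand_tag = "+", nm = 0L,
                       stringsAsFactors = FALSE),
            class = c("simulated_alignment", "data.frame"))
}

test_that("a perfect read contributes one count per covered position", {
  set.seed(51)
  g <- random_dna(100)
  aln <- mk_aln(21L, "50M", substr(g, 21, 70))
  pu <- build_pileup(aln, g)
  expect_equal(sum(pu$depth), 50L)
  expect_equal(which(pu$depth == 1L), 21:70)
  for (p in c(21L, 45L, 70L)) {
    expect_equal(unname(pu$counts[p, substr(g, p, p)]), 1L)
  }
})

test_that("deletions count at each deleted position and insertions at the preceding one", {
  set.seed(52)
  g <- random_dna(60)
  read_del <- paste0(substr(g, 11, 20), substr(g, 22, 31))
  read_ins <- paste0(substr(g, 11, 20), "A", substr(g, 21, 30))
  pu <- build_pileup(mk_aln(c(11L, 11L), c("10M1D10M", "10M1I10M"),
                            c(read_del, read_ins)), g)
  expect_equal(unname(pu$counts[21L, "del"]), 1L)
  expect_equal(pu$depth[21L], 2L)           # deletion + the other read's base
  expect_equal(pu$insertions$position, 21L) # insertion precedes position 21
  expect_equal(pu$insertions$inserted, "A")
  expect_equal(pu$insertions$count, 1L)
})

test_that("mapq gating drops reads entirely and header mismatches error", {
  g <- random_dna(50)
  aln <- mk_aln(1L, "20M", substr(g, 1, 20), mapq = 5L)
  pu <- build_pileup(aln, g, min_mapq = 20L)
  expect_equal(sum(pu$depth), 0L)

  bad <- mk_aln(1L, "20M", substr(g, 1, 20))
  attr(bad, "rname") <- "other"
  expect_error(build_pileup(bad, annotated_plastome(g, name = "ref")),
               "does not match")
  expect_error(build_pileup(mk_aln(1L, "10M5H5M", substr(g, 1, 15)), g),
               "unsupported CIGAR")
})

test_that("pileup counts equal an independent read-replay oracle", {
  bp <- toy_plastome(seed = 53L, level = 0.5, slip9 = 0.3)
  bp$truth$error_rate <- 0.01
  aln <- simulate_reads(bp$plastome, bp$truth, n_reads = 100L,
                        read_length = 60L, seed = 6L,
                        error_profile = "realistic")
  pu <- build_pileup(aln, bp$plastome, min_baseq = 0L)
  expect_equal(pu$counts, oracle_replay_pileup(aln, bp$plastome$length))

  ## conservation: total depth equals aligned bases plus deletion columns,
  ## with inserted bases contributing nothing
  ops <- lapply(aln$cigar, chloroslip:::.parse_cigar)
  aligned <- sum(vapply(ops, function(o) {
    sum(o$len[o$op %in% c("M", "=", "X", "D")])
  }, numeric(1)))
  expect_equal(sum(pu$depth), aligned)
})

test_that("left normalization shifts same-base indels to the run start and is idempotent", {
  g <- paste0("GG", strrep("A", 8), "CTT")   # run at 3..10
  del <- left_normalize_indel(list(position = 7L, type = "deletion",
                                   bases = "A"), g)
  expect_equal(del$position, 3L)
  ins <- left_normalize_indel(list(position = 11L, type = "insertion",
                                   bases = "A"), g)
  expect_equal(ins$position, 3L)
  expect_equal(left_normalize_indel(del, g), del)   # idempotent
  ## never shifts right, and non-matching bases stay put
  other <- left_normalize_indel(list(position = 7L, type = "insertion",
                                     bases = "G"), g)
  expect_equal(other$position, 7L)
})

test_that("left normalization agrees with exhaustive equivalence search", {
  set.seed(54)
  for (rep in 1:40) {
    g <- paste0(random_dna(5), strrep(sample(c("A", "C", "G", "T"), 1),
                                      sample(4:9, 1)), random_dna(5))
    p <- sample(2:(nchar(g) - 1L), 1L)
    base <- substr(g, p, p)
    norm <- left_normalize_indel(list(position = p, type = "deletion",
                                      bases = base), g)
    ## oracle: smallest q such that deleting q yields the same string
    del_at <- function(q) paste0(substr(g, 1, q - 1L),
                                 substr(g, q + 1L, nchar(g)))
    target <- del_at(p)
    q_min <- min(which(vapply(seq_len(nchar(g)), function(q) {
      del_at(q) == target
    }, logical(1))))
    expect_equal(norm$position, q_min)
  }
})

test_that("spanning and indel tallies follow their definitions", {
  g <- paste0(random_dna(30), strrep("A", 10), random_dna(30))  # run 31..40
  loci <- find_ssrs(g, circular = FALSE)
  expect_equal(loci$start, 31L)
  ## 3 spanning clean, 1 spanning with an A-deletion, 1 spanning with a G
  ## insertion (not slippage), 1 overlapping but not spanning
  reads <- list(
    list(pos = 25L, cig = "25M", seq = substr(g, 25, 49)),
    list(pos = 28L, cig = "25M", seq = substr(g, 28, 52)),
    list(pos = 20L, cig = "30M", seq = substr(g, 20, 49)),
    list(pos = 25L, cig = "10M1D15M",
         seq = paste0(substr(g, 25, 34), substr(g, 36, 50))),
    list(pos = 25L, cig = "12M1G", seq = NA),   # placeholder replaced below
    list(pos = 35L, cig = "20M", seq = substr(g, 35, 54)))
  reads[[5]] <- list(pos = 25L, cig = "10M1I14M",
                     seq = paste0(substr(g, 25, 34), "G", substr(g, 35, 48)))
  aln <- mk_aln(vapply(reads, `[[`, integer(1), "pos"),
                vapply(reads, `[[`, character(1), "cig"),
                vapply(reads, `[[`, character(1), "seq"))
  tal <- scan_ssr_indels(aln, loci, g)
  t1 <- tal$tallies
  expect_equal(t1$spanning_reads, 5L)       # read 6 does not span
  expect_equal(t1$indel_reads, 1L)          # only the A deletion
  expect_equal(t1$deletion_reads, 1L)
  expect_equal(t1$insertion_reads, 0L)
  expect_equal(t1$other_indel_reads, 1L)    # the G insertion
  expect_equal(tal$net[tal$net$delta == -1L, "reads"], 1L)
  expect_equal(tal$net[tal$net$delta == 0L, "reads"], 4L)
})

test_that("per-locus tallies equal a naive per-read recount on simulated data", {
  bp <- toy_plastome(seed = 55L, slip9 = 0.25)
  aln <- simulate_reads(bp$plastome, bp$truth, n_reads = 2500L,
                        read_length = 60L, seed = 12L)
  loci <- bp$plastome$ssrs
  tal <- scan_ssr_indels(aln, loci, bp$plastome)$tallies
  rs <- loci$start[1]; re <- loci$end[1]
  ref_len <- chloroslip:::.cigar_ref_len(aln$cigar)
  spanning <- aln$pos <= rs - 1L & aln$pos + ref_len - 1L >= re + 1L
  has_del <- grepl("D", aln$cigar)
  has_ins <- grepl("I", aln$cigar)
  expect_equal(tal$spanning_reads, sum(spanning))
  expect_equal(tal$deletion_reads, sum(spanning & has_del))
  expect_equal(tal$insertion_reads, sum(spanning & has_ins))
})
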