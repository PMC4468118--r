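test_that("identical sequences yield zero variants", {
  set.seed(91)
  s <- random_dna(5000)
  v <- call_variants(align_plastomes(s, s))
  expect_equal(nrow(v), 0L)
})

test_that("a single planted substitution is recovered at its site", {
  set.seed(92)
  a <- random_dna(10000)
  b <- a
  substr(b, 4321, 4321) <- c(A = "G", G = "A", C = "T",
                             T = "C")[[substr(a, 4321, 4321)]]
  v <- call_variants(align_plastomes(a, b))
  expect_equal(nrow(v), 1L)
  expect_equal(v$position, 4321L)
  expect_equal(v$variant_type, "SNV")
  expect_equal(v$snv_class, "transition")
})

test_that("adjacent gap columns merge into one indel event", {
  aln <- structure(list(ref = "ACGTACCGTACGT", query = "ACGTA--GTACGT"),
                   class = "plastome_alignment")
  v <- call_variants(aln)
  expect_equal(nrow(v), 1L)
  expect_equal(v$variant_type, "deletion")
  expect_equal(v$length, 2L)
  expect_equal(v$ref_allele, "CC")
  ## and an A<->G column is a transition by definition
  aln2 <- structure(list(ref = "ACGTA", query = "ACGTG"),
                    class = "plastome_alignment")
  v2 <- call_variants(aln2)
  expect_equal(v2$snv_class, "transition")
})

test_that("indels are left-normalized in homopolymer context", {
  ## deletion of one A inside a run reported at the run start
  set.seed(98)
  ctx <- random_dna(60)
  ref <- paste0(ctx, "GC", strrep("A", 6), "TGCA", random_dna(60))
  qry <- sub("GCAAAAAAT", "GCAAAAAT", ref, fixed = TRUE)
  v <- call_variants(align_plastomes(ref, qry))
  expect_equal(v$variant_type, "deletion")
  expect_equal(v$position, 63L)
  expect_equal(v$ref_allele, "A")
})

test_that("swapping ref and query mirrors indels and preserves SNVs", {
  set.seed(93)
  s <- random_dna(4000)
  pl <- plant_variants(s, n_snv = 6L, n_ins = 2L, n_del = 2L, seed = 17L,
                       indel_max_len = 2L)
  fwd <- call_variants(align_plastomes(s, pl$query))
  rev <- call_variants(align_plastomes(pl$query, s))
  expect_equal(sum(fwd$variant_type == "SNV"), sum(rev$variant_type == "SNV"))
  expect_equal(sum(fwd$variant_type == "insertion"),
               sum(rev$variant_type == "deletion"))
  expect_equal(sum(fwd$variant_type == "deletion"),
               sum(rev$variant_type == "insertion"))
  expect_equal(fwd$snv_class[fwd$variant_type == "SNV"],
               rev$snv_class[rev$variant_type == "SNV"])
  ## transitions + transversions always partition the SNVs
  expect_equal(sum(fwd$snv_class %in% c("transition", "transversion")),
               sum(fwd$variant_type == "SNV"))
})

test_that("planted variants are recovered exactly on random pairs", {
  set.seed(94)
  for (rep in 1:25) {
    s <- random_dna(3000)
    pl <- plant_variants(s, n_snv = sample(2:8, 1), n_ins = sample(0:2, 1),
                         n_del = sample(0:2, 1), seed = 1000L + rep,
                         indel_max_len = 2L)
    v <- call_variants(align_plastomes(s, pl$query))
    expect_equal(v[, c("position", "variant_type", "ref_allele",
                       "alt_allele")],
                 pl$truth[, c("position", "variant_type", "ref_allele",
                              "alt_allele")],
                 ignore_attr = TRUE, info = rep)
  }
})

test_that("the anchored long-sequence path agrees with planted truth", {
  set.seed(95)
  s <- random_dna(40000)
  pl <- plant_variants(s, n_snv = 12L, n_ins = 3L, n_del = 3L, seed = 55L,
                       indel_max_len = 2L)
  v <- call_variants(align_plastomes(s, pl$query))
  expect_equal(v[, c("position", "variant_type", "ref_allele", "alt_allele")],
               pl$truth[, c("position", "variant_type", "ref_allele",
                            "alt_allele")],
               ignore_attr = TRUE)
})

test_that("alignment cost is optimal under the affine scoring on tiny pairs", {
  set.seed(96)
  for (rep in 1:10) {
    s <- random_dna(sample(250:320, 1))
    pl <- plant_variants(s, n_snv = 2L, n_ins = 1L, n_del = 1L,
                         seed = 2000L + rep, indel_max_len = 2L)
    aln <- align_plastomes(s, pl$query)
    expect_equal(alignment_cost(aln), oracle_gotoh_cost(s, pl$query),
                 info = rep)
  }
})

test_that("length mismatch beyond 5% is rejected with guidance", {
  expect_error(align_plastomes(random_dna(1000), random_dna(1500)),
               "rotation")
})

test_that("heteroplasmy verdicts: maternal, mixed, inconclusive", {
  set.seed(97)
  cfg_m <- plastome_config(ir_length = 300L, lsc_length = 1600L,
                           ssc_length = 800L, ssr_spec = NULL,
                           gene_spec = NULL, error_rate = 0, seed = 41L)
  maternal <- build_plastome(cfg_m)
  ## paternal genome differs by SNVs only, so reads map at identical
  ## coordinates on the maternal reference
  pl <- plant_variants(maternal$plastome$seq, n_snv = 10L, n_ins = 0L,
                       n_del = 0L, seed = 42L)
  paternal <- annotated_plastome(pl$query, name = maternal$plastome$name)
  variants <- call_variants(align_plastomes(maternal$plastome$seq, pl$query))

  sim <- function(genome, n, seed) {
    simulate_reads(genome, maternal$truth, n_reads = n, read_length = 60L,
                   seed = seed)
  }
  pu_m <- build_pileup(sim(maternal$plastome, 12000L, 1L),
                       maternal$plastome)
  res_m <- assess_heteroplasmy(variants, pu_m, min_depth = 100L)
  expect_equal(res_m$verdict, "maternal")
  expect_true(all(res_m$per_variant$maternal_fraction == 1))

  mixed_aln <- rbind(sim(maternal$plastome, 6000L, 2L),
                     sim(paternal, 6000L, 3L))
  attr(mixed_aln, "rname") <- maternal$plastome$name
  attr(mixed_aln, "rlength") <- maternal$plastome$length
  pu_mix <- build_pileup(mixed_aln, maternal$plastome)
  res_mix <- assess_heteroplasmy(variants, pu_mix, min_depth = 100L)
  expect_equal(res_mix$verdict, "mixed")
  frac <- res_mix$per_variant$maternal_fraction
  expect_true(all(abs(frac - 0.5) < 0.15))

  shallow <- assess_heteroplasmy(variants, pu_m, min_depth = 10^6)
  expect_equal(shallow$verdict, "inconclusive")
  empty <- assess_heteroplasmy(variants[0, ], pu_m)
  expect_equal(empty$verdict, "inconclusive")
})
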