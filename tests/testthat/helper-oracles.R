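# Independent oracles and small fixture builders shared across tests. Each
# oracle is a deliberately naive implementation kept separate from the code
# path it checks.

## brute-force maximal-run enumerator (linear sequences): for every start,
## extend the candidate motif as far as possible; O(n * L)
oracle_find_runs <- function(s, min_len = 8L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- list()
  ## mononucleotide
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
    if (j - i + 1L >= min_len && ch[i] %in% c("A", "C", "G", "T")) {
      out[[length(out) + 1L]] <- data.frame(motif = ch[i], start = i,
                                            total_length = j - i + 1L)
    }
    i <- j + 1L
  }
  ## dinucleotide (full units, leftmost phase, skipping homopolymer pairs)
  i <- 1L
  while (i <= n - 1L) {
    if (ch[i] != ch[i + 1L] && all(ch[c(i, i + 1L)] %in% c("A", "C", "G", "T"))) {
      j <- i + 1L
      while (j < n && ch[j + 1L] == ch[j - 1L]) j <- j + 1L
      stretch <- j - i + 1L
      total <- 2L * (stretch %/% 2L)
      left_ext <- i > 1L && ch[i - 1L] == ch[i + 1L]
      if (total >= min_len && !left_ext) {
        out[[length(out) + 1L]] <- data.frame(
          motif = paste0(ch[i], ch[i + 1L]), start = i, total_length = total)
      }
      if (total >= min_len) { i <- j; next }
    }
    i <- i + 1L
  }
  if (!length(out)) {
    return(data.frame(motif = character(), start = integer(),
                      total_length = integer()))
  }
  d <- do.call(rbind, out)
  d[order(d$start, nchar(d$motif)), , drop = FALSE]
}

## naive per-read pileup replay: nested loops over reads and CIGAR ops
oracle_replay_pileup <- function(aln, L, min_mapq = 20L) {
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  for (i in seq_len(nrow(aln))) {
    if (aln$mapq[i] < min_mapq) next
    cig <- aln$cigar[i]
    m <- gregexpr("\\d+[A-Z=]", cig)[[1]]
    toks <- regmatches(cig, list(m))[[1]]
    ref <- aln$pos[i]; q <- 1L
    for (t in toks) {
      len <- as.integer(substr(t, 1L, nchar(t) - 1L))
      op <- substr(t, nchar(t), nchar(t))
      if (op %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          b <- substr(aln$seq[i], q, q)
          if (b %in% c("A", "C", "G", "T")) {
            counts[ref, b] <- counts[ref, b] + 1L
          }
          ref <- ref + 1L; q <- q + 1L
        }
      } else if (op == "I") {
        q <- q + len
      } else if (op == "S") {
        q <- q + len
      } else if (op == "D") {
        for (k in seq_len(len)) {
          counts[ref, "del"] <- counts[ref, "del"] + 1L
          ref <- ref + 1L
        }
      } else if (op == "N") {
        ref <- ref + len
      }
    }
  }
  counts
}

## independent translation via seqinr (the standard and bacterial/plastid
## tables agree on all 64 codon -> amino acid mappings)
oracle_translate <- function(dna) {
  paste(seqinr::translate(seqinr::s2c(dna)), collapse = "")
}

## naive indel-consequence oracle: mutate, splice, translate, compare
oracle_indel_consequence <- function(genome_seq, gene, indel, edit_sites = NULL) {
  s <- genome_seq
  if (!is.null(edit_sites) && nrow(edit_sites)) {
    for (k in seq_len(nrow(edit_sites))) {
      substr(s, edit_sites$position[k], edit_sites$position[k]) <-
        if (edit_sites$strand[k] == "+") "T" else "A"
    }
  }
  apply_mut <- function(seq) {
    if (indel$type == "none") return(seq)
    p <- indel$position
    if (indel$type == "insertion") {
      paste0(substr(seq, 1L, p - 1L), indel$base, substr(seq, p, nchar(seq)))
    } else {
      paste0(substr(seq, 1L, p - 1L), substr(seq, p + 1L, nchar(seq)))
    }
  }
  tx_from <- function(seq) {
    if (gene$strand == "+") {
      substr(seq, gene$span[1L], nchar(seq))
    } else {
      end <- gene$span[2L] + if (indel$type == "insertion") 1L else
        if (indel$type == "deletion") -1L else 0L
      end <- if (gene$strand == "-" && indel$type != "none" &&
                 indel$position > gene$span[2L]) gene$span[2L] else end
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(substr(seq, 1L, end), "", fixed = TRUE)[[1]]),
                   collapse = ""))
    }
  }
  prot <- function(tx) {
    n <- nchar(tx) - nchar(tx) %% 3L
    aa <- oracle_translate(substr(tx, 1L, n))
    aa <- sub("^.", "M", aa)
    stop_i <- regexpr("*", aa, fixed = TRUE)
    if (stop_i < 0L) aa else substr(aa, 1L, stop_i - 1L)
  }
  ref_prot <- prot(tx_from(s))
  mut_prot <- prot(tx_from(apply_mut(s)))
  shared <- 0L
  while (shared < min(nchar(ref_prot), nchar(mut_prot)) &&
         substr(ref_prot, shared + 1L, shared + 1L) ==
         substr(mut_prot, shared + 1L, shared + 1L)) {
    shared <- shared + 1L
  }
  list(protein_length = nchar(mut_prot), shared_n_terminal = shared,
       protein = mut_prot, reference_protein = ref_prot)
}

## Gotoh global alignment cost (mismatch 1, gap open 2, gap extend 1);
## returns the optimal cost for tiny sequences
oracle_gotoh_cost <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  INF <- 1e9
  M <- matrix(INF, n + 1L, m + 1L)
  X <- matrix(INF, n + 1L, m + 1L)  # gap in b (deletion from a)
  Y <- matrix(INF, n + 1L, m + 1L)  # gap in a (insertion)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- 2 + (i - 1L)
  for (j in 2L:(m + 1L)) Y[1L, j] <- 2 + (j - 1L)
  for (i in 1L:(n + 1L)) {
    for (j in 1L:(m + 1L)) {
      if (i > 1L && j > 1L) {
        sub <- if (av[i - 1L] == bv[j - 1L]) 0 else 1
        M[i, j] <- min(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                       Y[i - 1L, j - 1L]) + sub
      }
      if (i > 1L) {
        X[i, j] <- min(X[i, j], min(M[i - 1L, j], Y[i - 1L, j]) + 3,
                       X[i - 1L, j] + 1)
      }
      if (j > 1L) {
        Y[i, j] <- min(Y[i, j], min(M[i, j - 1L], X[i, j - 1L]) + 3,
                       Y[i, j - 1L] + 1)
      }
    }
  }
  min(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## cost of a gapped alignment under the same scoring
alignment_cost <- function(aln) {
  ra <- strsplit(aln$ref, "", fixed = TRUE)[[1]]
  qa <- strsplit(aln$query, "", fixed = TRUE)[[1]]
  state <- ifelse(ra == "-", "ins", ifelse(qa == "-", "del",
                  ifelse(ra == qa, "m", "x")))
  cost <- sum(state == "x")
  r <- rle(state)
  gaps <- r$lengths[r$values %in% c("ins", "del")]
  cost + sum(2 + gaps)
}

## small plastome + truth for reuse in pileup/editing/slippage tests
toy_plastome <- function(seed = 11L, level = 0.8, slip9 = 0.15) {
  cfg <- plastome_config(
    ir_length = 150L, lsc_length = 900L, ssc_length = 300L,
    ssr_spec = data.frame(motif_base = "A", run_length = 9L, count = 1L),
    gene_spec = data.frame(name = c("gPlus", "gMinus"),
                           strand = c("+", "-"), cds_length = c(240L, 180L)),
    editing_spec = data.frame(gene = c("gPlus", "gMinus"),
                              level = c(level, level)),
    slip_model = function(L) rep(slip9, length(L)),
    error_rate = 0,
    seed = seed)
  build_plastome(cfg)
}

## plant substitutions/indels into a sequence, returning the mutated string
## and the expected left-normalized variant table
plant_variants <- function(seq, n_snv, n_ins, n_del, seed,
                           indel_max_len = 1L) {
  set.seed(seed)
  L <- nchar(seq)
  ## keep variants well separated so events cannot interact
  pos <- sort(sample(seq.int(50L, L - 50L), n_snv + n_ins + n_del))
  while (any(diff(pos) < 40L)) {
    pos <- sort(sample(seq.int(50L, L - 50L), n_snv + n_ins + n_del))
  }
  kind <- sample(rep(c("SNV", "insertion", "deletion"),
                     c(n_snv, n_ins, n_del)))
  records <- vector("list", length(pos))
  ## apply right-to-left so earlier coordinates stay valid
  q <- seq
  for (k in rev(seq_along(pos))) {
    p <- pos[k]
    if (kind[k] == "SNV") {
      ref <- substr(seq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      substr(q, p, p) <- alt
      records[[k]] <- data.frame(position = p, variant_type = "SNV",
                                 ref_allele = ref, alt_allele = alt,
                                 length = 1L)
    } else if (kind[k] == "insertion") {
      len <- sample.int(indel_max_len, 1L)
      bases <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
      q <- paste0(substr(q, 1L, p - 1L), bases, substr(q, p, nchar(q)))
      norm <- left_normalize_indel(list(position = p, type = "insertion",
                                        bases = bases), seq)
      records[[k]] <- data.frame(position = norm$position,
                                 variant_type = "insertion",
                                 ref_allele = "", alt_allele = norm$bases,
                                 length = len)
    } else {
      len <- sample.int(indel_max_len, 1L)
      bases <- substr(seq, p, p + len - 1L)
      q <- paste0(substr(q, 1L, p - 1L), substr(q, p + len, nchar(q)))
      norm <- left_normalize_indel(list(position = p, type = "deletion",
                                        bases = bases), seq)
      records[[k]] <- data.frame(position = norm$position,
                                 variant_type = "deletion",
                                 ref_allele = norm$bases, alt_allele = "",
                                 length = len)
    }
  }
  truth <- do.call(rbind, records)
  truth <- truth[order(truth$position, truth$variant_type), , drop = FALSE]
  rownames(truth) <- NULL
  list(query = q, truth = truth)
}

extdata <- function(f) system.file("extdata", f, package = "chloroslip")
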