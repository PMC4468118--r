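# Pairwise comparison of near-identical plastomes: end-to-end alignment,
# SNV/indel calling with transition/transversion classification, and
# heteroplasmy assessment of an offspring against parent-distinguishing
# variants.

## unit-mismatch / affine-gap scoring shared by the direct and anchored
## aligners: match 0, mismatch -1, gap open 2, gap extend 1 (a gap of length
## n costs 2 + n), which prefers one 2-bp gap over two 1-bp gaps
.align_pair <- function(a, b) {
  if (a == b) return(list(ref = a, query = b))
  if (nchar(a) == 0L) return(list(ref = strrep("-", nchar(b)), query = b))
  if (nchar(b) == 0L) return(list(ref = a, query = strrep("-", nchar(a))))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  list(ref = as.character(Biostrings::alignedPattern(pa)),
       query = as.character(Biostrings::alignedSubject(pa)))
}

## collinear unique shared k-mer anchors between two near-identical sequences
.find_anchors <- function(ref, query, k = 31L, min_spacing = 500L) {
  ir <- seq_len(nchar(ref) - k + 1L)
  iq <- seq_len(nchar(query) - k + 1L)
  dr <- data.table::data.table(kmer = substring(ref, ir, ir + k - 1L), i = ir)
  dq <- data.table::data.table(kmer = substring(query, iq, iq + k - 1L), j = iq)
  dr <- dr[, if (.N == 1L) .SD, by = "kmer"]
  dq <- dq[, if (.N == 1L) .SD, by = "kmer"]
  an <- merge(dr, dq, by = "kmer")
  data.table::setorder(an, i)
  if (nrow(an) == 0L) return(an)
  ## longest increasing subsequence over j enforces collinearity
  j <- an$j
  n <- length(j)
  tails <- integer(0); tails_idx <- integer(0); prev <- integer(n)
  for (t in seq_len(n)) {
    p <- findInterval(j[t] - 1L, tails) + 1L
    tails[p] <- j[t]; tails_idx[p] <- t
    if (length(tails) > p) length(tails) <- p
    prev[t] <- if (p > 1L) tails_idx[p - 1L] else 0L
  }
  sel <- integer(0); t <- tails_idx[length(tails_idx)]
  while (t > 0L) { sel <- c(t, sel); t <- prev[t] }
  an <- an[sel]
  ## thin to the requested spacing
  keep <- logical(nrow(an)); last <- -Inf
  for (t in seq_len(nrow(an))) {
    if (an$i[t] - last >= min_spacing) { keep[t] <- TRUE; last <- an$i[t] }
  }
  keep[nrow(an)] <- TRUE
  an[keep]
}

#' Globally align two near-identical plastomes
#'
#' Produces an end-to-end alignment under unit mismatch / affine gap scoring
#' (mismatch 1, gap open 2, gap extend 1). Short sequence pairs are aligned
#' directly with Needleman-Wunsch; long pairs are aligned by anchoring on
#' collinear unique shared 31-mers and aligning the inter-anchor segments,
#' which is exact for isolated variants between anchors. Sequences must be in
#' the same orientation and rotation and within 5% of each other's length.
#'
#' @param ref,query Sequences (character scalars or `annotated_plastome`s).
#' @param direct_max Maximum length for direct dynamic-programming alignment
#'   (default 3000 bp).
#' @return List of class `plastome_alignment` with gapped strings `ref` and
#'   `query` of equal length.
#' @export
align_plastomes <- function(ref, query, direct_max = 3000L) {
  a <- if (inherits(ref, "annotated_plastome")) ref$seq else ref
  b <- if (inherits(query, "annotated_plastome")) query$seq else query
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > 0.05 * max(la, lb)) {
    stop("sequence lengths differ by more than 5%; check rotation and ",
         "orientation of the two plastomes")
  }
  if (max(la, lb) <= direct_max) {
    aln <- .align_pair(a, b)
  } else {
    an <- .find_anchors(a, b)
    if (nrow(an) == 0L) stop("no alignment anchors found; are the sequences ",
                             "from the same genome and rotation?")
    ra <- character(0); rb <- character(0)
    prev_i <- 1L; prev_j <- 1L
    for (t in seq_len(nrow(an))) {
      seg <- .align_pair(substr(a, prev_i, an$i[t] - 1L),
                         substr(b, prev_j, an$j[t] - 1L))
      ra <- c(ra, seg$ref); rb <- c(rb, seg$query)
      prev_i <- an$i[t]; prev_j <- an$j[t]
    }
    seg <- .align_pair(substr(a, prev_i, la), substr(b, prev_j, lb))
    ra <- c(ra, seg$ref); rb <- c(rb, seg$query)
    aln <- list(ref = paste(ra, collapse = ""),
                query = paste(rb, collapse = ""))
  }
  structure(list(ref = aln$ref, query = aln$query),
            class = "plastome_alignment")
}

#' Call SNVs and indels from a plastome alignment
#'
#' Walks the alignment columns: mismatch columns become SNVs (classified as
#' transition for A<->G / C<->T, else transversion); runs of adjacent gap
#' columns merge into single indel events, which are left-normalized in
#' homopolymer context against the reference.
#'
#' @param alignment A `plastome_alignment` from [align_plastomes()].
#' @return `data.frame` of class records: `position` (1-based reference
#'   coordinate; for insertions, the reference base the insertion precedes),
#'   `variant_type` (`SNV`/`insertion`/`deletion`), `ref_allele`,
#'   `alt_allele`, `length`, `snv_class` (`transition`/`transversion`/`NA`).
#' @export
call_variants <- function(alignment) {
  ra <- strsplit(alignment$ref, "", fixed = TRUE)[[1]]
  qa <- strsplit(alignment$query, "", fixed = TRUE)[[1]]
  stopifnot(length(ra) == length(qa))
  refseq <- paste(ra[ra != "-"], collapse = "")
  refpos <- cumsum(ra != "-")

  empty <- data.frame(position = integer(), variant_type = character(),
                      ref_allele = character(), alt_allele = character(),
                      length = integer(), snv_class = character(),
                      stringsAsFactors = FALSE)
  state <- ifelse(ra == "-", "ins", ifelse(qa == "-", "del",
                  ifelse(ra == qa, "match", "snv")))
  out <- list()

  snv_i <- which(state == "snv")
  if (length(snv_i)) {
    ts <- paste0(ra[snv_i], qa[snv_i]) %in% c("AG", "GA", "CT", "TC")
    out[[1L]] <- data.frame(
      position = refpos[snv_i], variant_type = "SNV",
      ref_allele = ra[snv_i], alt_allele = qa[snv_i], length = 1L,
      snv_class = ifelse(ts, "transition", "transversion"),
      stringsAsFactors = FALSE)
  }

  gap <- state %in% c("ins", "del")
  if (any(gap)) {
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values %in% c("ins", "del"))) {
      cols <- seq.int(starts[k], ends[k])
      if (r$values[k] == "ins") {
        bases <- paste(qa[cols], collapse = "")
        pos <- refpos[cols[1L]] + 1L   # insertion precedes this ref base
        norm <- left_normalize_indel(list(position = pos, type = "insertion",
                                          bases = bases), refseq)
        out[[length(out) + 1L]] <- data.frame(
          position = norm$position, variant_type = "insertion",
          ref_allele = "", alt_allele = norm$bases,
          length = nchar(bases), snv_class = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        bases <- paste(ra[cols], collapse = "")
        pos <- refpos[cols[1L]]
        norm <- left_normalize_indel(list(position = pos, type = "deletion",
                                          bases = bases), refseq)
        out[[length(out) + 1L]] <- data.frame(
          position = norm$position, variant_type = "deletion",
          ref_allele = norm$bases, alt_allele = "",
          length = nchar(bases), snv_class = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$variant_type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assess heteroplasmy / paternal leakage in an offspring pileup
#'
#' For each parent-distinguishing variant, computes the fraction of offspring
#' reads supporting the maternal (reference) allele versus the paternal
#' (alternate) allele. The verdict is `maternal` iff every adequately covered
#' variant shows a maternal fraction of at least `1 - minor_fraction`,
#' `paternal` for the mirror case, `mixed` if any site shows both parental
#' alleles above `minor_fraction`, and `inconclusive` when no variant is
#' adequately covered (or the variant list is empty).
#'
#' @param variants Variant `data.frame` from [call_variants()], with the
#'   maternal genome as reference and the paternal as query.
#' @param offspring_pileup A `site_pileup` of offspring reads aligned to the
#'   maternal reference.
#' @param min_depth Minimum depth for a variant to count (default 1000,
#'   appropriate for deep organellar sequencing; lower it for shallow data).
#' @param minor_fraction Minor-allele fraction above which an allele is
#'   considered present (default 0.01).
#' @return List of class `heteroplasmy_assessment`: `per_variant`
#'   (`data.frame` with `position`, `variant_type`, `maternal_allele`,
#'   `paternal_allele`, `maternal_fraction`, `depth`, `assessed`), `verdict`,
#'   `note`.
#' @export
assess_heteroplasmy <- function(variants, offspring_pileup, min_depth = 1000L,
                                minor_fraction = 0.01) {
  if (is.null(variants) || nrow(variants) == 0L) {
    return(structure(list(per_variant = NULL, verdict = "inconclusive",
                          note = "no parent-distinguishing variants supplied"),
                     class = "heteroplasmy_assessment"))
  }
  cn <- offspring_pileup$counts
  ins <- offspring_pileup$insertions
  rows <- vector("list", nrow(variants))
  for (k in seq_len(nrow(variants))) {
    v <- variants[k, ]
    if (v$variant_type == "SNV") {
      m <- cn[v$position, v$ref_allele]
      p <- cn[v$position, v$alt_allele]
    } else if (v$variant_type == "deletion") {
      p <- cn[v$position, "del"]
      m <- sum(cn[v$position, c("A", "C", "G", "T")])
    } else {                     # insertion relative to maternal reference
      p <- sum(ins$count[ins$position == v$position &
                         ins$inserted == v$alt_allele])
      m <- max(sum(cn[v$position, c("A", "C", "G", "T")]) - p, 0L)
    }
    depth <- m + p
    rows[[k]] <- data.frame(
      position = v$position, variant_type = v$variant_type,
      maternal_allele = v$ref_allele, paternal_allele = v$alt_allele,
      maternal_fraction = if (depth > 0L) m / depth else NA_real_,
      depth = depth, assessed = depth >= min_depth,
      stringsAsFactors = FALSE)
  }
  pv <- do.call(rbind, rows)
  ok <- pv[pv$assessed, , drop = FALSE]
  if (nrow(ok) == 0L) {
    verdict <- "inconclusive"
    note <- "no variant position reached min_depth"
  } else if (any(ok$maternal_fraction > minor_fraction &
                 1 - ok$maternal_fraction > minor_fraction)) {
    verdict <- "mixed"
    note <- "both parental alleles present above minor_fraction"
  } else if (all(ok$maternal_fraction >= 1 - minor_fraction)) {
    verdict <- "maternal"
    note <- "all assessed variants carry the maternal allele"
  } else if (all(ok$maternal_fraction <= minor_fraction)) {
    verdict <- "paternal"
    note <- "all assessed variants carry the paternal allele"
  } else {
    verdict <- "mixed"
    note <- "variants disagree on the parental origin"
  }
  structure(list(per_variant = pv, verdict = verdict, note = note),
            class = "heteroplasmy_assessment")
}

#' Write variants as a minimal VCF 4.2
#'
#' Indels are emitted in the padded VCF convention (anchor base prepended)
#' with left-normalized positions.
#'
#' @param variants Variant `data.frame` from [call_variants()].
#' @param ref Reference sequence (character scalar or `annotated_plastome`).
#' @param path Output path.
#' @param chrom Chromosome name (default the plastome name or "plastome").
#' @export
write_vcf <- function(variants, ref, path, chrom = NULL) {
  seq <- if (inherits(ref, "annotated_plastome")) ref$seq else ref
  if (is.null(chrom)) {
    chrom <- if (inherits(ref, "annotated_plastome")) ref$name else "plastome"
  }
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ",length=", nchar(seq), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(nrow(variants))
  for (k in seq_len(nrow(variants))) {
    v <- variants[k, ]
    if (v$variant_type == "SNV") {
      pos <- v$position; refa <- v$ref_allele; alta <- v$alt_allele
    } else if (v$variant_type == "deletion") {
      pos <- v$position - 1L
      anchor <- substr(seq, pos, pos)
      refa <- paste0(anchor, v$ref_allele); alta <- anchor
    } else {
      pos <- v$position - 1L
      anchor <- substr(seq, pos, pos)
      refa <- anchor; alta <- paste0(anchor, v$alt_allele)
    }
    lines[k] <- paste(chrom, pos, ".", refa, alta, ".", "PASS", ".",
                      sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
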