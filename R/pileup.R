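# Pileup engine: converts aligned reads into per-site base counts and
# per-SSR indel/spanning tallies. This is the shared substrate for the
# editing caller and the slippage statistics.

.CIGAR_OPS <- c("M", "I", "D", "N", "S", "=", "X")

## parse one CIGAR into parallel op/len vectors
.parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  list(len = as.integer(substr(tok, 1L, nchar(tok) - 1L)),
       op = substr(tok, nchar(tok), nchar(tok)))
}

## reference span length consumed by each CIGAR (vectorized over reads)
.cigar_ref_len <- function(cigars) {
  m <- gregexpr("\\d+(?=[MDN=X])", cigars, perl = TRUE)
  vapply(regmatches(cigars, m), function(x) sum(as.integer(x)),
         integer(1L), USE.NAMES = FALSE)
}

## extract indel events from one aligned read: data.frame of
## type (insertion/deletion), position (first deleted base, or the base the
## insertion precedes), bases
.read_indels <- function(pos, cigar, seq, genome) {
  ops <- .parse_cigar(cigar)
  out <- list()
  ref <- pos; qoff <- 1L
  for (k in seq_along(ops$op)) {
    n <- ops$len[k]
    op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      ref <- ref + n; qoff <- qoff + n
    } else if (op == "I") {
      out[[length(out) + 1L]] <- data.frame(
        type = "insertion", position = ref,
        bases = substr(seq, qoff, qoff + n - 1L), stringsAsFactors = FALSE)
      qoff <- qoff + n
    } else if (op == "D") {
      out[[length(out) + 1L]] <- data.frame(
        type = "deletion", position = ref,
        bases = substr(genome, ref, ref + n - 1L), stringsAsFactors = FALSE)
      ref <- ref + n
    } else if (op == "N") {
      ref <- ref + n
    } else if (op == "S") {
      qoff <- qoff + n
    } else {
      stop("unsupported CIGAR op '", op, "'")
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Build a per-position pileup from aligned reads
#'
#' Every aligned, quality-passing base contributes exactly one count; each
#' deleted reference position receives a deletion count; insertions are
#' recorded at the reference position they precede. Reads failing the
#' mapping-quality filter are excluded entirely. `N` (splice) operations are
#' treated as coverage gaps. Supported CIGAR operations: M/=/X/I/D/S/N.
#'
#' @param aln Alignment `data.frame` from [read_sam()] or [simulate_reads()].
#' @param genome An `annotated_plastome` (or plain sequence string) the reads
#'   were aligned to; the SAM reference name and length must match.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param min_baseq Minimum base quality (default 13; `*` quality strings are
#'   not filtered).
#' @return A list of class `site_pileup`: `counts`, an L x 5 integer matrix
#'   with columns A, C, G, T, del; `insertions`, a `data.frame` of
#'   `position` (the base the insertion precedes), `inserted`, `count`; and
#'   `depth`, the per-position row sum of `counts`.
#' @export
build_pileup <- function(aln, genome, min_mapq = 20L, min_baseq = 13L) {
  seq <- if (inherits(genome, "annotated_plastome")) genome$seq else genome
  gname <- if (inherits(genome, "annotated_plastome")) genome$name else NULL
  L <- nchar(seq)
  rn <- attr(aln, "rname")
  if (!is.null(rn) && !is.na(rn) && !is.null(gname) && rn != gname) {
    stop("SAM reference '", rn, "' does not match genome '", gname, "'")
  }
  rl <- attr(aln, "rlength")
  if (!is.null(rl) && !is.na(rl) && rl != L) {
    stop("SAM reference length ", rl, " does not match genome length ", L)
  }
  bad_op <- grepl("[HP]", aln$cigar)
  if (any(bad_op)) {
    stop("unsupported CIGAR op in read ", aln$qname[which(bad_op)[1L]])
  }

  keep <- aln$mapq >= min_mapq & bitwAnd(aln$flag, 4L) == 0L
  aln <- aln[keep, , drop = FALSE]

  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  ins_acc <- list()

  if (nrow(aln)) {
    simple <- grepl("^\\d+M$", aln$cigar)

    ## fast path: pure-match reads, bulk-expanded
    if (any(simple)) {
      bulk <- function(sa, apply_q) {
        lens <- nchar(sa$seq)
        pos <- sequence(lens, from = sa$pos)
        base <- unlist(strsplit(sa$seq, "", fixed = TRUE), use.names = FALSE)
        ok <- rep.int(TRUE, length(pos))
        if (apply_q) {
          qv <- utf8ToInt(paste(sa$qual, collapse = "")) - 33L
          ok <- qv >= min_baseq
        }
        code <- match(base, BASES)
        use <- ok & !is.na(code) & pos >= 1L & pos <= L
        tabulate((pos[use] - 1L) * 5L + code[use], nbins = 5L * L)
      }
      sa <- aln[simple, , drop = FALSE]
      has_q <- sa$qual != "*" & min_baseq > 0L
      tab <- integer(5L * L)
      if (any(!has_q)) tab <- tab + bulk(sa[!has_q, , drop = FALSE], FALSE)
      if (any(has_q)) tab <- tab + bulk(sa[has_q, , drop = FALSE], TRUE)
      counts <- counts + matrix(tab, nrow = L, ncol = 5L, byrow = TRUE)
    }

    ## general path: reads with indels / clips / splices
    for (i in which(!simple)) {
      ops <- .parse_cigar(aln$cigar[i])
      ref <- aln$pos[i]; qoff <- 1L
      sq <- aln$seq[i]; ql <- aln$qual[i]
      for (k in seq_along(ops$op)) {
        n <- ops$len[k]; op <- ops$op[k]
        if (op %in% c("M", "=", "X")) {
          p <- seq.int(ref, ref + n - 1L)
          b <- substring(sq, qoff:(qoff + n - 1L), qoff:(qoff + n - 1L))
          okq <- rep.int(TRUE, n)
          if (ql != "*" && min_baseq > 0L) {
            okq <- (utf8ToInt(substr(ql, qoff, qoff + n - 1L)) - 33L) >= min_baseq
          }
          code <- match(b, BASES)
          use <- okq & !is.na(code) & p <= L
          for (j in which(use)) {
            counts[p[j], code[j]] <- counts[p[j], code[j]] + 1L
          }
          ref <- ref + n; qoff <- qoff + n
        } else if (op == "I") {
          ins_acc[[length(ins_acc) + 1L]] <- data.frame(
            position = ref, inserted = substr(sq, qoff, qoff + n - 1L),
            stringsAsFactors = FALSE)
          qoff <- qoff + n
        } else if (op == "D") {
          p <- seq.int(ref, min(ref + n - 1L, L))
          counts[p, 5L] <- counts[p, 5L] + 1L
          ref <- ref + n
        } else if (op == "N") {
          ref <- ref + n
        } else if (op == "S") {
          qoff <- qoff + n
        }
      }
    }
  }

  insertions <- if (length(ins_acc)) {
    d <- do.call(rbind, ins_acc)
    agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                            by = d[, c("position", "inserted")], FUN = sum)
    agg[order(agg$position), , drop = FALSE]
  } else {
    data.frame(position = integer(), inserted = character(), count = integer())
  }

  structure(list(counts = counts, insertions = insertions,
                 depth = as.integer(rowSums(counts))),
            class = "site_pileup")
}

#' @export
print.site_pileup <- function(x, ...) {
  cov <- sum(x$depth > 0L)
  cat("site_pileup: ", nrow(x$counts), " positions, ", cov,
      " covered, max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Pileup as a per-site data frame
#'
#' @param x A `site_pileup`.
#' @param covered_only Drop zero-depth positions (default `TRUE`).
#' @param ... Unused.
#' @return `data.frame` with `position`, `depth`, `A`, `C`, `G`, `T`, `del`.
#' @export
as.data.frame.site_pileup <- function(x, covered_only = TRUE, ...) {
  df <- data.frame(position = seq_len(nrow(x$counts)), depth = x$depth,
                   x$counts)
  if (covered_only) df <- df[df$depth > 0L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Left-normalize an indel in homopolymer context
#'
#' Shifts a same-base indel to the leftmost equivalent position of its
#' homopolymer run: a deletion's position becomes the first base of the run
#' containing it; an insertion's position (the base it precedes) becomes the
#' run start whenever the inserted bases extend a run they touch. The
#' operation is idempotent and never shifts right. Multi-base alleles are
#' rotated through the standard prefix-shift.
#'
#' @param indel List or one-row `data.frame` with `position`, `type`
#'   (`"insertion"`/`"deletion"`), `bases`.
#' @param genome An `annotated_plastome` or sequence string.
#' @return The indel with a (possibly) smaller `position` and rotated `bases`.
#' @export
left_normalize_indel <- function(indel, genome) {
  seq <- if (inherits(genome, "annotated_plastome")) genome$seq else genome
  p <- as.integer(indel$position)
  bases <- as.character(indel$bases)
  len <- nchar(bases)
  while (p > 1L) {
    prev <- substr(seq, p - 1L, p - 1L)
    if (prev != substr(bases, len, len)) break
    bases <- paste0(prev, substr(bases, 1L, len - 1L))
    p <- p - 1L
  }
  list(position = p, type = as.character(indel$type), bases = bases)
}

#' Tally spanning and slippage-indel reads per SSR locus
#'
#' A read spans a locus iff it covers the full run plus `min_anchor` non-run
#' bases on each side. A spanning read is an indel read for the locus iff it
#' carries at least one indel whose left-normalized position falls within
#' `[run_start - 1, run_end]` and whose bases match the run motif; indels of
#' other bases inside the window are tallied separately as `other_indel_reads`
#' and never attributed to transcriptional slippage. Reads are counted once
#' per locus regardless of how many indels they carry, classified by the net
#' length change (insertion if positive, deletion if negative; a net of zero
#' leaves the read out of `indel_reads` but in the net-length histogram).
#'
#' @param aln Alignment `data.frame`.
#' @param loci SSR loci from [find_ssrs()] on the same genome.
#' @param genome `annotated_plastome` or sequence string.
#' @param min_anchor Non-run anchor bases required on each side (default 1).
#' @param min_mapq Minimum mapping quality (default 20).
#' @return A list of class `locus_tally`: `tallies`, a `data.frame` with
#'   `ssr_id`, `spanning_reads`, `indel_reads`, `insertion_reads`,
#'   `deletion_reads`, `other_indel_reads`; and `net`, a long `data.frame`
#'   (`ssr_id`, `delta`, `reads`) holding the net-length histograms.
#' @export
scan_ssr_indels <- function(aln, loci, genome, min_anchor = 1L,
                            min_mapq = 20L) {
  seq <- if (inherits(genome, "annotated_plastome")) genome$seq else genome
  L <- nchar(seq)
  if (nrow(loci) && any(loci$start < 1L |
                        loci$start + loci$total_length - 1L > L + L)) {
    stop("locus outside genome")
  }
  aln <- aln[aln$mapq >= min_mapq & bitwAnd(aln$flag, 4L) == 0L, , drop = FALSE]
  ref_end <- if (nrow(aln)) aln$pos + .cigar_ref_len(aln$cigar) - 1L else integer(0)

  has_indel <- grepl("[ID]", aln$cigar)
  indels <- vector("list", nrow(aln))
  for (i in which(has_indel)) {
    ev <- .read_indels(aln$pos[i], aln$cigar[i], aln$seq[i], seq)
    if (!is.null(ev)) {
      norm <- lapply(seq_len(nrow(ev)), function(k) {
        left_normalize_indel(ev[k, ], seq)
      })
      ev$position <- vapply(norm, `[[`, integer(1L), "position")
      ev$bases <- vapply(norm, `[[`, character(1L), "bases")
      indels[[i]] <- ev
    }
  }

  tallies <- vector("list", nrow(loci))
  nets <- vector("list", nrow(loci))
  for (r in seq_len(nrow(loci))) {
    rs <- loci$start[r]
    re <- rs + loci$total_length[r] - 1L   # linear end (wrapping loci skipped)
    if (loci$wraps_origin[r]) {
      tallies[[r]] <- data.frame(ssr_id = loci$ssr_id[r], spanning_reads = NA_integer_,
                                 indel_reads = NA_integer_, insertion_reads = NA_integer_,
                                 deletion_reads = NA_integer_, other_indel_reads = NA_integer_)
      next
    }
    motif <- loci$motif[r]
    span <- which(aln$pos <= rs - min_anchor & ref_end >= re + min_anchor)
    delta <- integer(length(span))
    other <- logical(length(span))
    for (k in seq_along(span)) {
      ev <- indels[[span[k]]]
      if (is.null(ev)) next
      inwin <- ev$position >= rs - 1L & ev$position <= re
      if (!any(inwin)) next
      ev <- ev[inwin, , drop = FALSE]
      match_motif <- vapply(ev$bases, .matches_motif, logical(1L), motif = motif)
      if (any(!match_motif)) other[k] <- TRUE
      ev <- ev[match_motif, , drop = FALSE]
      if (nrow(ev)) {
        delta[k] <- sum(ifelse(ev$type == "insertion", 1L, -1L) * nchar(ev$bases))
      }
    }
    tab <- table(delta)
    nets[[r]] <- if (length(tab)) {
      data.frame(ssr_id = loci$ssr_id[r], delta = as.integer(names(tab)),
                 reads = as.integer(tab), stringsAsFactors = FALSE)
    }
    tallies[[r]] <- data.frame(
      ssr_id = loci$ssr_id[r],
      spanning_reads = length(span),
      indel_reads = sum(delta != 0L),
      insertion_reads = sum(delta > 0L),
      deletion_reads = sum(delta < 0L),
      other_indel_reads = sum(other),
      stringsAsFactors = FALSE)
  }
  structure(list(tallies = do.call(rbind, tallies),
                 net = do.call(rbind, nets)),
            class = "locus_tally")
}

## do the indel bases consist of whole repeats of the run motif (or, for a
## mononucleotide motif, only the run base)?
.matches_motif <- function(bases, motif) {
  if (nchar(motif) == 1L) {
    return(all(strsplit(bases, "", fixed = TRUE)[[1]] == motif))
  }
  if (nchar(bases) %% 2L != 0L) return(FALSE)
  reps <- paste(rep(motif, nchar(bases) %/% 2L), collapse = "")
  rot <- paste0(substr(motif, 2L, 2L), substr(motif, 1L, 1L))
  reps_rot <- paste(rep(rot, nchar(bases) %/% 2L), collapse = "")
  bases == reps || bases == reps_rot
}

#' Write per-site pileup and per-locus tallies as TSV
#' @param pileup A `site_pileup`.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(as.data.frame(pileup), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @param tally A `locus_tally` from [scan_ssr_indels()].
#' @export
write_tally_tsv <- function(tally, path) {
  utils::write.table(tally$tallies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
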