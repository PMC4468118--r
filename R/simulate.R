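#' Simulate aligned transcript reads from a synthetic plastome
#'
#' Emits single-end reads in genome orientation (as a splice-aware mapper
#' would present them), with a transcript-strand tag taken from the gene
#' overlapping the read midpoint. Each read covering a planted editing
#' position carries the edited base with probability `true_level` (reference
#' C to read T on plus-strand transcripts; reference G to read A on
#' minus-strand transcripts). Each read spanning an SSR run plus one anchor
#' base on either side carries at most one same-base +/-1 indel inside the
#' run with probability `true_indel_prob` (an insertion with probability
#' `insertion_fraction`, else a deletion); the indel breakpoint is placed
#' uniformly within the run so that downstream left-normalization is
#' exercised. Substitution errors are added uniformly at `error_rate`,
#' excluding SSR runs (+/- 1) and editing positions so that truth-recovery
#' stays sharp ("sharp" profile); the "realistic" profile lifts that
#' restriction.
#'
#' @param plastome An `annotated_plastome` from [build_plastome()].
#' @param truth Matching `truth_table`.
#' @param n_reads Number of reads (> 0).
#' @param read_length Read length in bp (> longest SSR + 2 anchor bases).
#' @param seed Integer seed.
#' @param error_profile `"sharp"` (default) or `"realistic"`.
#' @return A `data.frame` of class `simulated_alignment` with columns
#'   `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`, `qual`,
#'   `strand_tag`, `nm`.
#' @export
simulate_reads <- function(plastome, truth, n_reads, read_length, seed = 1L,
                           error_profile = c("sharp", "realistic")) {
  error_profile <- match.arg(error_profile)
  if (n_reads <= 0L) stop("n_reads must be positive")
  if (read_length <= 0L) stop("read_length must be positive")
  ssrs <- plastome$ssrs
  if (!is.null(ssrs) && nrow(ssrs) &&
      read_length <= max(ssrs$total_length) + 2L) {
    stop("read_length must exceed the longest SSR plus 2 anchor bases")
  }
  set.seed(seed)
  genome <- plastome$seq
  L <- plastome$length

  starts <- sample.int(L - read_length, n_reads, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_length - 1L)
  cig_m <- rep.int(NA_character_, n_reads)   # NA -> plain match
  span_end <- starts + read_length - 1L
  nm <- integer(n_reads)

  ## slippage: at most one +/-1 same-base indel per read per locus
  if (!is.null(ssrs) && nrow(ssrs) && nrow(truth$slippage_truth)) {
    st <- truth$slippage_truth
    for (r in seq_len(nrow(ssrs))) {
      if (ssrs$wraps_origin[r]) next
      p <- st$true_indel_prob[match(ssrs$ssr_id[r], st$ssr_id)]
      if (is.na(p) || p <= 0) next
      rs <- ssrs$start[r]; re <- ssrs$end[r]
      base <- substr(ssrs$motif[r], 1L, 1L)
      if (nchar(ssrs$motif[r]) != 1L) next   # slippage model is mononucleotide
      spanning <- which(starts <= rs - 1L & span_end >= re + 1L &
                        is.na(cig_m))
      if (!length(spanning)) next
      slip <- spanning[stats::runif(length(spanning)) < p]
      if (!length(slip)) next
      ins <- stats::runif(length(slip)) < truth$slippage_truth$insertion_fraction[
        match(ssrs$ssr_id[r], st$ssr_id)]
      for (k in seq_along(slip)) {
        i <- slip[k]
        s <- starts[i]
        if (ins[k]) {
          ## keep the read spanning: if the un-inserted read ended exactly one
          ## base past the run, shift the window one base left
          if (s + read_length - 2L < re + 1L) {
            if (s <= 1L) next
            s <- s - 1L
            starts[i] <- s
          }
          q <- .sample1(seq.int(rs, min(re + 1L, s + read_length - 3L)))  # insert before q
          seqs[i] <- paste0(substr(genome, s, q - 1L), base,
                            substr(genome, q, s + read_length - 2L))
          cig_m[i] <- paste0(q - s, "M1I", read_length - 1L - (q - s), "M")
          span_end[i] <- s + read_length - 2L
        } else {
          if (s + read_length > L) next
          q <- .sample1(seq.int(rs, re))           # delete base q
          seqs[i] <- paste0(substr(genome, s, q - 1L),
                            substr(genome, q + 1L, s + read_length))
          cig_m[i] <- paste0(q - s, "M1D", read_length - (q - s), "M")
          span_end[i] <- s + read_length
        }
        nm[i] <- nm[i] + 1L
      }
    }
  }

  ## C-to-U editing: per-read Bernoulli at each covered truth site
  et <- truth$editing_truth
  if (!is.null(et) && nrow(et)) {
    for (r in seq_len(nrow(et))) {
      pos <- et$position[r]
      cover <- which(starts <= pos & span_end >= pos)
      if (!length(cover)) next
      hit <- cover[stats::runif(length(cover)) < et$true_level[r]]
      new_base <- if (et$strand[r] == "+") "T" else "A"
      for (i in hit) {
        off <- .ref_to_read_offset(pos, starts[i], cig_m[i])
        if (is.na(off)) next
        seqs[i] <- str_sub_replace(seqs[i], off, new_base)
        nm[i] <- nm[i] + 1L
      }
    }
  }

  ## uniform substitution errors
  if (truth$error_rate > 0) {
    excl <- integer(0)
    if (error_profile == "sharp") {
      if (!is.null(ssrs) && nrow(ssrs)) {
        excl <- unlist(lapply(seq_len(nrow(ssrs)), function(r) {
          seq.int(ssrs$start[r] - 1L, ssrs$start[r] + ssrs$total_length[r])
        }))
      }
      if (!is.null(et) && nrow(et)) excl <- c(excl, et$position)
    }
    n_err <- stats::rbinom(n_reads, read_length, truth$error_rate)
    for (i in which(n_err > 0L)) {
      offs <- sample.int(nchar(seqs[i]), n_err[i])
      for (off in offs) {
        refpos <- .read_to_ref_pos(off, starts[i], cig_m[i])
        if (!is.na(refpos) && refpos %in% excl) next
        old <- substr(seqs[i], off, off)
        seqs[i] <- str_sub_replace(seqs[i], off, sample(setdiff(BASES, old), 1L))
        nm[i] <- nm[i] + 1L
      }
    }
  }

  cig_m[is.na(cig_m)] <- paste0(read_length, "M")
  strand_tag <- rep("+", n_reads)
  if (!is.null(plastome$genes) && nrow(plastome$genes)) {
    mid <- starts + read_length %/% 2L
    for (g in seq_len(nrow(plastome$genes))) {
      inside <- mid >= plastome$genes$start[g] & mid <= plastome$genes$end[g]
      strand_tag[inside] <- plastome$genes$strand[g]
    }
  }

  structure(
    data.frame(qname = sprintf("read%06d", seq_len(n_reads)),
               flag = 0L, rname = plastome$name, pos = starts, mapq = 60L,
               cigar = cig_m, seq = seqs,
               qual = strrep("I", nchar(seqs)),
               strand_tag = strand_tag, nm = nm,
               stringsAsFactors = FALSE),
    class = c("simulated_alignment", "data.frame"),
    rname = plastome$name, rlength = L
  )
}

## read offset of a reference position under a (possibly NA = pure match)
## one-indel CIGAR; NA when the position is deleted or not covered
.ref_to_read_offset <- function(pos, start, cigar) {
  if (is.na(cigar)) return(pos - start + 1L)
  ops <- .parse_cigar(cigar)
  roff <- 0L; qoff <- 0L
  ref <- start - 1L
  for (k in seq_along(ops$op)) {
    n <- ops$len[k]
    op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      if (pos <= ref + n) return(qoff + (pos - ref))
      ref <- ref + n; qoff <- qoff + n
    } else if (op == "I") {
      qoff <- qoff + n
    } else if (op %in% c("D", "N")) {
      if (op == "D" && pos <= ref + n) return(NA_integer_)
      if (op == "N" && pos <= ref + n) return(NA_integer_)
      ref <- ref + n
    } else if (op == "S") {
      qoff <- qoff + n
    }
  }
  NA_integer_
}

## reference position of a read offset (NA for inserted/clipped bases)
.read_to_ref_pos <- function(off, start, cigar) {
  if (is.na(cigar)) return(start + off - 1L)
  ops <- .parse_cigar(cigar)
  qoff <- 0L; ref <- start - 1L
  for (k in seq_along(ops$op)) {
    n <- ops$len[k]
    op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      if (off <= qoff + n) return(ref + (off - qoff))
      ref <- ref + n; qoff <- qoff + n
    } else if (op %in% c("I", "S")) {
      if (off <= qoff + n) return(NA_integer_)
      qoff <- qoff + n
    } else if (op %in% c("D", "N")) {
      ref <- ref + n
    }
  }
  NA_integer_
}

#' Write simulated or parsed alignments as SAM
#'
#' Emits a minimal SAM 1.6 file: `@HD`/`@SQ` header, mandatory fields, an NM
#' edit-distance tag and an XS transcript-strand tag.
#'
#' @param aln Alignment `data.frame` from [simulate_reads()] or [read_sam()].
#' @param path Output path.
#' @param rname,rlength Reference name and length for the `@SQ` line
#'   (defaulted from the object's attributes).
#' @export
write_sam <- function(aln, path, rname = attr(aln, "rname"),
                      rlength = attr(aln, "rlength")) {
  if (is.null(rname)) rname <- aln$rname[1]
  if (is.null(rlength)) stop("reference length unknown; pass rlength")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", rname, "\tLN:", rlength))
  nm <- if (!is.null(aln$nm)) aln$nm else 0L
  xs <- if (!is.null(aln$strand_tag)) aln$strand_tag else "+"
  body <- if (nrow(aln) == 0L) character(0) else paste(
    aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
    "*", 0L, 0L, aln$seq, aln$qual,
    paste0("NM:i:", nm), paste0("XS:A:", xs),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file
#'
#' Parses the text SAM format into the alignment `data.frame` used by
#' [build_pileup()] and [scan_ssr_indels()]. Only single-reference headers
#' are supported; the `@SQ` name and length are kept as attributes.
#'
#' @param path SAM file.
#' @return Alignment `data.frame` with attributes `rname` and `rlength`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  rname <- NA_character_; rlength <- NA_integer_
  if (length(sq)) {
    f <- strsplit(sq[1], "\t", fixed = TRUE)[[1]]
    rname <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
    rlength <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
  }
  if (length(body) == 0L) {
    out <- data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), qual = character(),
                      strand_tag = character(), nm = integer(),
                      stringsAsFactors = FALSE)
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    get <- function(i) vapply(f, `[[`, character(1L), i)
    tagv <- function(prefix, default) {
      vapply(f, function(x) {
        hit <- x[startsWith(x, prefix)]
        if (length(hit)) sub(prefix, "", hit[1]) else default
      }, character(1L))
    }
    out <- data.frame(qname = get(1), flag = as.integer(get(2)),
                      rname = get(3), pos = as.integer(get(4)),
                      mapq = as.integer(get(5)), cigar = get(6),
                      seq = get(10), qual = get(11),
                      strand_tag = tagv("XS:A:", "+"),
                      nm = suppressWarnings(as.integer(tagv("NM:i:", "0"))),
                      stringsAsFactors = FALSE)
  }
  structure(out, class = c("simulated_alignment", "data.frame"),
            rname = rname, rlength = rlength)
}
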