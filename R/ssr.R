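#' Find simple sequence repeats on a (circular) DNA sequence
#'
#' Scans for maximal runs of mono- and dinucleotide motifs, in the MISA
#' dialect restricted to motif sizes 1-2. Dinucleotide runs are counted in
#' full motif units (a trailing half unit does not extend the locus) and a
#' "dinucleotide" run whose motif is a homopolymer pair (e.g. AA) is reported
#' as a mononucleotide run only. On circular input a run spanning the origin
#' is reported once, attributed to its leftmost base, with
#' `wraps_origin = TRUE`.
#'
#' The threshold is a total run length in bp: the default of 8 reports
#' 8-mers and longer, the convention under which published plastome SSR
#' tables that list 8-mers are reproduced.
#'
#' @param sequence Character scalar, uppercase ACGT (N allowed; never inside
#'   a reported run).
#' @param min_total_length Minimum total run length in bp (default 8).
#' @param motif_sizes Motif sizes to search; subset of `c(1, 2)`.
#' @param circular Treat the sequence as circular (default `TRUE`).
#' @return `data.frame` with columns `ssr_id`, `motif`, `unit_count`, `start`,
#'   `end`, `total_length`, `wraps_origin`. `end` is the (possibly wrapped)
#'   1-based inclusive coordinate of the last base.
#' @export
find_ssrs <- function(sequence, min_total_length = 8L, motif_sizes = c(1L, 2L),
                      circular = TRUE) {
  ch <- .dna_chars(sequence, allow_n = TRUE)
  L <- length(ch)
  stopifnot(min_total_length >= 1L, all(motif_sizes %in% c(1L, 2L)))
  d <- if (circular && L > 1L) c(ch, ch) else ch

  loci <- list()

  if (1L %in% motif_sizes) {
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_total_length & r$values %in% BASES & starts <= L
    ## the run at position 1 is the tail of an origin-wrapping run (unless the
    ## whole genome is a single run, which the length cap below handles)
    if (circular && L > 1L && length(r$lengths) > 1L && ch[L] == ch[1L]) {
      keep[starts == 1L] <- FALSE
    }
    if (any(keep)) {
      len <- pmin(r$lengths[keep], L)
      st <- starts[keep]
      loci[[length(loci) + 1L]] <- data.frame(
        motif = r$values[keep], unit_count = len,
        start = st, total_length = len,
        wraps_origin = circular & (st + len - 1L > L),
        stringsAsFactors = FALSE
      )
    }
  }

  if (2L %in% motif_sizes && L >= 4L) {
    n <- length(d)
    eq2 <- d[seq_len(n - 2L)] == d[3:n]
    r <- rle(eq2)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values)
    for (i in cand) {
      s <- starts[i]
      t_len <- r$lengths[i] + 2L           # period-2 stretch length in bases
      if (circular && L > 1L && s == 1L && ch[L] == ch[2L]) next  # wrap tail
      if (s > L) next
      b1 <- d[s]; b2 <- d[s + 1L]
      if (b1 == b2 || !(b1 %in% BASES) || !(b2 %in% BASES)) next
      units <- t_len %/% 2L
      total <- 2L * units
      if (total < min_total_length) next
      total <- min(total, if (L %% 2L == 0L) L else L - 1L)
      units <- total %/% 2L
      loci[[length(loci) + 1L]] <- data.frame(
        motif = paste0(b1, b2), unit_count = units,
        start = s, total_length = total,
        wraps_origin = circular & (s + total - 1L > L),
        stringsAsFactors = FALSE
      )
    }
  }

  if (length(loci) == 0L) {
    return(data.frame(ssr_id = character(), motif = character(),
                      unit_count = integer(), start = integer(),
                      end = integer(), total_length = integer(),
                      wraps_origin = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  out$end <- ((out$start + out$total_length - 2L) %% L) + 1L
  out$ssr_id <- sprintf("SSR%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("ssr_id", "motif", "unit_count", "start", "end",
          "total_length", "wraps_origin")]
}

#' Histogram of mononucleotide SSR lengths
#'
#' @param loci SSR `data.frame` from [find_ssrs()].
#' @return Named integer vector mapping total length (bp) to locus count,
#'   over mononucleotide loci only.
#' @export
summarize_ssr_lengths <- function(loci) {
  mono <- loci[nchar(loci$motif) == 1L, , drop = FALSE]
  if (nrow(mono) == 0L) return(integer(0))
  tab <- table(mono$total_length)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Write SSR loci as TSV
#' @param loci SSR `data.frame` from [find_ssrs()].
#' @param path Output path.
#' @export
write_ssr_tsv <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SSR loci as BED (0-based half-open)
#' @param loci SSR `data.frame` from [find_ssrs()].
#' @param path Output path.
#' @param seqname Chromosome name for column 1.
#' @export
write_ssr_bed <- function(loci, path, seqname = "plastome") {
  bed <- data.frame(chrom = seqname, start = loci$start - 1L,
                    end = loci$start - 1L + loci$total_length,
                    name = loci$ssr_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
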