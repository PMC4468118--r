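# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars internally; Biostrings objects only at the
# boundaries (I/O, reverse complement, alignment).

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param s A character scalar over the alphabet ACGTN.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## validate and split a DNA string; errors name the first offending position
.dna_chars <- function(s, allow_n = TRUE, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop(what, " must be a non-empty character scalar")
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ok <- ch %in% c(BASES, if (allow_n) "N")
  if (!all(ok)) {
    p <- which(!ok)[1L]
    stop(what, " contains non-ACGT", if (allow_n) "N", " character '",
         ch[p], "' at position ", p)
  }
  ch
}

## substring on a circular sequence, 1-based, wraps past the end
substr_circ <- function(seq, start, len) {
  L <- nchar(seq)
  if (len <= 0L) return("")
  idx <- ((start - 1L + seq_len(len) - 1L) %% L) + 1L
  ## contiguous fast path
  if (start >= 1L && start + len - 1L <= L) return(substr(seq, start, start + len - 1L))
  paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
}

## random DNA string of length n using the session RNG
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

.GENETIC_CODE_11 <- local({
  gc11 <- Biostrings::getGeneticCode("11")
  names(gc11) <- chartr("U", "T", names(gc11))
  gc11
})

## bacterial/plastid start codons (NCBI table 11)
.STARTS_11 <- c("ATG", "GTG", "TTG", "CTG", "ATT", "ATC", "ATA")

#' Translate a DNA coding sequence with the bacterial/plastid code
#'
#' Uses NCBI translation table 11. When `init = TRUE` the first codon is
#' rendered as M if it is one of the table-11 initiation codons. Trailing
#' partial codons are dropped. Stops appear as `*`.
#'
#' @param dna Character scalar, coding sequence in transcript orientation.
#' @param init Translate an alternative initiation codon at position 1 as M.
#' @return Character scalar of amino acids.
#' @export
translate_cds <- function(dna, init = TRUE) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(.GENETIC_CODE_11[codons])
  aa[is.na(aa)] <- "X"
  if (init && codons[1L] %in% .STARTS_11) aa[1L] <- "M"
  paste(aa, collapse = "")
}

## length of the longest common prefix of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1]]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

## sample one element (length-1 vectors are returned as-is, avoiding
## sample()'s scalar expansion)
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

## replace substring at [at, at + nchar(value) - 1]
str_sub_replace <- function(s, at, value) {
  paste0(substr(s, 1L, at - 1L), value, substr(s, at + nchar(value), nchar(s)))
}
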