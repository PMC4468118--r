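#' Detect the inverted-repeat pair and quadripartite partition
#'
#' Finds the longest pair of disjoint intervals whose sequences are exact
#' reverse complements of each other (the IRa/IRb pair of a plastome), by
#' seeding exact k-mer matches between the sequence and its reverse
#' complement and merging seeds along diagonals. The reported pair is maximal
#' under single-base extension at all four boundaries. The two remaining arcs
#' of the circle are labeled LSC (longer) and SSC (shorter).
#'
#' Ties between equal-length candidate pairs are broken towards the pair
#' whose first interval starts at the smallest coordinate. IRs spanning the
#' sequence origin are not searched; rotate the sequence first if needed.
#'
#' @param sequence Character scalar, uppercase ACGT.
#' @param min_ir_length Minimum IR length to report (bp).
#' @return A list of class `quadripartite` with elements `found`, `ira`,
#'   `irb`, `lsc`, `ssc` (each `c(start, end)`; the arc wrapping the origin
#'   has `start > end`), and `ir_length`, `lsc_length`, `ssc_length`. When no
#'   IR of the requested length exists, `found = FALSE` and the remaining
#'   elements are `NULL` -- a structured no-IR result, not an error.
#' @export
detect_inverted_repeats <- function(sequence, min_ir_length = 1000L) {
  L <- nchar(sequence)
  if (L < 4L * min_ir_length) {
    stop("sequence length ", L, " is shorter than 4 * min_ir_length")
  }
  rc <- revcomp(sequence)
  k <- as.integer(min(min_ir_length, 15L))

  idx <- seq_len(L - k + 1L)
  dtS <- data.table::data.table(kmer = substring(sequence, idx, idx + k - 1L), i = idx)
  dtR <- data.table::data.table(kmer = substring(rc, idx, idx + k - 1L), j = idx)
  pairs <- merge(dtS, dtR, by = "kmer", allow.cartesian = TRUE)
  no_ir <- structure(list(found = FALSE, ira = NULL, irb = NULL, lsc = NULL,
                          ssc = NULL, ir_length = 0L, lsc_length = NA_integer_,
                          ssc_length = NA_integer_), class = "quadripartite")
  if (nrow(pairs) == 0L) return(no_ir)

  ## merge seeds sharing a diagonal into maximal exact matches: within one
  ## match every start offset seeds the same diagonal, so consecutive seed
  ## starts differ by exactly 1 and any gap marks a mismatch
  pairs[, diag := i - j]
  data.table::setorder(pairs, diag, i)
  pairs[, seg := cumsum(c(1L, diff(i) != 1L | diff(diag) != 0L))]
  segs <- pairs[, list(a0 = i[1L], a1 = i[.N] + k - 1L,
                       b0 = j[1L], b1 = j[.N] + k - 1L), by = "seg"]

  segs[, len := a1 - a0 + 1L]
  ## partner interval of the reverse-complement match, in genome coordinates
  segs[, p0 := L - b1 + 1L]
  segs[, p1 := L - b0 + 1L]
  ## each IR pair is seen twice (and palindromes match themselves); keep the
  ## orientation with the first interval left of its disjoint partner
  segs <- segs[len >= min_ir_length & a1 < p0]
  if (nrow(segs) == 0L) return(no_ir)
  data.table::setorder(segs, -len, a0)
  best <- segs[1L]

  ira <- c(best$a0, best$a1)
  irb <- c(best$p0, best$p1)
  arc1 <- c(ira[2L] + 1L, irb[1L] - 1L)                 # between IRa and IRb
  arc2 <- c((irb[2L] %% L) + 1L, ira[1L] - 1L)          # wraps the origin
  arc_len <- function(a) {
    if (a[2L] >= a[1L]) a[2L] - a[1L] + 1L else L - a[1L] + 1L + a[2L]
  }
  l1 <- arc_len(arc1); l2 <- arc_len(arc2)
  if (l1 >= l2) {
    lsc <- arc1; ssc <- arc2
  } else {
    lsc <- arc2; ssc <- arc1
  }
  structure(list(found = TRUE, ira = ira, irb = irb, lsc = lsc, ssc = ssc,
                 ir_length = best$len, lsc_length = max(l1, l2),
                 ssc_length = min(l1, l2)),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (!x$found) {
    cat("quadripartite: no inverted repeat found\n")
  } else {
    cat("quadripartite: IR ", x$ir_length, " bp (IRa ", x$ira[1], "-", x$ira[2],
        ", IRb ", x$irb[1], "-", x$irb[2], "), LSC ", x$lsc_length,
        " bp, SSC ", x$ssc_length, " bp\n", sep = "")
  }
  invisible(x)
}

#' Write a quadripartite partition as JSON
#' @param partition A `quadripartite` object.
#' @param path Output path.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
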