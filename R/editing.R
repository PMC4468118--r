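#' Call C-to-U RNA-editing sites from a pileup
#'
#' A site is called iff the reference base is C on a plus-strand transcript
#' (or G on a minus-strand transcript, where a C-to-U edit appears as
#' reference-G to read-A in genome orientation), total depth is at least
#' `min_depth`, and the editing level is at least `min_level`. The editing
#' level is the edited-over-(edited+unedited) read fraction -- T/(C+T) on the
#' plus strand, A/(G+A) on the minus strand -- matching the U/C ratio
#' convention; other bases at the site are treated as sequencing error and
#' excluded from the denominator. The transcript strand is taken from the
#' overlapping gene model; both strands are tested for intergenic positions.
#' Candidate U-to-C events (reference T with C excess, or the strand
#' reflection) are screened with the same rule and returned separately.
#'
#' @param pileup A `site_pileup` from [build_pileup()].
#' @param genome `annotated_plastome` or sequence string.
#' @param gene_models Gene-model `data.frame` (`name`, `strand`, `start`,
#'   `end`), or `NULL` to treat everything as intergenic.
#' @param min_level Minimum editing level (default 0.05).
#' @param min_depth Minimum total read depth at the site (default 20).
#' @return A list with `sites` and `u_to_c`, each a `data.frame` with columns
#'   `position`, `gene`, `strand`, `level`, `edited_reads`, `total_reads`,
#'   `direction`.
#' @export
call_editing_sites <- function(pileup, genome, gene_models = NULL,
                               min_level = 0.05, min_depth = 20L) {
  seq <- if (inherits(genome, "annotated_plastome")) genome$seq else genome
  if (is.null(gene_models) && inherits(genome, "annotated_plastome")) {
    gene_models <- genome$genes
  }
  L <- nchar(seq)
  if (nrow(pileup$counts) != L) {
    stop("pileup was built against a different genome (length mismatch)")
  }
  if (!is.null(gene_models) && nrow(gene_models) &&
      any(gene_models$start < 1L | gene_models$end > L)) {
    stop("gene model outside genome")
  }
  ref <- strsplit(seq, "", fixed = TRUE)[[1]]

  strand_at <- rep(NA_character_, L)       # NA = intergenic, test both
  if (!is.null(gene_models) && nrow(gene_models)) {
    for (g in seq_len(nrow(gene_models))) {
      idx <- seq.int(gene_models$start[g], gene_models$end[g])
      strand_at[idx[is.na(strand_at[idx])]] <- gene_models$strand[g]
    }
  }

  depth <- pileup$depth
  cn <- pileup$counts

  screen <- function(ref_base, edited_col, unedited_col, strand, direction) {
    cand <- which(ref == ref_base & depth >= min_depth &
                  (is.na(strand_at) | strand_at == strand))
    if (!length(cand)) return(NULL)
    ed <- cn[cand, edited_col]
    un <- cn[cand, unedited_col]
    denom <- ed + un
    lvl <- ifelse(denom > 0L, ed / denom, 0)
    hit <- which(lvl >= min_level & ed > 0L)
    if (!length(hit)) return(NULL)
    data.frame(
      position = cand[hit],
      gene = vapply(cand[hit], function(p) {
        g <- gene_at_position(gene_models, p)
        if (is.na(g)) "intergenic" else g
      }, character(1L)),
      strand = strand, level = lvl[hit], edited_reads = ed[hit],
      total_reads = denom[hit], direction = direction,
      stringsAsFactors = FALSE)
  }

  bind <- function(...) {
    parts <- Filter(Negate(is.null), list(...))
    if (!length(parts)) {
      return(data.frame(position = integer(), gene = character(),
                        strand = character(), level = numeric(),
                        edited_reads = integer(), total_reads = integer(),
                        direction = character(), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, parts)
    out[order(out$position), , drop = FALSE]
  }

  sites <- bind(screen("C", "T", "C", "+", "C-to-U"),
                screen("G", "A", "G", "-", "C-to-U"))
  u_to_c <- bind(screen("T", "C", "T", "+", "U-to-C"),
                 screen("A", "G", "A", "-", "U-to-C"))
  rownames(sites) <- rownames(u_to_c) <- NULL
  list(sites = sites, u_to_c = u_to_c)
}

#' Bin editing levels into low / moderate / high
#'
#' Levels below one third are low, between one third and two thirds
#' (inclusive on both ends) moderate, and above two thirds high; the three
#' bins partition the input.
#'
#' @param sites Editing-site `data.frame` with a `level` column.
#' @return Named list of `data.frame`s: `low`, `moderate`, `high`.
#' @export
bin_editing_levels <- function(sites) {
  list(low = sites[sites$level < 1 / 3, , drop = FALSE],
       moderate = sites[sites$level >= 1 / 3 & sites$level <= 2 / 3, , drop = FALSE],
       high = sites[sites$level > 2 / 3, , drop = FALSE])
}
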