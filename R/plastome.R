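#' Annotated plastome container
#'
#' Bundles a circular genome sequence with its quadripartite partition, gene
#' models and SSR loci. All coordinates are 1-based inclusive.
#'
#' @param seq Character scalar, the circular genome sequence (uppercase ACGTN).
#' @param name Sequence name used in FASTA/SAM/GFF3 output.
#' @param genes `data.frame` with columns `name`, `strand` (`+`/`-`), `start`,
#'   `end`; one row per CDS interval (intervals of a spliced gene share a name).
#' @param ssrs `data.frame` of SSR loci as returned by [find_ssrs()], or `NULL`.
#' @param partition Quadripartite partition as returned by
#'   [detect_inverted_repeats()], or `NULL`.
#' @return An object of class `annotated_plastome`.
#' @export
annotated_plastome <- function(seq, name = "plastome", genes = NULL,
                               ssrs = NULL, partition = NULL) {
  .dna_chars(seq)
  if (!is.null(genes)) {
    stopifnot(all(c("name", "strand", "start", "end") %in% names(genes)))
    if (any(genes$start < 1L | genes$end > nchar(seq))) {
      stop("gene model outside genome")
    }
  }
  structure(
    list(seq = seq, name = name, length = nchar(seq),
         genes = genes, ssrs = ssrs, partition = partition),
    class = "annotated_plastome"
  )
}

#' @export
print.annotated_plastome <- function(x, ...) {
  cat("annotated_plastome '", x$name, "': ", x$length, " bp",
      if (!is.null(x$genes)) paste0(", ", length(unique(x$genes$name)), " genes"),
      if (!is.null(x$ssrs)) paste0(", ", nrow(x$ssrs), " SSR loci"),
      "\n", sep = "")
  invisible(x)
}

#' Read a plastome sequence from FASTA
#'
#' @param path FASTA file with a single record.
#' @param ... Passed on to [annotated_plastome()].
#' @return An `annotated_plastome`.
#' @export
read_plastome <- function(path, ...) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single FASTA record in ", path)
  annotated_plastome(toupper(as.character(ss[[1]])),
                     name = sub("\\s.*", "", names(ss)[1]), ...)
}

#' Write a plastome to FASTA (70-column wrap)
#'
#' @param plastome An `annotated_plastome`.
#' @param path Output path.
#' @export
write_plastome <- function(plastome, path) {
  ss <- Biostrings::DNAStringSet(plastome$seq)
  names(ss) <- plastome$name
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' CDS features (falling back to `gene` features if no CDS is present) are
#' returned as one row per interval, 1-based inclusive, with strand.
#'
#' @param path GFF3 file.
#' @return `data.frame` with columns `name`, `strand`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type == "CDS"
  if (!any(keep)) keep <- type == "gene"
  gr <- gr[keep]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  data.frame(
    name = nm,
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model `data.frame` (`name`, `strand`, `start`, `end`).
#' @param path Output path.
#' @param seqname Sequence name for column 1.
#' @export
write_gene_models <- function(genes, path, seqname = "plastome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "CDS",
    phase = 0L,
    ID = genes$name,
    Name = genes$name
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract one gene as a gene-model list
#'
#' Collects the CDS interval(s) of one gene from a gene-model `data.frame`
#' into the list form used by the consequence annotator.
#'
#' @param genes Gene-model `data.frame` (`name`, `strand`, `start`, `end`).
#' @param name Gene name.
#' @return List with `name`, `strand`, `cds` (`data.frame` of `start`/`end`
#'   in genomic order) and `span` (`c(start, end)` of the full extent).
#' @export
gene_model <- function(genes, name) {
  rows <- genes[genes$name == name, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown gene '", name, "'")
  rows <- rows[order(rows$start), , drop = FALSE]
  list(name = name, strand = rows$strand[1L],
       cds = rows[, c("start", "end")],
       span = c(min(rows$start), max(rows$end)))
}

## gene containing a genomic position (first match), or NA
gene_at_position <- function(genes, pos) {
  if (is.null(genes) || nrow(genes) == 0L) return(NA_character_)
  hit <- which(genes$start <= pos & genes$end >= pos)
  if (length(hit) == 0L) NA_character_ else genes$name[hit[1L]]
}
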