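# Codon-level consequences of editing sites and frameshift consequences of
# +/-1 slippage indels. Translation uses the bacterial/plastid code (NCBI
# table 11); alternative initiation codons are rendered as M at codon 1 only.

## CDS sequence (transcript orientation) of a gene-model list
.cds_seq <- function(gene, genome_seq) {
  parts <- substring(genome_seq, gene$cds$start, gene$cds$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

## transcript offset (1-based) of a genomic position in a gene, or NA
.cds_offset <- function(gene, pos) {
  widths <- gene$cds$end - gene$cds$start + 1L
  offs <- cumsum(c(0L, widths[-length(widths)]))
  hit <- which(pos >= gene$cds$start & pos <= gene$cds$end)
  if (length(hit) == 0L) return(NA_integer_)
  fwd <- offs[hit] + (pos - gene$cds$start[hit]) + 1L
  if (gene$strand == "+") fwd else sum(widths) - fwd + 1L
}

#' Annotate a C-to-U editing site at codon level
#'
#' Computes the affected codon and position on the transcript strand, the
#' amino-acid change under the plastid/bacterial code, and the effect class:
#' `synonymous`, `nonsynonymous`, `start_gain` (ACG to AUG at codon 1) or
#' `stop_gain` (edited codon is a stop). Sites outside the gene's CDS yield a
#' structured `non_coding` annotation, not an error.
#'
#' @param site One editing site: list or one-row `data.frame` with `position`
#'   (1-based genomic) and optionally `gene`.
#' @param gene Gene-model list from [gene_model()], or `NULL` for intergenic.
#' @param genome `annotated_plastome` or sequence string.
#' @return One-row `data.frame`: `gene`, `position`, `strand`, `codon_from`,
#'   `codon_to` (RNA alphabet), `codon_position`, `aa_from`, `aa_to`,
#'   `effect`.
#' @export
annotate_editing_site <- function(site, gene, genome) {
  seq <- if (inherits(genome, "annotated_plastome")) genome$seq else genome
  pos <- as.integer(site$position)
  non_coding <- data.frame(
    gene = if (is.null(gene)) "intergenic" else gene$name,
    position = pos, strand = if (is.null(gene)) "+" else gene$strand,
    codon_from = NA_character_, codon_to = NA_character_,
    codon_position = NA_integer_, aa_from = NA_character_,
    aa_to = NA_character_, effect = "non_coding", stringsAsFactors = FALSE)
  if (is.null(gene)) return(non_coding)
  off <- .cds_offset(gene, pos)
  if (is.na(off)) return(non_coding)
  cds <- .cds_seq(gene, seq)
  codon_i <- (off - 1L) %/% 3L + 1L
  cpos <- (off - 1L) %% 3L + 1L
  codon_from <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
  if (substr(codon_from, cpos, cpos) != "C") {
    warning("transcript base at editing site is not C (gene ", gene$name,
            ", position ", pos, ")")
  }
  codon_to <- codon_from
  substr(codon_to, cpos, cpos) <- "T"
  aa_from <- translate_cds(codon_from, init = FALSE)
  aa_to <- translate_cds(codon_to, init = FALSE)
  effect <- if (codon_i == 1L && codon_from == "ACG" && codon_to == "ATG") {
    "start_gain"
  } else if (aa_to == "*") {
    "stop_gain"
  } else if (aa_from == aa_to) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
  data.frame(gene = gene$name, position = pos, strand = gene$strand,
             codon_from = chartr("T", "U", codon_from),
             codon_to = chartr("T", "U", codon_to),
             codon_position = cpos, aa_from = aa_from, aa_to = aa_to,
             effect = effect, stringsAsFactors = FALSE)
}

#' Summarize editing effects by codon position and effect class
#'
#' @param annotations `data.frame` of rows from [annotate_editing_site()].
#' @return List with `n_sites` (all rows), `n_coding`, `codon_position`
#'   (named counts over positions 1-3 of coding sites) and `effect` (named
#'   counts over effect classes of coding sites).
#' @export
summarize_editing_effects <- function(annotations) {
  coding <- annotations[annotations$effect != "non_coding", , drop = FALSE]
  cp <- table(factor(coding$codon_position, levels = 1:3))
  ef <- table(coding$effect)
  list(n_sites = nrow(annotations), n_coding = nrow(coding),
       codon_position = stats::setNames(as.integer(cp), names(cp)),
       effect = stats::setNames(as.integer(ef), names(ef)))
}

#' Annotate a table of observed codon changes
#'
#' Replays rows of (gene, strand, codon_from, codon_position) -- the shape in
#' which editing patterns are reported -- through [annotate_editing_site()]
#' by reconstructing a minimal single-codon gene context for each row (a
#' micro-gene `ATG <codon> TAA`, embedded on the stated strand). Rows whose
#' `codon_from` is not a triplet (e.g. an intergenic spacer site) yield
#' `non_coding` annotations.
#'
#' @param rows `data.frame` with columns `gene`, `strand`, `codon_from` (RNA
#'   or DNA alphabet), `codon_position`.
#' @return Annotation `data.frame` as from [annotate_editing_site()].
#' @export
annotate_codon_changes <- function(rows) {
  pad <- "GCGCA"
  if (nrow(rows) == 0L) {
    return(data.frame(gene = character(), position = integer(),
                      strand = character(), codon_from = character(),
                      codon_to = character(), codon_position = integer(),
                      aa_from = character(), aa_to = character(),
                      effect = character(), stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    codon <- chartr("U", "T", rows$codon_from[i])
    if (is.na(codon) || nchar(codon) != 3L) {
      out[[i]] <- data.frame(
        gene = rows$gene[i], position = NA_integer_, strand = rows$strand[i],
        codon_from = NA_character_, codon_to = NA_character_,
        codon_position = NA_integer_, aa_from = NA_character_,
        aa_to = NA_character_, effect = "non_coding", stringsAsFactors = FALSE)
      next
    }
    t <- paste0("ATG", codon, "TAA")
    strand <- rows$strand[i]
    g0 <- nchar(pad) + 1L
    genome <- paste0(pad, if (strand == "-") revcomp(t) else t, pad)
    gene <- list(name = rows$gene[i], strand = strand,
                 cds = data.frame(start = g0, end = g0 + 8L),
                 span = c(g0, g0 + 8L))
    off <- 3L + rows$codon_position[i]
    pos <- if (strand == "+") g0 + off - 1L else (g0 + 8L) - off + 1L
    ann <- annotate_editing_site(list(position = pos), gene, genome)
    ann$gene <- rows$gene[i]
    out[[i]] <- ann
  }
  do.call(rbind, out)
}

#' Predict the protein consequence of a +/-1 indel in a transcript
#'
#' Builds the mutant transcript (strand-aware, with requested C-to-U editing
#' applied before translation), translates from the gene's start codon to the
#' first in-frame stop -- scanning past the reference stop into downstream
#' sequence when the frameshift removes it -- and reports the variant protein
#' length, the length of the N-terminal stretch shared with the reference
#' protein, whether the new stop lies within the gene's own reference span,
#' and the downstream gene whose own stop codon terminates the extended
#' reading frame, if any (a read-through fusion protein). Proteins are
#' reported without the terminal stop.
#'
#' @param gene Gene-model list from [gene_model()].
#' @param genome `annotated_plastome` or sequence string (circular).
#' @param indel List with `position` (1-based genomic), `type`
#'   (`"insertion"`/`"deletion"`/`"none"`), `base` (inserted base; ignored
#'   for deletions).
#' @param apply_editing Optional editing-site `data.frame` (`position`,
#'   `strand`) applied to the genome before translation.
#' @param gene_models Optional gene-model `data.frame` used to name the
#'   fusion partner.
#' @param max_scan Maximum bases scanned downstream for a stop (default 5000).
#' @return List of class `indel_consequence`: `variant_type`,
#'   `protein_length`, `shared_n_terminal`, `stops_in_gene`,
#'   `fusion_partner` (`NA` if none), `protein`, `no_stop`.
#' @export
predict_indel_consequence <- function(gene, genome, indel,
                                      apply_editing = NULL,
                                      gene_models = NULL, max_scan = 5000L) {
  seq <- if (inherits(genome, "annotated_plastome")) genome$seq else genome
  if (is.null(gene_models) && inherits(genome, "annotated_plastome")) {
    gene_models <- genome$genes
  }
  L <- nchar(seq)
  if (!is.null(apply_editing) && nrow(apply_editing)) {
    for (k in seq_len(nrow(apply_editing))) {
      p <- apply_editing$position[k]
      newb <- if (apply_editing$strand[k] == "+") "T" else "A"
      seq <- str_sub_replace(seq, p, newb)
    }
  }
  type <- indel$type
  span <- gene$span
  if (type != "none") {
    p <- as.integer(indel$position)
    lo <- min(span[1L], p); hi <- max(span[2L], p)
    if (p < lo - 1L || p > hi + 1L || hi - lo > L) {
      stop("indel outside transcript context of gene ", gene$name)
    }
  }

  mutate <- function(s) {
    if (type == "none") return(s)
    p <- as.integer(indel$position)
    if (type == "insertion") {
      paste0(substr(s, 1L, p - 1L), indel$base, substr(s, p, nchar(s)))
    } else if (type == "deletion") {
      paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
    } else {
      stop("unknown indel type '", type, "'")
    }
  }

  ## transcript window from the start codon, running downstream `max_scan`
  ## bases past the gene (circular); track genomic coordinates per base
  if (gene$strand == "+") {
    coords <- ((span[1L] - 1L + seq_len(span[2L] - span[1L] + 1L + max_scan) - 1L) %% L) + 1L
    window <- paste(strsplit(seq, "", fixed = TRUE)[[1]][coords], collapse = "")
  } else {
    coords <- ((span[2L] - 1L - (seq_len(span[2L] - span[1L] + 1L + max_scan) - 1L)) %% L) + 1L
    window <- paste(chartr("ACGTN", "TGCAN",
                           strsplit(seq, "", fixed = TRUE)[[1]][coords]),
                    collapse = "")
  }

  mut_window <- if (type == "none") {
    window
  } else {
    p <- as.integer(indel$position)
    w_off <- match(p, coords)
    if (is.na(w_off)) stop("indel outside transcript context of gene ", gene$name)
    if (gene$strand == "+") {
      if (type == "insertion") {
        paste0(substr(window, 1L, w_off - 1L), indel$base,
               substr(window, w_off, nchar(window)))
      } else {
        paste0(substr(window, 1L, w_off - 1L),
               substr(window, w_off + 1L, nchar(window)))
      }
    } else {
      ## on the minus strand an insertion before genomic p sits after the
      ## transcript base at p; the inserted base is complemented
      if (type == "insertion") {
        paste0(substr(window, 1L, w_off), chartr("ACGT", "TGCA", indel$base),
               substr(window, w_off + 1L, nchar(window)))
      } else {
        paste0(substr(window, 1L, w_off - 1L),
               substr(window, w_off + 1L, nchar(window)))
      }
    }
  }

  translate_to_stop <- function(tx) {
    aa <- translate_cds(tx, init = TRUE)
    stop_i <- regexpr("*", aa, fixed = TRUE)
    if (stop_i < 0L) list(protein = aa, stop_codon_idx = NA_integer_)
    else list(protein = substr(aa, 1L, stop_i - 1L), stop_codon_idx = as.integer(stop_i))
  }

  ref <- translate_to_stop(window)
  mut <- translate_to_stop(mut_window)

  ## genomic coordinates of the mutant stop codon
  stop_coords <- NA
  if (!is.na(mut$stop_codon_idx)) {
    tx_pos <- 3L * mut$stop_codon_idx - 2L:0L
    tx_pos <- sort(tx_pos)
    ## map mutant-transcript offsets back to window offsets
    if (type == "insertion") {
      w_off <- match(as.integer(indel$position), coords)
      ins_at <- if (gene$strand == "+") w_off else w_off + 1L
      w_pos <- ifelse(tx_pos < ins_at, tx_pos,
                      ifelse(tx_pos == ins_at, NA_integer_, tx_pos - 1L))
    } else if (type == "deletion") {
      w_off <- match(as.integer(indel$position), coords)
      w_pos <- ifelse(tx_pos < w_off, tx_pos, tx_pos + 1L)
    } else {
      w_pos <- tx_pos
    }
    stop_coords <- coords[w_pos[!is.na(w_pos)]]
  }

  stops_in_gene <- !all(is.na(stop_coords)) &&
    any(stop_coords >= span[1L] & stop_coords <= span[2L])

  fusion_partner <- NA_character_
  if (!all(is.na(stop_coords)) && !is.null(gene_models) && nrow(gene_models)) {
    others <- gene_models[gene_models$name != gene$name &
                          gene_models$strand == gene$strand, , drop = FALSE]
    for (g in unique(others$name)) {
      gm <- gene_model(others, g)
      stop_pos <- if (gm$strand == "+") {
        seq.int(gm$span[2L] - 2L, gm$span[2L])
      } else {
        seq.int(gm$span[1L], gm$span[1L] + 2L)
      }
      if (setequal(stop_coords, stop_pos)) {
        fusion_partner <- g
        break
      }
    }
  }

  structure(list(
    variant_type = type,
    protein_length = nchar(mut$protein),
    shared_n_terminal = common_prefix_len(ref$protein, mut$protein),
    stops_in_gene = stops_in_gene,
    fusion_partner = fusion_partner,
    protein = mut$protein,
    reference_protein = ref$protein,
    no_stop = is.na(mut$stop_codon_idx)), class = "indel_consequence")
}

#' @export
print.indel_consequence <- function(x, ...) {
  cat("indel_consequence: ", x$variant_type, ", protein ", x$protein_length,
      " aa (", x$shared_n_terminal, " shared N-terminal)",
      if (!is.na(x$fusion_partner)) paste0(", fusion with ", x$fusion_partner),
      "\n", sep = "")
  invisible(x)
}
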