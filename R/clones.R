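# Clone-sequence simulation and classification: full-length transcript
# variants differing by C-to-U editing at one site and/or a single +/-1
# same-base indel in one SSR run, the six-class scheme used to verify
# editing/slippage co-occurrence by amplicon cloning.

CLONE_CLASSES <- c("edited|no-indel", "unedited|no-indel",
                   "edited|U-ins", "edited|U-del",
                   "unedited|U-ins", "unedited|U-del")

## build one variant of the reference transcript; delta is the run-length
## change (+1 for the canonical U-ins, -1 for U-del, any integer accepted)
.make_clone <- function(ref, edit_pos, run_start, run_end, edited, delta) {
  base <- substr(ref, run_start, run_start)
  s <- if (delta >= 0L) {
    paste0(substr(ref, 1L, run_start - 1L), strrep(base, delta),
           substr(ref, run_start, nchar(ref)))
  } else {
    paste0(substr(ref, 1L, run_start - 1L),
           substr(ref, run_start - delta, nchar(ref)))
  }
  if (edited) {
    p <- if (edit_pos > run_end) edit_pos + delta else edit_pos
    if (substr(s, p, p) != "C") stop("reference base at editing site is not C")
    s <- str_sub_replace(s, p, "T")
  }
  s
}

#' Simulate a set of clone sequences with known class counts
#'
#' Emits full-length variant sequences of a reference transcript for the
#' requested counts of the six editing-by-indel classes. The indel is a
#' single same-base insertion or deletion at the start of the SSR run; the
#' editing state is a C or T at the (indel-adjusted) editing position.
#' Sequence order is shuffled under the seed.
#'
#' @param class_counts Named integer vector; names from
#'   `"edited|no-indel"`, `"unedited|no-indel"`, `"edited|U-ins"`,
#'   `"edited|U-del"`, `"unedited|U-ins"`, `"unedited|U-del"`.
#' @param ref_transcript Reference transcript sequence (plus orientation,
#'   unedited C at `edit_pos`).
#' @param edit_pos 1-based position of the editing site in the transcript.
#' @param run_start,run_end 1-based span of the SSR run in the transcript.
#' @param seed Integer seed.
#' @return Named character vector of clone sequences (names
#'   `<class>_<index>`).
#' @export
simulate_clone_set <- function(class_counts, ref_transcript, edit_pos,
                               run_start, run_end, seed = 1L) {
  unknown <- setdiff(names(class_counts), CLONE_CLASSES)
  if (length(unknown)) {
    stop("unknown clone class label: ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  out <- character(0)
  for (cls in names(class_counts)) {
    n <- class_counts[[cls]]
    if (n <= 0L) next
    parts <- strsplit(cls, "|", fixed = TRUE)[[1]]
    s <- .make_clone(ref_transcript, edit_pos, run_start, run_end,
                     edited = parts[1L] == "edited",
                     delta = switch(parts[2L], "no-indel" = 0L,
                                    "U-ins" = 1L, "U-del" = -1L))
    v <- rep(s, n)
    names(v) <- sprintf("%s_%03d", gsub("[^A-Za-z]", "_", cls), seq_len(n))
    out <- c(out, v)
  }
  out[sample.int(length(out))]
}

#' Classify a clone sequence by editing and slippage state
#'
#' Determines the run-length difference against the reference transcript
#' from the clone's total length and verifies the clone against the
#' reconstructed variant sequence for each compatible editing state, which
#' stays correct when the edited base extends the repeat run (the psbF
#' geometry). Returns one of the six classes `edited/unedited` x
#' `no-indel/U-ins/U-del`; run-length differences of 2 or more are reported
#' as `"other"`, and sequences matching no reconstruction are
#' `"unclassifiable"`.
#'
#' @param clone Clone sequence (plus orientation).
#' @param ref_transcript Reference transcript (unedited C at `edit_pos`).
#' @param edit_pos,run_start,run_end As in [simulate_clone_set()].
#' @return List with `class`, `edited`, `run_delta`.
#' @export
classify_clone_sequence <- function(clone, ref_transcript, edit_pos,
                                    run_start, run_end) {
  delta <- nchar(clone) - nchar(ref_transcript)
  hit <- NA
  for (edited in c(TRUE, FALSE)) {
    expected <- .make_clone(ref_transcript, edit_pos, run_start, run_end,
                            edited, delta)
    if (clone == expected) { hit <- edited; break }
  }
  if (is.na(hit)) {
    return(list(class = "unclassifiable", edited = NA,
                run_delta = NA_integer_))
  }
  if (abs(delta) >= 2L) {
    return(list(class = "other", edited = hit, run_delta = delta))
  }
  indel <- if (delta == 0L) "no-indel" else if (delta == 1L) "U-ins" else "U-del"
  list(class = paste0(if (hit) "edited" else "unedited", "|", indel),
       edited = hit, run_delta = delta)
}

#' Summarize clone classes
#'
#' @param clones Named character vector from [simulate_clone_set()] (or any
#'   clone sequences).
#' @param ref_transcript,edit_pos,run_start,run_end As in
#'   [classify_clone_sequence()].
#' @return `data.frame` with `class`, `count`, `percent` over the six classes
#'   (plus `other`/`unclassifiable` when present).
#' @export
summarize_clone_classes <- function(clones, ref_transcript, edit_pos,
                                    run_start, run_end) {
  cls <- vapply(clones, function(s) {
    classify_clone_sequence(s, ref_transcript, edit_pos, run_start,
                            run_end)$class
  }, character(1L), USE.NAMES = FALSE)
  lev <- c(CLONE_CLASSES, intersect(c("other", "unclassifiable"), cls))
  tab <- table(factor(cls, levels = lev))
  data.frame(class = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(cls), 2L),
             stringsAsFactors = FALSE)
}
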