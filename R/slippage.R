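#' Per-locus transcriptional-slippage frequencies
#'
#' The TS frequency of a locus is the fraction of spanning reads that carry a
#' same-base slippage indel attributable to the run. Loci with zero spanning
#' reads are flagged (`ts_frequency = NA`, `flagged = TRUE`), never divided.
#'
#' @param tally A `locus_tally` from [scan_ssr_indels()] (or its `tallies`
#'   `data.frame`).
#' @param loci SSR loci from [find_ssrs()], keyed consistently by `ssr_id`.
#' @return `data.frame` with `ssr_id`, `motif`, `total_length`,
#'   `spanning_reads`, `indel_reads`, `ts_frequency`, `insertion_fraction`,
#'   `flagged`.
#' @export
compute_ts_frequencies <- function(tally, loci) {
  t <- if (inherits(tally, "locus_tally")) tally$tallies else tally
  if (!all(t$ssr_id %in% loci$ssr_id)) {
    stop("unknown ssr_id in tallies: ",
         paste(setdiff(t$ssr_id, loci$ssr_id), collapse = ", "))
  }
  m <- match(t$ssr_id, loci$ssr_id)
  span <- t$spanning_reads
  freq <- ifelse(!is.na(span) & span > 0L, t$indel_reads / span, NA_real_)
  insf <- ifelse(!is.na(t$indel_reads) & t$indel_reads > 0L,
                 t$insertion_reads / t$indel_reads, NA_real_)
  data.frame(ssr_id = t$ssr_id, motif = loci$motif[m],
             total_length = loci$total_length[m],
             spanning_reads = span, indel_reads = t$indel_reads,
             ts_frequency = freq, insertion_fraction = insf,
             flagged = is.na(span) | span == 0L,
             stringsAsFactors = FALSE)
}

#' Regress mean TS frequency on SSR length
#'
#' Aggregates per-locus TS frequencies by SSR total length (mean and standard
#' error per length), optionally drops lengths represented by a single locus
#' (which lack replicates for a standard error), and fits an unweighted
#' ordinary least squares line of the per-length mean frequency on length.
#' The regression is on per-length means, not per-locus points, matching how
#' mean +/- SE per repeat length is usually plotted and reported.
#'
#' @param results `data.frame` from [compute_ts_frequencies()].
#' @param exclude_singleton_lengths Drop lengths with a single locus
#'   (default `TRUE`).
#' @return List with `slope`, `intercept`, `r_squared` and `aggregates`
#'   (`data.frame`: `length`, `n_loci`, `mean_frequency`, `standard_error`).
#' @export
regress_frequency_on_length <- function(results,
                                        exclude_singleton_lengths = TRUE) {
  usable <- results[!results$flagged & !is.na(results$ts_frequency), ,
                    drop = FALSE]
  if (nrow(usable) == 0L) stop("no loci with defined TS frequency")
  agg <- do.call(rbind, lapply(split(usable, usable$total_length), function(d) {
    data.frame(length = d$total_length[1L], n_loci = nrow(d),
               mean_frequency = mean(d$ts_frequency),
               standard_error = if (nrow(d) >= 2L) {
                 stats::sd(d$ts_frequency) / sqrt(nrow(d))
               } else NA_real_)
  }))
  rownames(agg) <- NULL
  fit_agg <- if (exclude_singleton_lengths) {
    agg[agg$n_loci >= 2L, , drop = FALSE]
  } else {
    agg
  }
  if (length(unique(fit_agg$length)) < 2L) {
    stop("fewer than 2 usable SSR lengths for regression")
  }
  fit <- stats::lm(mean_frequency ~ length, data = fit_agg)
  co <- stats::coef(fit)
  list(slope = unname(co["length"]), intercept = unname(co["(Intercept)"]),
       r_squared = summary(fit)$r.squared, aggregates = agg,
       fitted_lengths = fit_agg$length)
}

#' Write per-locus slippage results and the regression summary
#'
#' @param results `data.frame` from [compute_ts_frequencies()].
#' @param path Output TSV path.
#' @export
write_slippage_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_slippage_tsv
#' @param regression List from [regress_frequency_on_length()].
#' @export
write_regression_json <- function(regression, path) {
  jsonlite::write_json(regression, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
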