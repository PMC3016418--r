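# Performance metrics: marker-level recall/precision against simulated (or
# otherwise known) truth, and per-pool-kind F+/F- hit rates.

#' Classify deconvolution calls against truth
#'
#' A marker is `TP` when the assigned clone set is non-empty and a subset
#' of the true TP clones (a strict subset still anchors the correct
#' contig), `F+` when it contains at least one non-true clone, and
#' `no_solution` when the algorithm returned none. For non-unique calls
#' the assigned set is the union of the tied top-score solutions.
#'
#' @param results List of `deconv_result` objects (or a `deconv_results`).
#' @param truth A `sim_truth` (needs `tp_clones`), or a named list mapping
#'   marker to its true clone set.
#' @return data.frame with columns `marker`, `call`.
#' @export
classify_markers <- function(results, truth) {
  tp_clones <- if (inherits(truth, "sim_truth")) truth$tp_clones else truth
  rows <- lapply(results, function(r) {
    tr <- tp_clones[[r$marker]]
    if (is.null(tr)) stop("marker missing from truth: ", r$marker)
    call <- if (r$status == "no_solution" || length(r$assigned) == 0L) {
      "no_solution"
    } else if (all(r$assigned %in% tr)) "TP" else "F+"
    data.frame(marker = r$marker, call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Recall and precision from marker outcomes
#'
#' Recall = TP markers / all markers analyzed; precision = TP markers /
#' markers with solutions (TP + F+). `recall_2dp`/`precision_2dp` carry
#' the conventional 2-decimal half-up presentation rounding.
#'
#' @param outcomes data.frame from [classify_markers()], or the three
#'   counts directly via `n_tp`, `n_fp`, `n_no_solution`.
#' @param n_tp,n_fp,n_no_solution Alternative count interface.
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(outcomes = NULL, n_tp = NULL, n_fp = NULL,
                            n_no_solution = NULL) {
  if (!is.null(outcomes)) {
    stopifnot(nrow(outcomes) >= 1L)
    n_tp <- sum(outcomes$call == "TP")
    n_fp <- sum(outcomes$call == "F+")
    n_no_solution <- sum(outcomes$call == "no_solution")
  }
  n <- n_tp + n_fp + n_no_solution
  if (n < 1L) stop("at least one marker outcome is required")
  recall <- n_tp / n
  precision <- if (n_tp + n_fp > 0L) n_tp / (n_tp + n_fp) else NA_real_
  structure(list(n_markers = n, n_tp = n_tp, n_fp = n_fp,
                 n_no_solution = n_no_solution,
                 recall = recall, precision = precision,
                 recall_2dp = round_half_up(recall, 2),
                 precision_2dp = if (is.na(precision)) NA_real_ else
                   round_half_up(precision, 2)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("markers: %d | TP: %d | F+: %d | no solution: %d\n",
              x$n_markers, x$n_tp, x$n_fp, x$n_no_solution))
  cat(sprintf("recall: %.2f | precision: %s\n", x$recall_2dp,
              if (is.na(x$precision)) "NA" else
                sprintf("%.2f", x$precision_2dp)))
  invisible(x)
}

#' Per-pool-kind false-positive and false-negative hit rates
#'
#' The F+ rate of a pool kind is the number of observed hits absent from
#' the true hits divided by all observed hits; the F- rate is the number
#' of true hits absent from the observed hits divided by all true hits
#' (counted over all markers). Standard errors are binomial.
#'
#' @param observed List of [marker_hits()] as screened.
#' @param truth A `sim_truth` (uses its `true_hits`), or a list of
#'   [marker_hits()] with the true hits, marker-aligned by name.
#' @return data.frame with one row per pool kind: `kind`, `f_plus_rate`,
#'   `f_minus_rate`, their standard errors, and the hit counts.
#' @export
pool_hit_rates <- function(observed, truth) {
  true_hits <- if (inherits(truth, "sim_truth")) truth$true_hits else truth
  tmap <- stats::setNames(true_hits,
                          vapply(true_hits, `[[`, "", "marker"))
  rows <- lapply(POOL_KINDS, function(kind) {
    field <- tolower(kind)
    n_obs <- 0L; n_fp <- 0L; n_true <- 0L; n_fn <- 0L
    for (h in observed) {
      tr <- tmap[[h$marker]]
      if (is.null(tr)) stop("marker missing from truth: ", h$marker)
      o <- h[[field]]; t <- tr[[field]]
      n_obs <- n_obs + length(o)
      n_fp <- n_fp + length(setdiff(o, t))
      n_true <- n_true + length(t)
      n_fn <- n_fn + length(setdiff(t, o))
    }
    fpr <- if (n_obs > 0L) n_fp / n_obs else NA_real_
    fnr <- if (n_true > 0L) n_fn / n_true else NA_real_
    data.frame(kind = kind,
               f_plus_rate = fpr,
               f_minus_rate = fnr,
               f_plus_se = if (n_obs > 0L) sqrt(fpr * (1 - fpr) / n_obs)
                 else NA_real_,
               f_minus_se = if (n_true > 0L) sqrt(fnr * (1 - fnr) / n_true)
                 else NA_real_,
               n_observed = n_obs, n_true = n_true,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a metrics report
#'
#' @param metrics A `metrics_report`.
#' @param path Output TSV path.
#' @param rates Optional data.frame from [pool_hit_rates()], appended.
#' @param outcomes Optional per-marker outcome data.frame, written next to
#'   `path` with suffix `_markers.tsv`.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(metrics, path, rates = NULL, outcomes = NULL) {
  con <- file(path, "w")
  writeLines("# pooldeconv evaluation metrics v1", con)
  writeLines("metric\tvalue", con)
  for (f in c("n_markers", "n_tp", "n_fp", "n_no_solution")) {
    writeLines(paste(f, metrics[[f]], sep = "\t"), con)
  }
  writeLines(paste("recall", sprintf("%.2f", metrics$recall_2dp),
                   sep = "\t"), con)
  writeLines(paste("precision",
                   if (is.na(metrics$precision)) "NA" else
                     sprintf("%.2f", metrics$precision_2dp),
                   sep = "\t"), con)
  if (!is.null(rates)) {
    for (i in seq_len(nrow(rates))) {
      writeLines(paste(paste0(rates$kind[i], "_f_plus_rate"),
                       sprintf("%.4f", rates$f_plus_rate[i]), sep = "\t"),
                 con)
      writeLines(paste(paste0(rates$kind[i], "_f_minus_rate"),
                       sprintf("%.4f", rates$f_minus_rate[i]), sep = "\t"),
                 con)
    }
  }
  close(con)
  if (!is.null(outcomes)) {
    mpath <- sub("\\.tsv$", "_markers.tsv", path)
    con <- file(mpath, "w")
    writeLines("# pooldeconv per-marker outcomes v1", con)
    suppressWarnings(utils::write.table(outcomes, con, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    close(con)
  }
  invisible(path)
}
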