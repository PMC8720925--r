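#' Build a drug-event 2x2 contingency table
#'
#' Counts deduplicated reports into the standard pharmacovigilance
#' two-by-two table for one target drug and one target event term. A report
#' is drug-exposed when any of its retained drug entries matches the
#' (normalized) target name, and event-positive when any of its events
#' matches the target term at the chosen level; repeated terms within one
#' report count once, so each report falls in exactly one cell and
#' `a + b + c + d` equals the number of reports in the store.
#'
#' A drug or event absent from the store is not an error; it simply yields
#' zero counts in the corresponding margin.
#'
#' @param store a deduplicated [ReportStore-class] (typically also
#'   role-filtered to primary suspect drugs).
#' @param drug target drug name (normalized internally).
#' @param event target event term.
#' @param level `"PT"` to match preferred terms, `"SOC"` to match system
#'   organ classes ([applyTermMap()] must have been applied).
#' @return a [ContingencyTable-class].
#' @rdname buildTable
#' @export
setMethod("buildTable", "ReportStore",
          function(store, drug, event, level = c("PT", "SOC")) {
  level <- match.arg(level)
  drug <- normalizeDrugName(drug)
  n <- nrow(store@demo)
  exposed <- unique(store@drugs$report_key[store@drugs$drug_name == drug])
  term_col <- if (level == "PT") store@events$pt else store@events$soc
  if (level == "SOC" && nrow(store@events) > 0 && all(is.na(term_col)))
    stop("SOC-level table requested but no events are mapped; ",
         "run applyTermMap() first", call. = FALSE)
  hit <- !is.na(term_col) & term_col == event
  positive <- unique(store@events$report_key[hit])
  a <- sum(positive %in% exposed)
  b <- length(exposed) - a
  c_ <- length(positive) - a
  d <- n - a - b - c_
  new("ContingencyTable", a = as.integer(a), b = as.integer(b),
      c = as.integer(c_), d = as.integer(d))
})

#' Reporting odds ratio with Wald confidence interval
#'
#' Computes the ROR `(a d)/(b c)` of a 2x2 report table with a Wald
#' interval on the log-odds scale,
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' When any cell is zero the statistic is undefined; with
#' `zeroCell = "undefined"` (the default) the estimate and interval are
#' `NA` and the signal flag is `FALSE`, with `zeroCell = "haldane"` the
#' 0.5 continuity correction is added to every cell first and the result
#' is flagged `corrected`. The signal flag follows the usual
#' disproportionality rule: lower confidence limit above 1 and at least 2
#' observed co-reports — evaluated on the uncorrected `a`, since the
#' report-count condition refers to observed reports.
#'
#' @param table a [ContingencyTable-class].
#' @param z normal quantile for the interval; the default 1.959964 gives a
#'   95 percent interval.
#' @param zeroCell zero-cell policy, `"undefined"` or `"haldane"`.
#' @param drug,event,level optional labels carried into the result.
#' @return a [SignalResult-class].
#' @examples
#' computeRor(new("ContingencyTable", a = 10L, b = 90L, c = 100L, d = 9900L))
#' @export
computeRor <- function(table, z = 1.959964,
                       zeroCell = c("undefined", "haldane"),
                       drug = "", event = "", level = "") {
  zeroCell <- match.arg(zeroCell)
  stopifnot(is(table, "ContingencyTable"))
  validObject(table)
  a0 <- table@a
  cells <- c(table@a, table@b, table@c, table@d)
  corrected <- FALSE
  if (any(cells == 0L)) {
    if (zeroCell == "undefined") {
      return(new("SignalResult", drug = drug, event = event, level = level,
                 table = table, ror = NA_real_, ciLow = NA_real_,
                 ciHigh = NA_real_, z = z, corrected = FALSE,
                 isSignal = FALSE))
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  ror <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci_low <- exp(log(ror) - z * se)
  ci_high <- exp(log(ror) + z * se)
  new("SignalResult", drug = drug, event = event, level = level,
      table = table, ror = ror, ciLow = ci_low, ciHigh = ci_high, z = z,
      corrected = corrected, isSignal = (ci_low > 1) && (a0 >= 2L))
}

#' Scan all event terms co-reported with a drug
#'
#' Builds one [SignalResult-class] per distinct event term (at the chosen
#' level) whose co-report count with the target drug is at least `minA`,
#' and returns them as a data.frame sorted by descending ROR (undefined
#' RORs last), ties broken alphabetically by event term. The ordering is
#' deterministic, so repeated runs give identical tables.
#'
#' @param store a deduplicated, role-filtered [ReportStore-class].
#' @param drug target drug name.
#' @param level `"PT"` or `"SOC"`.
#' @param minA minimum co-report count `a` for a term to be reported
#'   (default 1).
#' @param z,zeroCell passed to [computeRor()].
#' @return data.frame with columns `drug`, `event`, `level`, `a`, `b`,
#'   `c`, `d`, `ror`, `ci_low`, `ci_high`, `corrected`, `is_signal`.
#' @seealso [writeSignals()]
#' @rdname scanEvents
#' @export
setMethod("scanEvents", "ReportStore",
          function(store, drug, level = c("PT", "SOC"), minA = 1L,
                   z = 1.959964, zeroCell = c("undefined", "haldane")) {
  level <- match.arg(level)
  zeroCell <- match.arg(zeroCell)
  drug_n <- normalizeDrugName(drug)
  n <- nrow(store@demo)
  exposed <- unique(store@drugs$report_key[store@drugs$drug_name == drug_n])

  term_col <- if (level == "PT") store@events$pt else store@events$soc
  keep <- !is.na(term_col) & nzchar(term_col)
  pairs <- unique(data.frame(report_key = store@events$report_key[keep],
                             term = term_col[keep],
                             stringsAsFactors = FALSE))
  if (nrow(pairs) == 0L) {
    return(.empty_signal_frame())
  }
  n_pos <- table(pairs$term)
  in_exposed <- pairs$report_key %in% exposed
  a_tab <- table(factor(pairs$term[in_exposed], levels = names(n_pos)))

  terms <- names(n_pos)
  a <- as.integer(a_tab[terms])
  npos <- as.integer(n_pos[terms])
  sel <- a >= as.integer(minA)
  terms <- terms[sel]; a <- a[sel]; npos <- npos[sel]
  if (!length(terms)) return(.empty_signal_frame())

  rows <- lapply(seq_along(terms), function(i) {
    tab <- new("ContingencyTable",
               a = a[i],
               b = as.integer(length(exposed) - a[i]),
               c = as.integer(npos[i] - a[i]),
               d = as.integer(n - length(exposed) - npos[i] + a[i]))
    res <- computeRor(tab, z = z, zeroCell = zeroCell, drug = drug_n,
                      event = terms[i], level = level)
    data.frame(drug = drug_n, event = terms[i], level = level,
               a = tab@a, b = tab@b, c = tab@c, d = tab@d,
               ror = res@ror, ci_low = res@ciLow, ci_high = res@ciHigh,
               corrected = res@corrected, is_signal = res@isSignal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$ror, out$event, na.last = TRUE, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
})

.empty_signal_frame <- function() {
  data.frame(drug = character(), event = character(), level = character(),
             a = integer(), b = integer(), c = integer(), d = integer(),
             ror = numeric(), ci_low = numeric(), ci_high = numeric(),
             corrected = logical(), is_signal = logical(),
             stringsAsFactors = FALSE)
}

#' Write a signal table as TSV
#'
#' Serializes the result of [scanEvents()] with undefined values written as
#' `NA` and floating-point columns at 6 significant digits.
#'
#' @param signals data.frame from [scanEvents()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeSignals <- function(signals, path) {
  out <- signals
  for (col in c("ror", "ci_low", "ci_high"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         as.character(signif(out[[col]], 6)))
  .write_tsv(out, path)
  invisible(path)
}
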