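#' Normalize a drug name
#'
#' Case-folds to lower case, trims leading/trailing whitespace and collapses
#' internal runs of whitespace to a single space. No active-ingredient or
#' brand-name dictionary is applied.
#'
#' @param x character vector of drug names.
#' @return normalized character vector.
#' @examples
#' normalizeDrugName("  MONTELUKAST   sodium ")
#' @export
normalizeDrugName <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Read one delimited table as all-character columns. Input is treated as
# UTF-8; undecodable bytes are replaced and the affected line count reported.
# Rows with too few fields are padded with "", rows with too many truncated
# (counted as malformed).
.read_raw_table <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path, call. = FALSE)
  bad_enc <- !validUTF8(lines)
  if (any(bad_enc))
    lines[bad_enc] <- iconv(lines[bad_enc], "UTF-8", "UTF-8", sub = "?")
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- tolower(trimws(parts[[1L]]))
  parts <- parts[-1L]
  nfld <- length(header)
  malformed <- sum(lengths(parts) > nfld)
  rows <- lapply(parts, function(p) {
    length(p) <- nfld          # pads with NA
    p
  })
  m <- do.call(rbind, c(rows, list(matrix(character(), 0, nfld))))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  df[] <- lapply(df, function(col) {
    col[is.na(col)] <- ""
    trimws(col)
  })
  list(table = df, n_rows = nrow(df), n_encoding_replaced = sum(bad_enc),
       n_malformed = malformed)
}

.require_cols <- function(tab, cols, what, path) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop(sprintf("%s table (%s) is missing required column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read FAERS-dialect report tables into a ReportStore
#'
#' Parses the three quarterly FAERS ASCII tables (DEMO, DRUG, REAC) into a
#' normalized [ReportStore-class]. Both the original `"$"`-delimited dialect
#' and a tab-separated dialect with the same schemas are supported. Each
#' distinct `primaryid` becomes one report; drug and event rows are joined
#' to their report by `primaryid`. Rows referencing a `primaryid` absent
#' from DEMO, rows with an unreadable role code and rows with empty
#' drug/event terms are dropped and counted in the provenance.
#'
#' Required columns (case-insensitive): DEMO `primaryid`, `caseid` and
#' optionally `caseversion` or `fda_dt`; DRUG `primaryid`, `role_cod`,
#' `drugname`; REAC `primaryid`, `pt`. The version rank used by
#' [deduplicate()] is the case version when present, else the receipt date
#' (`fda_dt`), else file order.
#'
#' @param demoPath,drugPath,reacPath paths to the three tables.
#' @param dialect `"dollar"` for `$`-separated FAERS ASCII, `"tsv"` for the
#'   tab-separated fixture dialect.
#' @return a [ReportStore-class] with provenance filled
#'   (`parsed = kept + dropped` per table).
#' @seealso [deduplicate()], [filterByRole()], [applyTermMap()],
#'   [writeReportTables()]
#' @export
readFaersTables <- function(demoPath, drugPath, reacPath,
                            dialect = c("tsv", "dollar")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "dollar") "$" else "\t"

  demo_raw <- .read_raw_table(demoPath, sep)
  drug_raw <- .read_raw_table(drugPath, sep)
  reac_raw <- .read_raw_table(reacPath, sep)

  .require_cols(demo_raw$table, c("primaryid", "caseid"), "DEMO", demoPath)
  .require_cols(drug_raw$table, c("primaryid", "role_cod", "drugname"),
                "DRUG", drugPath)
  .require_cols(reac_raw$table, c("primaryid", "pt"), "REAC", reacPath)

  dtab <- demo_raw$table
  n_demo_empty <- sum(!nzchar(dtab$primaryid) | !nzchar(dtab$caseid))
  dtab <- dtab[nzchar(dtab$primaryid) & nzchar(dtab$caseid), , drop = FALSE]
  n_demo_dup <- sum(duplicated(dtab$primaryid))
  dtab <- dtab[!duplicated(dtab$primaryid), , drop = FALSE]

  version_rank <- if ("caseversion" %in% names(dtab)) {
    suppressWarnings(as.numeric(dtab$caseversion))
  } else if ("fda_dt" %in% names(dtab)) {
    suppressWarnings(as.numeric(dtab$fda_dt))
  } else {
    NA_real_
  }
  if (all(is.na(version_rank)) && nrow(dtab) > 0)
    version_rank <- seq_len(nrow(dtab))
  version_rank[is.na(version_rank)] <- -Inf

  demo <- data.frame(report_key = dtab$primaryid, case_id = dtab$caseid,
                     version_rank = as.numeric(version_rank),
                     stringsAsFactors = FALSE)

  gtab <- drug_raw$table
  gtab$role_cod <- toupper(trimws(gtab$role_cod))
  gtab$drugname <- normalizeDrugName(gtab$drugname)
  known <- gtab$primaryid %in% demo$report_key
  n_drug_orphan <- sum(!known)
  bad_role <- known & !(gtab$role_cod %in% VALID_ROLES)
  empty_name <- known & !bad_role & !nzchar(gtab$drugname)
  keep <- known & !bad_role & !empty_name
  drugs <- data.frame(report_key = gtab$primaryid[keep],
                      drug_name = gtab$drugname[keep],
                      role = gtab$role_cod[keep], stringsAsFactors = FALSE)

  rtab <- reac_raw$table
  rtab$pt <- trimws(rtab$pt)
  r_known <- rtab$primaryid %in% demo$report_key
  n_reac_orphan <- sum(!r_known)
  r_empty <- r_known & !nzchar(rtab$pt)
  r_keep <- r_known & !r_empty
  events <- data.frame(report_key = rtab$primaryid[r_keep],
                       pt = rtab$pt[r_keep],
                       soc = rep(NA_character_, sum(r_keep)),
                       stringsAsFactors = FALSE)

  prov <- list(
    files = c(demo = demoPath, drug = drugPath, reac = reacPath),
    dialect = dialect,
    rows_parsed = c(demo = demo_raw$n_rows, drug = drug_raw$n_rows,
                    reac = reac_raw$n_rows),
    rows_dropped = list(
      demo_empty_key = n_demo_empty, demo_duplicate_key = n_demo_dup,
      drug_orphan = n_drug_orphan, drug_bad_role = sum(bad_role),
      drug_empty_name = sum(empty_name),
      reac_orphan = n_reac_orphan, reac_empty_pt = sum(r_empty)),
    encoding_replaced_lines = demo_raw$n_encoding_replaced +
      drug_raw$n_encoding_replaced + reac_raw$n_encoding_replaced,
    malformed_rows = demo_raw$n_malformed + drug_raw$n_malformed +
      reac_raw$n_malformed
  )

  new("ReportStore", demo = demo, drugs = drugs, events = events,
      provenance = prov)
}

#' Keep one report per case (latest case version)
#'
#' Spontaneous-report databases receive resubmitted versions of the same
#' patient case; analyses keep one record per case. `deduplicate` retains,
#' for every `case_id`, the report with the greatest version rank (case
#' version when available, else receipt date, else file order). Ties are
#' broken deterministically by the lexicographically greatest `report_key`.
#' The operation is idempotent.
#'
#' @param store a [ReportStore-class].
#' @return a new `ReportStore` with one report per case and dedup
#'   statistics appended to the provenance.
#' @rdname deduplicate
#' @export
setMethod("deduplicate", "ReportStore", function(store) {
  demo <- store@demo
  if (nrow(demo) == 0L) return(store)
  ord <- order(demo$case_id, -demo$version_rank,
               -xtfrm(demo$report_key), method = "radix")
  demo_sorted <- demo[ord, , drop = FALSE]
  keep_rows <- !duplicated(demo_sorted$case_id)
  kept <- demo_sorted[keep_rows, , drop = FALSE]
  rownames(kept) <- NULL
  keys <- kept$report_key

  prov <- store@provenance
  prov$dedup <- list(n_before = nrow(demo), n_after = nrow(kept),
                     n_removed = nrow(demo) - nrow(kept))
  new("ReportStore",
      demo = kept,
      drugs = store@drugs[store@drugs$report_key %in% keys, , drop = FALSE],
      events = store@events[store@events$report_key %in% keys, , drop = FALSE],
      provenance = prov)
})

#' Restrict a store to drugs with given role codes
#'
#' Keeps only drug entries whose role code belongs to `roles` (typically
#' `"PS"`, the primary suspect drug). Reports left with no drug entries
#' are excluded from the result entirely; the input store is unmodified.
#'
#' @param store a [ReportStore-class].
#' @param roles non-empty character subset of `c("PS","SS","C","I")`.
#' @return a filtered `ReportStore`.
#' @rdname filterByRole
#' @export
setMethod("filterByRole", "ReportStore", function(store, roles) {
  if (missing(roles) || length(roles) == 0L)
    stop("'roles' must be a non-empty set of role codes", call. = FALSE)
  roles <- toupper(as.character(roles))
  bad <- setdiff(roles, VALID_ROLES)
  if (length(bad))
    stop("unknown role code(s): ", paste(bad, collapse = ", "), call. = FALSE)

  drugs <- store@drugs[store@drugs$role %in% roles, , drop = FALSE]
  keys <- unique(drugs$report_key)
  demo <- store@demo[store@demo$report_key %in% keys, , drop = FALSE]
  events <- store@events[store@events$report_key %in% keys, , drop = FALSE]
  rownames(demo) <- rownames(drugs) <- rownames(events) <- NULL

  prov <- store@provenance
  prov$role_filter <- list(roles = roles,
                           n_reports_before = nrow(store@demo),
                           n_reports_after = nrow(demo))
  new("ReportStore", demo = demo, drugs = drugs, events = events,
      provenance = prov)
})

#' Read a preferred-term to system-organ-class mapping
#'
#' The map is a two-column tab-separated file with header columns `pt` and
#' `soc` — a flat stand-in for the licensed MedDRA hierarchy.
#'
#' @param path TSV path.
#' @return named character vector: `names()` are preferred terms, values
#'   the system organ classes. Lookup of an unmapped PT yields `NA`,
#'   never an empty string.
#' @seealso [applyTermMap()]
#' @export
readTermMap <- function(path) {
  raw <- .read_raw_table(path, "\t")
  .require_cols(raw$table, c("pt", "soc"), "term map", path)
  tab <- raw$table
  tab <- tab[nzchar(tab$pt), , drop = FALSE]
  if (anyDuplicated(tab$pt)) {
    dup <- unique(tab$pt[duplicated(tab$pt)])
    stop("duplicated preferred term(s) in map: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  stats::setNames(tab$soc, tab$pt)
}

#' Map event preferred terms to system organ classes
#'
#' Fills the `soc` field of every event from a PT-to-SOC map. Terms missing
#' from the map are handled according to `onMiss`: dropped (and counted),
#' kept with `soc = NA`, or raised as an error naming the offending term.
#'
#' @param store a [ReportStore-class].
#' @param map named character vector as returned by [readTermMap()].
#' @param onMiss `"drop"` (default), `"keep_unmapped"`, or `"error"`.
#' @return a new `ReportStore` with mapped events; the number of unmapped
#'   terms encountered is recorded in the provenance.
#' @rdname applyTermMap
#' @export
setMethod("applyTermMap", "ReportStore",
          function(store, map, onMiss = c("drop", "keep_unmapped", "error")) {
  onMiss <- match.arg(onMiss)
  if (is.null(names(map)) || length(map) == 0L)
    stop("'map' must be a non-empty named character vector", call. = FALSE)
  events <- store@events
  soc <- unname(map[events$pt])
  miss <- is.na(soc)
  if (any(miss) && onMiss == "error") {
    terms <- unique(events$pt[miss])
    stop("unmapped preferred term(s): ",
         paste(utils::head(terms, 5L), collapse = ", "), call. = FALSE)
  }
  events$soc <- as.character(soc)
  if (onMiss == "drop") events <- events[!miss, , drop = FALSE]
  rownames(events) <- NULL
  prov <- store@provenance
  prov$term_map <- list(on_miss = onMiss, n_unmapped = sum(miss))
  new("ReportStore", demo = store@demo, drugs = store@drugs,
      events = events, provenance = prov)
})

#' Write a ReportStore back to the tab-separated dialect
#'
#' Emits `demo.tsv`, `drug.tsv` and `reac.tsv` in the tab-separated dialect
#' accepted by [readFaersTables()]; re-reading reproduces report, drug-entry
#' and event-entry counts exactly.
#'
#' @param store a [ReportStore-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeReportTables <- function(store, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(demo = file.path(dir, "demo.tsv"),
             drug = file.path(dir, "drug.tsv"),
             reac = file.path(dir, "reac.tsv"))
  demo_out <- data.frame(primaryid = store@demo$report_key,
                         caseid = store@demo$case_id,
                         caseversion = store@demo$version_rank)
  drug_out <- data.frame(primaryid = store@drugs$report_key,
                         role_cod = store@drugs$role,
                         drugname = store@drugs$drug_name)
  reac_out <- data.frame(primaryid = store@events$report_key,
                         pt = store@events$pt)
  .write_tsv(demo_out, paths[["demo"]])
  .write_tsv(drug_out, paths[["drug"]])
  .write_tsv(reac_out, paths[["reac"]])
  invisible(paths)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' @rdname reportstore-accessors
#' @export
setMethod("reportDemo", "ReportStore", function(x) x@demo)

#' @rdname reportstore-accessors
#' @export
setMethod("reportDrugs", "ReportStore", function(x) x@drugs)

#' @rdname reportstore-accessors
#' @export
setMethod("reportEvents", "ReportStore", function(x) x@events)

#' @rdname reportstore-accessors
#' @export
setMethod("provenance", "ReportStore", function(x) x@provenance)
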