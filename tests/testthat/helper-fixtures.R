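# Small programmatic fixtures shared across test files.

write_report_fixture <- function(dir, demo, drug, reac, sep = "\t") {
  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"))
  writeLines(gsub("\t", sep, demo, fixed = TRUE), paths[["demo"]])
  writeLines(gsub("\t", sep, drug, fixed = TRUE), paths[["drug"]])
  writeLines(gsub("\t", sep, reac, fixed = TRUE), paths[["reac"]])
  paths
}

# Three matching reports: R1 has two drugs, R2 and R3 one each.
basic_fixture_lines <- function() {
  list(
    demo = c("primaryid\tcaseid\tcaseversion",
             "R1\tC1\t1", "R2\tC2\t1", "R3\tC3\t1"),
    drug = c("primaryid\trole_cod\tdrugname",
             "R1\tPS\tMontelukast", "R1\tC\taspirin",
             "R2\tPS\taspirin", "R3\tPS\tibuprofen"),
    reac = c("primaryid\tpt",
             "R1\tSuicidal ideation", "R2\tHeadache", "R3\tNausea"))
}

read_basic_store <- function(extra_drug = character(),
                             reac_lines = NULL, sep = "\t",
                             dialect = "tsv") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  lines <- basic_fixture_lines()
  lines$drug <- c(lines$drug, extra_drug)
  if (!is.null(reac_lines)) lines$reac <- reac_lines
  p <- write_report_fixture(dir, lines$demo, lines$drug, lines$reac, sep)
  readFaersTables(p[["demo"]], p[["drug"]], p[["reac"]], dialect = dialect)
}

# Build a ReportStore directly from per-report drug/event lists.
make_store <- function(drugs_by_report, events_by_report,
                       case_ids = NULL, version_rank = NULL) {
  keys <- union(names(drugs_by_report), names(events_by_report))
  if (is.null(case_ids)) case_ids <- keys
  if (is.null(version_rank)) version_rank <- rep(1, length(keys))
  demo <- data.frame(report_key = keys, case_id = case_ids,
                     version_rank = version_rank, stringsAsFactors = FALSE)
  drugs <- do.call(rbind, c(lapply(names(drugs_by_report), function(k) {
    d <- drugs_by_report[[k]]
    if (!length(d)) return(NULL)
    data.frame(report_key = k, drug_name = names(d), role = unname(d),
               stringsAsFactors = FALSE)
  }), list(data.frame(report_key = character(), drug_name = character(),
                      role = character(), stringsAsFactors = FALSE))))
  events <- do.call(rbind, c(lapply(names(events_by_report), function(k) {
    e <- events_by_report[[k]]
    if (!length(e)) return(NULL)
    data.frame(report_key = k, pt = e, soc = NA_character_,
               stringsAsFactors = FALSE)
  }), list(data.frame(report_key = character(), pt = character(),
                      soc = character(), stringsAsFactors = FALSE))))
  new("ReportStore", demo = demo, drugs = drugs, events = events,
      provenance = list())
}

named_graph <- function(g, prefix = "N") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  g
}

# Erdos-Renyi graph with named vertices, reproducible.
random_named_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    named_graph(g, "V")
  })
}

mitab_row <- function(a, b, taxa = "taxid:9606(Homo sapiens)",
                      taxb = taxa, alias = TRUE) {
  f <- function(x) paste0("hgnc:", x)
  cols <- c(f(a), f(b), "-", "-",
            if (alias) f(a) else "-", if (alias) f(b) else "-",
            "psi-mi:\"MI:0045\"", "-", "pubmed:1", taxa, taxb,
            "psi-mi:\"MI:0915\"", "psi-mi:\"MI:0000\"", "-", "-")
  paste(cols, collapse = "\t")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
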