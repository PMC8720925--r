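test_that("FAERS tables parse into one report per key with joined rows", {
  store <- read_basic_store()
  expect_equal(nrow(reportDemo(store)), 3L)
  expect_equal(sum(reportDrugs(store)$report_key == "R1"), 2L)
  expect_equal(nrow(reportEvents(store)), 3L)
  expect_equal(reportDrugs(store)$drug_name[
    reportDrugs(store)$report_key == "R1" &
      reportDrugs(store)$role == "PS"], "montelukast")
})

test_that("dollar dialect parses identically to tsv", {
  tsv <- read_basic_store()
  dollar <- read_basic_store(sep = "$", dialect = "dollar")
  expect_equal(reportDemo(dollar), reportDemo(tsv))
  expect_equal(reportDrugs(dollar), reportDrugs(tsv))
  expect_equal(reportEvents(dollar), reportEvents(tsv))
})

test_that("orphan and malformed rows are dropped and counted", {
  store <- read_basic_store(extra_drug = "R9\tPS\tghostdrug")
  expect_equal(provenance(store)$rows_dropped$drug_orphan, 1L)
  expect_equal(nrow(reportDrugs(store)), 4L)

  bad_role <- read_basic_store(extra_drug = "R2\tXX\tmystery")
  expect_equal(provenance(bad_role)$rows_dropped$drug_bad_role, 1L)

  parsed <- provenance(store)$rows_parsed
  dropped <- provenance(store)$rows_dropped
  expect_equal(unname(parsed[["drug"]]),
               nrow(reportDrugs(store)) + dropped$drug_orphan +
                 dropped$drug_bad_role + dropped$drug_empty_name)
})

test_that("an event table with no usable rows leaves all event lists empty", {
  store <- read_basic_store(reac_lines = c("primaryid\tpt"))
  expect_equal(nrow(reportEvents(store)), 0L)
  tab <- buildTable(deduplicate(store), "aspirin", "Headache", "PT")
  expect_equal(tab@a, 0L)
})

test_that("missing required columns raise schema errors naming the column", {
  dir <- withr::local_tempdir()
  lines <- basic_fixture_lines()
  lines$drug <- sub("\t[^\t]*$", "", lines$drug)   # drugname column dropped
  p <- write_report_fixture(dir, lines$demo, lines$drug, lines$reac)
  expect_error(readFaersTables(p[["demo"]], p[["drug"]], p[["reac"]]),
               "drugname")
})

test_that("deduplication keeps the maximal version with deterministic ties", {
  st <- make_store(
    drugs_by_report = list(A1 = c(x = "PS"), A2 = c(x = "PS"),
                           A3 = c(y = "PS")),
    events_by_report = list(A1 = "e1", A2 = "e2", A3 = "e3"),
    case_ids = c("C1", "C1", "C1"), version_rank = c(1, 2, 3))
  dd <- deduplicate(st)
  expect_equal(reportDemo(dd)$report_key, "A3")

  # tie on version rank: lexicographically greatest report_key wins
  tie <- make_store(
    drugs_by_report = list(A = c(x = "PS"), B = c(x = "PS")),
    events_by_report = list(A = "e", B = "e"),
    case_ids = c("C1", "C1"), version_rank = c(5, 5))
  expect_equal(reportDemo(deduplicate(tie))$report_key, "B")

  # all-distinct case ids: identity
  distinct <- make_store(
    drugs_by_report = list(A = c(x = "PS"), B = c(y = "PS")),
    events_by_report = list(A = "e", B = "e"))
  expect_equal(nrow(reportDemo(deduplicate(distinct))), 2L)
})

test_that("deduplication is idempotent and sized by distinct case ids", {
  sim <- simulateReports(nReports = 300, dupFrac = 0.25, seed = 11)
  once <- deduplicate(sim$store)
  twice <- deduplicate(once)
  expect_equal(reportDemo(once), reportDemo(twice))
  expect_equal(nrow(reportDemo(once)),
               length(unique(reportDemo(sim$store)$case_id)))
  expect_equal(provenance(once)$dedup$n_removed, 75L)
})

test_that("role filtering retains matching entries and drops drugless reports", {
  st <- make_store(
    drugs_by_report = list(R1 = c(x = "PS", y = "C"), R2 = c(z = "C")),
    events_by_report = list(R1 = "e", R2 = "e"))
  ps <- filterByRole(st, "PS")
  expect_equal(reportDrugs(ps)$drug_name, "x")
  expect_equal(reportDemo(ps)$report_key, "R1")
  expect_false("R2" %in% reportEvents(ps)$report_key)

  all_roles <- filterByRole(st, c("PS", "SS", "C", "I"))
  expect_equal(nrow(reportDemo(all_roles)), 2L)
  expect_true(all(reportDrugs(filterByRole(st, "PS"))$role == "PS"))

  expect_error(filterByRole(st, character()), "non-empty")
  # input untouched
  expect_equal(nrow(reportDrugs(st)), 3L)
})

test_that("term mapping fills SOCs and handles misses per policy", {
  st <- make_store(
    drugs_by_report = list(R1 = c(x = "PS")),
    events_by_report = list(R1 = c("Suicidal ideation", "Weirdness")))
  map <- c("Suicidal ideation" = "Psychiatric disorders")

  dropped <- applyTermMap(st, map, onMiss = "drop")
  expect_equal(reportEvents(dropped)$soc, "Psychiatric disorders")
  expect_equal(nrow(reportEvents(dropped)), 1L)
  expect_equal(provenance(dropped)$term_map$n_unmapped, 1L)

  kept <- applyTermMap(st, map, onMiss = "keep_unmapped")
  expect_equal(nrow(reportEvents(kept)), 2L)
  expect_true(is.na(reportEvents(kept)$soc[
    reportEvents(kept)$pt == "Weirdness"]))

  expect_error(applyTermMap(st, map, onMiss = "error"), "Weirdness")
})

test_that("term map reader returns explicit NA for unmapped terms", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.tsv")
  writeLines(c("pt\tsoc", "Headache\tNervous system disorders"), path)
  map <- readTermMap(path)
  expect_equal(unname(map["Headache"]), "Nervous system disorders")
  expect_true(is.na(map["Not a term"]))
})

test_that("tsv round-trip preserves report, drug and event counts exactly", {
  sim <- simulateReports(nReports = 150, dupFrac = 0.1, seed = 7)
  dir <- withr::local_tempdir()
  writeReportTables(sim$store, dir)
  back <- readFaersTables(file.path(dir, "demo.tsv"),
                          file.path(dir, "drug.tsv"),
                          file.path(dir, "reac.tsv"), dialect = "tsv")
  expect_equal(nrow(reportDemo(back)), nrow(reportDemo(sim$store)))
  expect_equal(nrow(reportDrugs(back)), nrow(reportDrugs(sim$store)))
  expect_equal(nrow(reportEvents(back)), nrow(reportEvents(sim$store)))
  expect_equal(sum(unlist(provenance(back)$rows_dropped)), 0L)
})

test_that("drug name normalization folds case and collapses whitespace", {
  expect_equal(normalizeDrugName("  MONTELUKAST   Sodium "),
               "montelukast sodium")
  expect_equal(normalizeDrugName("aspirin"), "aspirin")
})
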