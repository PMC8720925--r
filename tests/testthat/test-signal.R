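ct <- function(a, b, c, d)
  new("ContingencyTable", a = as.integer(a), b = as.integer(b),
      c = as.integer(c), d = as.integer(d))

test_that("contingency tables count each report in exactly one cell", {
  st <- make_store(
    drugs_by_report = list(R1 = c(d = "PS"), R2 = c(d = "PS"),
                           R3 = c(x = "PS"), R4 = c(x = "PS")),
    events_by_report = list(R1 = "e", R3 = "e"))
  tab <- buildTable(st, "d", "e", "PT")
  expect_equal(c(tab@a, tab@b, tab@c, tab@d), c(1L, 1L, 1L, 1L))

  # repeated PT within one report counts once
  rep_pt <- make_store(
    drugs_by_report = list(R1 = c(d = "PS"), R2 = c(x = "PS")),
    events_by_report = list(R1 = c("e", "e")))
  tab2 <- buildTable(rep_pt, "d", "e", "PT")
  expect_equal(tab2@a, 1L)

  # absent drug/event: zero margins, not an error
  none <- buildTable(st, "nosuchdrug", "noevent", "PT")
  expect_equal(c(none@a, none@b, none@c, none@d), c(0L, 0L, 0L, 4L))
})

test_that("tables from a simulated store match a brute-force truth recount", {
  sim <- simulateReports(nReports = 200, seed = 42)
  store <- filterByRole(deduplicate(sim$store), "PS")
  truth <- sim$truth
  kept <- truth[!is.na(truth$ps_drug), , drop = FALSE]
  for (ev in c("suicidal ideation", "nausea")) {
    exp_flag <- kept$ps_drug == "montelukast"
    ev_flag <- kept[[paste0("event.", ev)]]
    tab <- buildTable(store, "montelukast", ev, "PT")
    expect_equal(tab@a, sum(exp_flag & ev_flag))
    expect_equal(tab@b, sum(exp_flag & !ev_flag))
    expect_equal(tab@c, sum(!exp_flag & ev_flag))
    expect_equal(tab@d, sum(!exp_flag & !ev_flag))
  }
})

test_that("ROR and Wald CI match the closed-form expressions", {
  sym <- computeRor(ct(5, 5, 5, 5))
  expect_identical(sym@ror, 1)
  expect_false(sym@isSignal)

  res <- computeRor(ct(10, 90, 100, 9900))
  expect_equal(res@ror, 11)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(res@ciLow, exp(log(11) - 1.959964 * se))
  expect_equal(res@ciHigh, exp(log(11) + 1.959964 * se))
  expect_true(res@isSignal)
})

test_that("zero cells give undefined results or a flagged correction", {
  und <- computeRor(ct(0, 10, 10, 100))
  expect_true(is.na(und@ror))
  expect_false(und@isSignal)

  hal <- computeRor(ct(0, 10, 10, 100), zeroCell = "haldane")
  expect_true(hal@corrected)
  expect_equal(hal@ror, (0.5 * 100.5) / (10.5 * 10.5))
  # the report-count condition uses the uncorrected a
  expect_false(hal@isSignal)

  a1 <- computeRor(ct(1, 1, 1, 1000), zeroCell = "haldane")
  expect_false(a1@corrected)
  expect_false(a1@isSignal)  # a = 1 < 2 even if CI excludes 1

  expect_error(new("ContingencyTable", a = -1L, b = 1L, c = 1L, d = 1L),
               "negative")
})

test_that("ROR equals the exact cross-product ratio on all small tables", {
  cells <- 1:6
  for (a in cells) for (b in cells) for (c in cells) for (d in cells) {
    res <- computeRor(ct(a, b, c, d))
    expect_identical(res@ror, (a * d) / (b * c))
  }
})

test_that("ROR is antisymmetric and monotone in a", {
  withr::with_seed(99, {
    for (i in 1:50) {
      cells <- sample(1:40, 4, replace = TRUE)
      fwd <- computeRor(ct(cells[1], cells[2], cells[3], cells[4]))
      rev <- computeRor(ct(cells[3], cells[4], cells[1], cells[2]))
      expect_equal(rev@ror, 1 / fwd@ror)
      up <- computeRor(ct(cells[1] + 1, cells[2], cells[3], cells[4]))
      expect_gt(up@ror, fwd@ror)
    }
  })
})

test_that("event scans are complete, thresholded and deterministically sorted", {
  st <- make_store(
    drugs_by_report = list(R1 = c(d = "PS"), R2 = c(d = "PS"),
                           R3 = c(d = "PS"), R4 = c(x = "PS"),
                           R5 = c(x = "PS")),
    events_by_report = list(R1 = c("e1", "e2"), R2 = "e1", R3 = "e3",
                            R4 = "e1", R5 = "e4"))
  res <- scanEvents(st, "d", "PT")
  expect_setequal(res$event, c("e1", "e2", "e3"))  # e4 never co-reported
  res2 <- scanEvents(st, "d", "PT", minA = 2L)
  expect_equal(res2$event, "e1")

  # stable ordering across runs
  expect_identical(res, scanEvents(st, "d", "PT"))
  finite_part <- res$ror[!is.na(res$ror)]
  expect_true(all(diff(finite_part) <= 0))
  expect_true(all(is.na(res$ror[seq_along(res$ror) > length(finite_part)])))
})

test_that("SOC-level scans aggregate preferred terms through the map", {
  st <- make_store(
    drugs_by_report = list(R1 = c(d = "PS"), R2 = c(d = "PS"),
                           R3 = c(x = "PS"), R4 = c(x = "PS")),
    events_by_report = list(R1 = "pt1", R2 = "pt2", R3 = "pt3"))
  map <- c(pt1 = "SOC_A", pt2 = "SOC_A", pt3 = "SOC_B")
  mapped <- applyTermMap(st, map)
  tab <- buildTable(mapped, "d", "SOC_A", "SOC")
  expect_equal(tab@a, 2L)
  expect_error(buildTable(st, "d", "SOC_A", "SOC"), "applyTermMap")
})

test_that("an injected association dominates the scan in most replicates", {
  hits <- vapply(1:20, function(s) {
    sim <- simulateReports(nReports = 4000, seed = 1000 + s)
    store <- filterByRole(deduplicate(sim$store), "PS")
    res <- scanEvents(store, "montelukast", "PT")
    res$event[which.max(res$ror)] == "suicidal ideation"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("signal TSVs serialize undefined values as NA", {
  st <- make_store(
    drugs_by_report = list(R1 = c(d = "PS"), R2 = c(x = "PS")),
    events_by_report = list(R1 = "e1", R2 = "e2"))
  res <- scanEvents(st, "d", "PT")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSignals(res, path)
  back <- read.delim(path)
  expect_true(any(is.na(back$ror)))
  expect_equal(nrow(back), nrow(res))
})
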