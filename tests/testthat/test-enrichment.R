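make_collection <- function(sets, kind = "pathway") {
  new("GeneSetCollection", sets = sets,
      termNames = paste(names(sets), "name"), kind = kind)
}

test_that("GMT files parse with per-line sets and strict validation", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tfirst set\tA\tB\tC",
               "S2\tsecond set\tD\tE\tF\tG\tH"), p)
  coll <- readGmt(p)
  expect_equal(lengths(coll@sets), c(S1 = 3L, S2 = 5L))

  writeLines("S1\trepeat gene\tA\ta\tB", p)
  expect_equal(lengths(readGmt(p)@sets), c(S1 = 2L))

  writeLines(c("S1\tx\tA", "S1\ty\tB"), p)
  expect_error(readGmt(p), "duplicated term")
  writeLines("S1\tonly two fields", p)
  expect_error(readGmt(p), "fewer than 3")
})

test_that("disease TSVs gather per-disease gene sets", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dis.tsv")
  writeLines(c("disease_id\tdisease_name\tgene",
               "D1\tmood disorders\tHTR2A",
               "D1\tmood disorders\tHCRT",
               "D2\tpneumonia\tIL13"), p)
  coll <- readDiseaseTsv(p)
  expect_equal(coll@kind, "disease")
  expect_setequal(coll@sets$D1, c("HTR2A", "HCRT"))
  expect_equal(coll@termNames[match("D2", names(coll@sets))], "pneumonia")
})

test_that("hypergeometric upper tails match exact combinatorial arithmetic", {
  expect_identical(hypergeomUpper(0, 5, 5, 20), 1)
  expect_equal(hypergeomUpper(5, 5, 5, 20), 1 / choose(20, 5))

  # exact rational summation of the mass function for every N <= 12
  exact_upper <- function(k, K, n, N) {
    i <- k:min(n, K)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
  }
  for (N in 2:12) for (K in 0:N) for (n in 0:N) {
    for (k in 0:min(n, K)) {
      expect_equal(hypergeomUpper(k, K, n, N), exact_upper(k, K, n, N),
                   tolerance = 1e-12)
    }
  }
  expect_error(hypergeomUpper(6, 5, 5, 20), "bounds")
  expect_error(hypergeomUpper(1, 5, 5, 4), "bounds")
})

test_that("BH adjustment reproduces the hand-evaluated step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  # step-up with monotonicity enforcement, by hand:
  # sorted (0.005, 0.04, 0.04), m/i scaling (0.015, 0.06, 0.04),
  # cummin from the top -> (0.015, 0.04, 0.04)
  expect_equal(bhAdjust(c(0.04, 0.005, 0.04)), c(0.04, 0.015, 0.04))

  withr::with_seed(8, {
    p <- runif(50)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p & adj <= 1))
  })
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("perfect-overlap queries rank their set first; disjoint queries vanish", {
  coll <- make_collection(list(HIT = c("A", "B", "C"),
                               OTHER = c("D", "E", "F"),
                               PART = c("A", "G", "H")))
  res <- enrich(c("a", "b", "c"), coll)
  expect_equal(res$term_id[1], "HIT")
  expect_equal(res$k[res$term_id == "HIT"], 3L)
  expect_equal(res$N[1], 8L)
  # minimal achievable p for this query size
  expect_equal(res$p[1], 1 / choose(8, 3) * choose(5, 0))

  empty <- enrich(c("D", "E"), make_collection(list(S = c("A", "B"))),
                  universe = c("A", "B", "D", "E"))
  expect_equal(nrow(empty), 0L)

  expect_warning(out <- enrich("ZZZ", coll), "universe")
  expect_equal(attr(out, "n_query_in_universe"), 0L)
  expect_error(enrich(character(0), coll), "empty query")
})

test_that("BH spans all tested terms and survives term permutation", {
  sets <- list(S1 = c("A", "B", "C", "D"), S2 = c("C", "D", "E", "F"),
               S3 = c("G", "H"), S4 = c("A", "H", "I", "J"))
  coll <- make_collection(sets)
  res <- enrich(c("A", "B", "C"), coll)
  perm <- make_collection(sets[c(3, 1, 4, 2)])
  res_perm <- enrich(c("A", "B", "C"), perm)
  expect_equal(res[order(res$term_id), ],
               res_perm[order(res_perm$term_id), ],
               ignore_attr = TRUE)
  # adjusted over all 4 tested terms, not only the 3 reported ones
  expect_equal(res$p_adj, p.adjust(res$p, method = "BH", n = 4))
})

test_that("adding a matching gene to the query never increases a term's p", {
  coll <- make_collection(list(S = sprintf("G%02d", 1:10)))
  universe <- sprintf("G%02d", 1:40)
  p_prev <- 1
  for (i in 1:6) {
    res <- enrich(sprintf("G%02d", 1:i), coll, universe = universe)
    expect_lte(res$p[1], p_prev + 1e-15)
    p_prev <- res$p[1]
  }
})

test_that("the hypergeometric test holds its size under the null", {
  # one term, query drawn uniformly from the universe; the achieved level
  # of the discrete test at alpha = 0.05 is computed analytically first
  N <- 500L; K <- 100L; n <- 80L
  alpha_achieved <- {
    ks <- 0:n
    surv <- vapply(ks, function(k) hypergeomUpper(k, K, n, N), numeric(1))
    kstar <- min(ks[surv <= 0.05])
    1 - stats::phyper(kstar - 1, K, N - K, n)
  }
  expect_gt(alpha_achieved, 0.03)   # parameters give a near-continuous test
  universe <- sprintf("U%04d", seq_len(N))
  coll <- make_collection(list(TERM = universe[seq_len(K)]))
  hits <- withr::with_seed(271828, {
    vapply(seq_len(1000), function(i) {
      k <- sum(sample(universe, n) %in% coll@sets$TERM)
      hypergeomUpper(k, K, n, N) <= 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("Storey q-values never exceed the BH values", {
  withr::with_seed(4, {
    sets <- lapply(1:30, function(i) sample(sprintf("G%03d", 1:200), 20))
    names(sets) <- sprintf("S%02d", 1:30)
    coll <- make_collection(sets)
    q_bh <- enrich(sprintf("G%03d", 1:25), coll)
    q_st <- enrich(sprintf("G%03d", 1:25), coll, qMethod = "storey")
    m <- match(q_st$term_id, q_bh$term_id)
    expect_true(all(q_st$q <= q_bh$q[m] + 1e-12))
  })
})
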