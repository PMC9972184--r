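test_that("normalize_profile rescales each rank independently and is idempotent", {
  p <- two_rank_profile(c(A = 50, B = 25), omit_superkingdom = TRUE)
  n <- normalize_profile(p)
  expect_equal(sort(n$entries$percentage), c(100 / 3, 200 / 3),
               tolerance = 1e-9)
  # idempotence
  expect_equal(normalize_profile(n)$entries$percentage, n$entries$percentage)
  # support conservation
  expect_equal(sort(n$entries$taxid), sort(p$entries$taxid))
  # per-rank independence: superkingdom {X:50}, phylum {A:10, B:10}
  rows <- data.frame(
    taxid = c("2", "A", "B"), rank = c("superkingdom", "phylum", "phylum"),
    taxpath = c("2", "2|A", "2|B"), taxpathsn = c("B", "B|A", "B|B"),
    percentage = c(50, 10, 10))
  q <- normalize_profile(taxonomic_profile("S1", rows,
                                           ranks = c("superkingdom", "phylum")))
  expect_equal(q$entries$percentage, c(100, 50, 50))
  # already-normalized rank unchanged
  r <- two_rank_profile(c(A = 60, B = 40), omit_superkingdom = TRUE)
  expect_equal(normalize_profile(r)$entries$percentage, c(60, 40))
})

test_that("filter_low_abundance drops strictly-below entries, keeps at-threshold", {
  p <- two_rank_profile(c(A = 5, B = 0.5), omit_superkingdom = TRUE)
  expect_equal(filter_low_abundance(p, 1)$entries$taxid, "A")
  expect_equal(nrow(filter_low_abundance(p, 0)$entries), 2)
  q <- two_rank_profile(c(A = 1.0), omit_superkingdom = TRUE)
  expect_equal(filter_low_abundance(q, 1.0)$entries$taxid, "A")
})

test_that("the comparison tree takes the union of lineages across sources", {
  t1 <- two_rank_profile(c(`1224` = 100), label = "tool1")
  t2 <- two_rank_profile(c(`1224` = 100), label = "tool2")
  tree <- build_comparison_tree(profile_set(list(t1, t2)))
  expect_equal(nrow(tree$nodes) - 1, 2)  # Bacteria + phylum 1224
  expect_equal(unname(tree$abundance["1224", ]), c(100, 100))

  # disjoint predictions both appear, zero where absent
  ta <- two_rank_profile(c(A = 100), label = "tool1")
  tb <- two_rank_profile(c(B = 100), label = "truth2")
  tree <- build_comparison_tree(profile_set(list(ta), truth = tb))
  expect_equal(unname(tree$abundance["A", ]), c(100, 0))
  expect_equal(unname(tree$abundance["B", ]), c(0, 100))
  expect_equal(tree$sources, c("tool1", "truth"))
})

test_that("missing ancestors are imputed as the sum of present descendants and flagged", {
  p <- two_rank_profile(c(A = 40, B = 30), omit_superkingdom = TRUE,
                        label = "tool1")
  tree <- build_comparison_tree(profile_set(list(p)))
  expect_equal(unname(tree$abundance["2", "tool1"]), 70)  # oracle: 40 + 30
  expect_true(tree$imputed["2", "tool1"])
  expect_false(tree$imputed["A", "tool1"])
  # a reported ancestor is NOT overwritten by its children's sum
  q <- two_rank_profile(c(A = 40, B = 30), label = "tool1")  # sk row = 70
  q$entries$percentage[q$entries$rank == "superkingdom"] <- 90
  tree <- build_comparison_tree(profile_set(list(q)))
  expect_equal(unname(tree$abundance["2", "tool1"]), 90)
  expect_false(tree$imputed["2", "tool1"])
})

test_that("rank_limit prunes the tree but keeps deep profilers' mass above", {
  # profile reporting only phylum rows, limited to superkingdom
  p <- two_rank_profile(c(A = 40, B = 30), omit_superkingdom = TRUE,
                        label = "tool1")
  tree <- build_comparison_tree(profile_set(list(p)),
                                opts = comparison_options(rank_limit = "superkingdom"))
  expect_equal(tree$rank_order, "superkingdom")
  expect_false("A" %in% tree$nodes$taxid)
  expect_equal(unname(tree$abundance["2", "tool1"]), 70)
  expect_error(
    build_comparison_tree(profile_set(list(p)),
                          opts = comparison_options(rank_limit = "genus")),
    "unknown rank")
})

test_that("incompatible rank orders and empty unions are errors", {
  a <- two_rank_profile(c(A = 1))
  b <- two_rank_profile(c(B = 1))
  b$ranks <- c("phylum", "superkingdom")
  expect_error(build_comparison_tree(profile_set(list(a, b))),
               "incompatible rank orders")
  empty <- taxonomic_profile("S1", ranks = c("superkingdom", "phylum"))
  expect_error(build_comparison_tree(profile_set(list(empty))),
               "empty union")
})

test_that("assess_nodes classifies TP/FP/FN per the support definitions", {
  tool <- two_rank_profile(c(A = 100), label = "tool1")
  truth <- two_rank_profile(c(A = 100))
  tree <- build_comparison_tree(profile_set(list(tool), truth = truth))
  a <- assess_nodes(tree)
  expect_equal(a["A", "status"], "TP")
  expect_equal(a["A", "relative_error"], 0)
  expect_false(a["A", "highlighted"])

  tool <- two_rank_profile(c(A = 50), label = "tool1")
  truth <- two_rank_profile(c(B = 100))
  tree <- build_comparison_tree(profile_set(list(tool), truth = truth))
  a <- assess_nodes(tree)
  expect_equal(a["A", "status"], "FP")
  expect_equal(a["B", "status"], "FN")

  # tool 50 vs truth 100: TP, relative error 0.5, highlighted at 30 (strict)
  tool <- two_rank_profile(c(A = 50), label = "tool1")
  truth <- two_rank_profile(c(A = 100))
  tree <- build_comparison_tree(profile_set(list(tool), truth = truth))
  a <- assess_nodes(tree, comparison_options(highlight_threshold = 30))
  expect_equal(a["A", "status"], "TP")
  expect_equal(a["A", "relative_error"], 0.5)
  expect_true(a["A", "highlighted"])
  a50 <- assess_nodes(tree, comparison_options(highlight_threshold = 50))
  expect_false(a50["A", "highlighted"])  # |50-100| = 50 is not > 50

  expect_error(assess_nodes(build_comparison_tree(profile_set(list(tool)))),
               "truth")
})

test_that("multi-tool relative error uses the mean of tool abundances", {
  t1 <- two_rank_profile(c(A = 40), label = "tool1")
  t2 <- two_rank_profile(c(A = 80), label = "tool2")
  truth <- two_rank_profile(c(A = 100))
  tree <- build_comparison_tree(profile_set(list(t1, t2), truth = truth))
  a <- assess_nodes(tree)
  expect_equal(a["A", "relative_error"], abs(mean(c(40, 80)) - 100) / 100)
})

test_that("highlight_pairwise uses strict percentage-point inequality", {
  mk <- function(a, b) {
    t1 <- two_rank_profile(c(A = a), label = "tool1")
    t2 <- two_rank_profile(c(A = b), label = "tool2")
    build_comparison_tree(profile_set(list(t1, t2)))
  }
  opts <- comparison_options(highlight_threshold = 30)
  expect_true("A" %in% highlight_pairwise(mk(60, 29), opts))   # diff 31
  expect_false("A" %in% highlight_pairwise(mk(60, 30), opts))  # diff exactly 30
  expect_length(highlight_pairwise(mk(50, 50), comparison_options(
    highlight_threshold = 0)), 0)
  t1 <- two_rank_profile(c(A = 1), label = "only")
  expect_error(highlight_pairwise(build_comparison_tree(profile_set(list(t1)))),
               "at least 2")
})

test_that("l1_error matches hand computation and input validation works", {
  t1 <- two_rank_profile(c(A = 60, B = 40), label = "tool1")
  t2 <- two_rank_profile(c(A = 50, B = 50), label = "tool2")
  tree <- build_comparison_tree(profile_set(list(t1, t2)))
  expect_equal(l1_error(tree, "tool1", "tool2", "phylum"), 20)  # |60-50|+|40-50|
  expect_equal(l1_error(tree, "tool1", "tool1", "phylum"), 0)
  expect_error(l1_error(tree, "tool1", "nope", "phylum"), "unknown source")
  expect_error(l1_error(tree, "tool1", "tool2", "genus"), "unknown rank")
})

test_that("abundance_summary is deterministic, ordered, and carries statuses", {
  spec <- synthetic_spec(seed = 3)
  td <- generate_taxdump(spec)
  gp <- generate_profile_set(spec, td$db, n_tools = 2)
  tree <- build_comparison_tree(gp$set, td$db)
  s1 <- abundance_summary(tree)
  expect_true(all(c("taxid", "rank", "name", "tool1", "tool2", "truth",
                    "status", "relative_error", "highlighted") %in% names(s1)))
  expect_equal(nrow(s1), nrow(tree$nodes) - 1)
  # ordering: rank blocks in rank order, descending truth abundance inside
  ri <- match(s1$rank, tree$rank_order)
  expect_true(!is.unsorted(ri))
  for (r in unique(s1$rank)) {
    expect_true(!is.unsorted(-s1$truth[s1$rank == r]))
  }
  # serialized twice -> byte identical
  f1 <- tempfile(); f2 <- tempfile()
  write_summary_tsv(s1, f1)
  write_summary_tsv(abundance_summary(tree), f2)
  expect_identical(readLines(f1), readLines(f2))
  # statuses match the generator's injection record
  expect_equal(sort(s1$taxid[s1$status == "FP"]), gp$record$expected_fp)
  expect_equal(sort(s1$taxid[s1$status == "FN"]), gp$record$expected_fn)
})

test_that("l1_error behaves as a metric at a fixed rank on random triples", {
  set.seed(99)
  for (rep in 1:25) {
    abund <- matrix(stats::runif(9, 0, 50), nrow = 3)
    ps <- lapply(1:3, function(i) {
      v <- abund[i, ]; names(v) <- c("A", "B", "C")
      two_rank_profile(v, label = paste0("tool", i))
    })
    tree <- build_comparison_tree(profile_set(ps))
    d <- function(a, b) l1_error(tree, a, b, "phylum")
    expect_equal(d("tool1", "tool2"), d("tool2", "tool1"))
    expect_gte(d("tool1", "tool2") + d("tool2", "tool3") -
                 d("tool1", "tool3"), -1e-9)
    expect_equal(d("tool1", "tool1"), 0)
  }
})
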