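test_that("a minimal CAMI block parses to one profile", {
  f <- write_lines_tmp(cami_lines())
  ps <- read_cami_profiles(f)
  expect_length(ps, 1)
  p <- ps[[1]]
  expect_s3_class(p, "taxonomic_profile")
  expect_equal(p$sample_id, "S1")
  expect_equal(p$ranks, c("superkingdom", "phylum"))
  expect_equal(nrow(p$entries), 1)
  expect_equal(p$entries$taxid, "2")
  expect_equal(p$entries$percentage, 100.0)
})

test_that("concatenated sample blocks parse in file order", {
  f <- write_lines_tmp(c(cami_lines("S1"), cami_lines("S2")))
  ps <- read_cami_profiles(f)
  expect_equal(vapply(ps, function(p) p$sample_id, character(1)),
               c("S1", "S2"))
})

test_that("parser tolerates CRLF endings, trailing whitespace, comments, case", {
  lines <- c("# a comment", "@sampleid:S1", "@RANKS:superkingdom|phylum", "",
             "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
             "2\tsuperkingdom\t2\tBacteria\t60.0   ",
             "1224\tphylum\t2|1224\tBacteria|Proteobacteria\t60.0")
  f <- tempfile()
  writeLines(paste0(lines, "\r"), f, sep = "\n")
  p <- read_cami_profiles(f)[[1]]
  expect_equal(p$sample_id, "S1")
  expect_equal(p$entries$percentage, c(60, 60))
})

test_that("malformed input produces format errors naming the line", {
  # data row before any @@ line
  f <- write_lines_tmp(c("@SampleID:S1", "2\tsuperkingdom\t2\tBacteria\t100"))
  expect_error(read_cami_profiles(f), "line 2.*@@")
  # too few fields
  f <- write_lines_tmp(cami_lines(rows = "2\tsuperkingdom\t100"))
  expect_error(read_cami_profiles(f), "5 tab-separated")
  # non-numeric percentage
  f <- write_lines_tmp(cami_lines(rows = "2\tsuperkingdom\t2\tBacteria\tlots"))
  expect_error(read_cami_profiles(f), "PERCENTAGE")
  # wrong column set
  f <- write_lines_tmp(c("@SampleID:S1", "@@TAXID\tRANK\tPERCENTAGE"))
  expect_error(read_cami_profiles(f), "column header")
})

test_that("extra columns and duplicate rows are tolerated with warnings", {
  lines <- c("@SampleID:S1", "@Ranks:superkingdom",
             "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE\tCOMMENT",
             "2\tsuperkingdom\t2\tBacteria\t40\tx",
             "2\tsuperkingdom\t2\tBacteria\t20\ty")
  f <- write_lines_tmp(lines)
  expect_warning(expect_warning(ps <- read_cami_profiles(f),
                                "extra column"),
                 "duplicate")
  expect_equal(ps[[1]]$entries$percentage, 60)
})

test_that("fraction-scale abundances warn but are stored as given", {
  f <- write_lines_tmp(cami_lines(rows = "2\tsuperkingdom\t2\tBacteria\t0.9"))
  expect_warning(p <- read_cami_profiles(f)[[1]], "fraction")
  expect_equal(p$entries$percentage, 0.9)
})

test_that("write-then-read is the identity on profiles", {
  phyla <- c(`1224` = 60.123456, `1239` = 39.876544)
  p <- two_rank_profile(phyla)
  f <- tempfile()
  write_cami_profile(p, f)
  q <- read_cami_profiles(f)[[1]]
  expect_equal(q$sample_id, p$sample_id)
  expect_equal(q$ranks, p$ranks)
  expect_equal(nrow(q$entries), nrow(p$entries))
  m <- match(paste(p$entries$taxid, p$entries$rank),
             paste(q$entries$taxid, q$entries$rank))
  expect_false(anyNA(m))
  expect_equal(q$entries$percentage[m], p$entries$percentage,
               tolerance = 1e-6)
  expect_equal(q$entries$taxpath[m], p$entries$taxpath)
})

test_that("an empty profile round-trips as a header-only block", {
  p <- taxonomic_profile("S1", ranks = c("superkingdom", "phylum"))
  f <- tempfile()
  write_cami_profile(p, f)
  q <- read_cami_profiles(f)[[1]]
  expect_equal(q$sample_id, "S1")
  expect_equal(nrow(q$entries), 0)
})

test_that("profile invariants are enforced", {
  expect_error(taxonomic_profile("S", data.frame(
    taxid = "2", rank = "phylum", taxpath = "2", taxpathsn = "B",
    percentage = -1)), "negative")
  expect_error(taxonomic_profile("S", data.frame(
    taxid = "2", rank = "kingdom", taxpath = "2", taxpathsn = "B",
    percentage = 1), ranks = c("superkingdom", "phylum")), "rank")
  expect_error(profile_set(list()), "1 and 3")
})

test_that("select_sample picks by id, defaults to a sole profile, errors helpfully", {
  ps <- list(taxonomic_profile("S1"), taxonomic_profile("S2"))
  expect_equal(select_sample(ps, "S2")$sample_id, "S2")
  expect_equal(select_sample(ps[1], "")$sample_id, "S1")
  expect_error(select_sample(ps, "S9"), "S1")
  expect_error(select_sample(ps, ""), "S1, S2")
})

write_biom_json <- function(rows, data, shape, matrix_type = "dense",
                            columns = list(list(id = "S1", metadata = NULL))) {
  f <- tempfile(fileext = ".biom")
  j <- list(id = "t", format = "Biological Observation Matrix 1.0.0",
            format_url = "http://biom-format.org", type = "OTU table",
            generated_by = "test", date = "2020-01-01T00:00:00",
            matrix_type = matrix_type, matrix_element_type = "int",
            shape = shape, rows = rows, columns = columns, data = data)
  jsonlite::write_json(j, f, auto_unbox = TRUE, null = "null")
  f
}

biom_row <- function(id, lineage) {
  list(id = id, metadata = list(taxonomy = as.list(lineage)))
}

test_that("BIOM: single observation normalizes to 100%", {
  f <- write_biom_json(list(biom_row("o1", "Bacteria")),
                       data = list(list(10L)), shape = c(1L, 1L))
  p <- read_biom_profile(f)
  expect_equal(nrow(p$entries), 1)
  expect_equal(p$entries$rank, "superkingdom")
  expect_equal(p$entries$percentage, 100)
})

test_that("BIOM: observations sharing a lineage are merged", {
  f <- write_biom_json(list(biom_row("o1", "Bacteria"),
                            biom_row("o2", "Bacteria")),
                       data = list(list(3L), list(7L)), shape = c(2L, 1L))
  p <- read_biom_profile(f)
  expect_equal(nrow(p$entries), 1)
  expect_equal(p$entries$percentage, 100)
})

test_that("BIOM: distinct phyla split by count share", {
  f <- write_biom_json(
    list(biom_row("o1", c("Bacteria", "Proteobacteria")),
         biom_row("o2", c("Bacteria", "Firmicutes"))),
    data = list(list(25L), list(75L)), shape = c(2L, 1L))
  p <- read_biom_profile(f)
  ph <- p$entries[p$entries$rank == "phylum", ]
  expect_equal(sort(ph$percentage), c(25, 75))
  sk <- p$entries[p$entries$rank == "superkingdom", ]
  expect_equal(sk$percentage, 100)
  # mass conservation per rank
  expect_equal(sum(ph$percentage), 100, tolerance = 1e-6)
})

test_that("BIOM: taxids resolve by scientific name against a taxonomy", {
  db <- load_tiny()
  f <- write_biom_json(list(biom_row("o1", c("Bacteria", "Proteobacteria"))),
                       data = list(list(5L)), shape = c(1L, 1L))
  p <- read_biom_profile(f, db = db)
  ph <- p$entries[p$entries$rank == "phylum", ]
  expect_equal(ph$taxid, "1224")
  expect_equal(ph$taxpath, "2|1224")
})

test_that("BIOM: missing taxonomy metadata and zero totals are errors", {
  f <- write_biom_json(list(biom_row("o1", "Bacteria"),
                            list(id = "o2", metadata = NULL)),
                       data = list(list(1L), list(1L)), shape = c(2L, 1L))
  expect_error(read_biom_profile(f), "o2")
  f <- write_biom_json(list(biom_row("o1", "Bacteria")),
                       data = list(list(0L)), shape = c(1L, 1L))
  expect_error(read_biom_profile(f), "zero total")
})
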