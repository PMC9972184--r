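# In-code fixtures shared across test files.

# minimal well-formed CAMI block(s) as a character vector of lines
cami_lines <- function(sample_id = "S1",
                       ranks = "superkingdom|phylum",
                       rows = "2\tsuperkingdom\t2\tBacteria\t100.0") {
  c(sprintf("@SampleID:%s", sample_id),
    "@Version:0.9.1",
    sprintf("@Ranks:%s", ranks),
    "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
    rows)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".profile")
  writeLines(lines, f)
  f
}

# hand-built 3-node taxdump: root 1, superkingdom 2 (Bacteria),
# phylum 1224 (Proteobacteria) under 2; optional merged 666 -> 2
tiny_taxdump <- function(merged = FALSE, extra_nodes = NULL,
                         extra_names = NULL) {
  dir <- tempfile("dump")
  dir.create(dir)
  nodes <- c("1\t|\t1\t|\tno rank\t|",
             "2\t|\t1\t|\tsuperkingdom\t|",
             "1224\t|\t2\t|\tphylum\t|",
             extra_nodes)
  names <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
             "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
             "2\t|\teubacteria\t|\t\t|\tsynonym\t|",
             "1224\t|\tProteobacteria\t|\t\t|\tscientific name\t|",
             extra_names)
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names, file.path(dir, "names.dmp"))
  if (merged) writeLines("666\t|\t2\t|", file.path(dir, "merged.dmp"))
  dir
}

load_tiny <- function(merged = FALSE, ...) {
  dir <- tiny_taxdump(merged = merged, ...)
  load_taxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"),
               if (merged) file.path(dir, "merged.dmp"))
}

# build a two-rank profile directly from a named phylum abundance vector;
# superkingdom row is the sum unless omit_superkingdom
two_rank_profile <- function(phyla, sample_id = "S1", label = sample_id,
                             omit_superkingdom = FALSE) {
  rows <- data.frame(taxid = names(phyla), rank = "phylum",
                     taxpath = paste0("2|", names(phyla)),
                     taxpathsn = paste0("Bacteria|P", names(phyla)),
                     percentage = unname(phyla), stringsAsFactors = FALSE)
  if (!omit_superkingdom) {
    rows <- rbind(data.frame(taxid = "2", rank = "superkingdom",
                             taxpath = "2", taxpathsn = "Bacteria",
                             percentage = sum(phyla),
                             stringsAsFactors = FALSE),
                  rows)
  }
  taxonomic_profile(sample_id, rows, ranks = c("superkingdom", "phylum"),
                    source_label = label)
}

# brute-force classification oracle: support-set algebra straight off the
# profiles (taxids of positive entries plus their TAXPATH ancestors),
# independent of the comparison-tree code path
brute_force_status <- function(set, eps = 1e-9) {
  support <- function(p) {
    e <- p$entries[p$entries$percentage > eps, , drop = FALSE]
    ids <- character()
    for (tp in e$taxpath) {
      seg <- strsplit(tp, "|", fixed = TRUE)[[1]]
      ids <- c(ids, seg[nzchar(seg)])
    }
    unique(ids)
  }
  pred <- unique(unlist(lapply(set$profiles, support)))
  truth <- support(set$truth)
  list(TP = sort(intersect(pred, truth)),
       FP = sort(setdiff(pred, truth)),
       FN = sort(setdiff(truth, pred)))
}
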