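# Merging profiles onto a shared taxonomy tree and quantifying agreement.

#' Options controlling profile comparison
#'
#' @param rank_limit Optional rank name; nodes deeper than it are excluded
#'   from the comparison tree (the tree is still built and ancestor abundance
#'   imputed on the full rank order first, so leaf-only profilers keep their
#'   mass at upper ranks).
#' @param min_abundance Percentage threshold; entries strictly below it are
#'   dropped before merging (entries exactly at the threshold are kept).
#'   Default 0 (keep everything).
#' @param highlight_threshold Percentage-point difference above which a clade
#'   is highlighted; strict inequality ("exceeds"). Default 30.
#' @param normalize Rescale each profile's percentages to sum to 100 within
#'   each rank before merging. Default `FALSE`.
#' @param epsilon Absence tolerance: abundances at or below it count as
#'   absent when classifying taxa. Default 1e-9 (profilers emit float noise).
#' @return An object of class `comparison_options`.
#' @export
comparison_options <- function(rank_limit = NULL, min_abundance = 0,
                               highlight_threshold = 30, normalize = FALSE,
                               epsilon = 1e-9) {
  stopifnot(min_abundance >= 0, highlight_threshold >= 0, epsilon >= 0)
  structure(list(rank_limit = rank_limit, min_abundance = min_abundance,
                 highlight_threshold = highlight_threshold,
                 normalize = normalize, epsilon = epsilon),
            class = "comparison_options")
}

#' Normalize a profile's percentages within each rank
#'
#' Within each rank independently, percentages are rescaled to sum to 100;
#' ranks with zero total are left untouched. Idempotent; support (the set of
#' reported taxa) is preserved.
#'
#' @param profile A [taxonomic_profile].
#' @return The rescaled profile.
#' @export
normalize_profile <- function(profile) {
  e <- profile$entries
  if (nrow(e) > 0) {
    for (r in unique(e$rank)) {
      sel <- e$rank == r
      tot <- sum(e$percentage[sel])
      if (tot > 0) e$percentage[sel] <- e$percentage[sel] * 100 / tot
    }
    profile$entries <- e
  }
  profile
}

#' Drop low-abundance entries from a profile
#'
#' Entries with percentage strictly below `min_abundance` are removed;
#' entries exactly at the threshold are kept.
#'
#' @param profile A [taxonomic_profile].
#' @param min_abundance Non-negative percentage threshold.
#' @return The filtered profile.
#' @export
filter_low_abundance <- function(profile, min_abundance) {
  stopifnot(min_abundance >= 0)
  e <- profile$entries
  profile$entries <- e[e$percentage >= min_abundance, , drop = FALSE]
  rownames(profile$entries) <- NULL
  profile
}

#' Merge a profile set into a comparison tree
#'
#' The union of all lineages across sources (tool profiles first, then
#' `"truth"` when present) forms a single taxonomy tree. Every node carries
#' one abundance per source: the source's reported percentage at that taxon,
#' or, for ancestors a source implies but never reports, the sum of that
#' source's abundances over the node's children (imputed, and flagged as
#' such). Sources that lack a taxon entirely carry 0 there.
#'
#' @param set A [profile_set].
#' @param db Optional [taxonomy_db]; when given, taxids are merged-resolved
#'   and ranks/names are taken from the taxonomy (which wins over TAXPATH on
#'   conflict, with a warning).
#' @param opts A [comparison_options].
#' @return An object of class `comparison_tree`: `nodes` (data frame with
#'   `taxid`, `rank`, `name`, `parent_id`, `depth`), `abundance` and
#'   `imputed` matrices (taxid x source), `sources`, `rank_order`, `root_id`,
#'   `has_truth`.
#' @export
build_comparison_tree <- function(set, db = NULL,
                                  opts = comparison_options()) {
  stopifnot(inherits(set, "profile_set"))
  profiles <- set$profiles
  all_profiles <- c(profiles, if (!is.null(set$truth)) list(set$truth))
  if (isTRUE(opts$normalize)) all_profiles <- lapply(all_profiles, normalize_profile)
  if (opts$min_abundance > 0) {
    all_profiles <- lapply(all_profiles, filter_low_abundance, opts$min_abundance)
  }
  sources <- c(vapply(profiles, function(p) p$source_label, character(1),
                      USE.NAMES = FALSE),
               if (!is.null(set$truth)) "truth")
  if (anyDuplicated(sources)) {
    sources <- make.unique(sources, sep = "_")
  }

  # merged rank order: every profile's ranks must be a subsequence of the
  # longest declared rank list
  lens <- vapply(all_profiles, function(p) length(p$ranks), integer(1))
  rank_order <- all_profiles[[which.max(lens)]]$ranks
  for (p in all_profiles) {
    idx <- match(p$ranks, rank_order)
    if (anyNA(idx) || is.unsorted(idx, strictly = TRUE)) {
      stop("incompatible rank orders: '", paste(p$ranks, collapse = "|"),
           "' vs '", paste(rank_order, collapse = "|"), "'")
    }
  }

  root_id <- if (!is.null(db)) db$root_id else "__root__"
  parent <- c(stats::setNames(root_id, root_id))
  rank <- c(stats::setNames(NA_character_, root_id))
  name <- c(stats::setNames("root", root_id))
  direct <- lapply(seq_along(sources), function(i) numeric(0))

  register <- function(tid, rk, nm, par) {
    if (!tid %in% names(parent)) {
      parent[[tid]] <<- par
      rank[[tid]] <<- rk
      name[[tid]] <<- nm
    }
  }

  for (s in seq_along(all_profiles)) {
    p <- all_profiles[[s]]
    e <- p$entries
    for (i in seq_len(nrow(e))) {
      lin <- lineage_from_taxpath(e$taxpath[i], e$taxpathsn[i], p$ranks, db)
      par <- root_id
      for (j in seq_len(nrow(lin))) {
        register(lin$taxid[j], lin$rank[j], lin$name[j], par)
        par <- lin$taxid[j]
      }
      leaf <- lin$taxid[nrow(lin)]
      cur <- direct[[s]]
      cur[leaf] <- (if (leaf %in% names(cur)) cur[[leaf]] else 0) + e$percentage[i]
      direct[[s]] <- cur
    }
  }
  taxids <- names(parent)
  if (length(taxids) <= 1) stop("empty union: no taxa found in any profile")

  depth_of <- function(tid) {
    d <- 0L
    while (tid != root_id) { d <- d + 1L; tid <- parent[[tid]] }
    d
  }
  depth <- vapply(taxids, depth_of, integer(1))

  ab <- matrix(0, nrow = length(taxids), ncol = length(sources),
               dimnames = list(taxids, sources))
  imp <- matrix(FALSE, nrow = length(taxids), ncol = length(sources),
                dimnames = list(taxids, sources))
  children <- split(taxids[taxids != root_id],
                    factor(parent[taxids != root_id], levels = taxids))
  # bottom-up: direct value if reported, else sum over children (imputed)
  for (tid in taxids[order(depth, decreasing = TRUE)]) {
    kids <- children[[tid]]
    for (s in seq_along(sources)) {
      if (tid %in% names(direct[[s]])) {
        ab[tid, s] <- direct[[s]][[tid]]
      } else if (!is.null(kids) && length(kids) > 0) {
        v <- sum(ab[kids, s])
        ab[tid, s] <- v
        imp[tid, s] <- v > 0
      }
    }
  }

  # rank restriction is applied after imputation so deep-only profilers
  # keep their mass at the retained ranks
  rank_order_used <- rank_order
  if (!is.null(opts$rank_limit)) {
    li <- match(tolower(trim(opts$rank_limit)), rank_order)
    if (is.na(li)) {
      stop("unknown rank_limit '", opts$rank_limit, "'; declared ranks: ",
           paste(rank_order, collapse = ", "))
    }
    rank_order_used <- rank_order[seq_len(li)]
    keep <- taxids == root_id | rank[taxids] %in% rank_order_used
    taxids <- taxids[keep]
    ab <- ab[taxids, , drop = FALSE]
    imp <- imp[taxids, , drop = FALSE]
    depth <- depth[taxids]
    # reattach orphaned nodes to their nearest retained ancestor
    for (tid in taxids) {
      par <- parent[[tid]]
      while (!par %in% taxids) par <- parent[[par]]
      parent[[tid]] <- par
    }
  }

  nodes <- data.frame(taxid = taxids,
                      rank = unname(rank[taxids]),
                      name = unname(name[taxids]),
                      parent_id = unname(unlist(parent[taxids])),
                      depth = unname(depth),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- nodes$taxid
  structure(list(nodes = nodes, abundance = ab, imputed = imp,
                 sources = sources, rank_order = rank_order_used,
                 root_id = root_id, has_truth = !is.null(set$truth)),
            class = "comparison_tree")
}

#' @export
print.comparison_tree <- function(x, ...) {
  cat(sprintf("<comparison_tree> %d taxa, sources: %s, ranks: %s\n",
              nrow(x$nodes) - 1L, paste(x$sources, collapse = ", "),
              paste(x$rank_order, collapse = "|")))
  invisible(x)
}

tool_columns <- function(tree) {
  if (tree$has_truth) tree$sources[-length(tree$sources)] else tree$sources
}

#' Classify each clade against the ground truth
#'
#' Requires a `"truth"` source. Per non-root node: `FP` when some tool
#' reports positive abundance but the truth does not; `FN` when the truth is
#' positive and every tool reports zero; `TP` when both are positive;
#' `both-absent` otherwise. Presence is abundance strictly above
#' `opts$epsilon`. For TP nodes the relative error is
#' `|mean(tool abundances) - truth| / truth`; a node is highlighted when the
#' largest tool-vs-truth difference strictly exceeds
#' `opts$highlight_threshold` percentage points.
#'
#' @param tree A [build_comparison_tree()] result whose set included a truth
#'   profile.
#' @param opts A [comparison_options].
#' @return A data frame (one row per non-root taxid) with columns `taxid`,
#'   `status`, `relative_error` (NA for non-TP), `highlighted`.
#' @export
assess_nodes <- function(tree, opts = comparison_options()) {
  if (!tree$has_truth) {
    stop("assess_nodes requires a ground-truth source in the comparison tree")
  }
  taxids <- setdiff(rownames(tree$abundance), tree$root_id)
  tools <- tree$abundance[taxids, tool_columns(tree), drop = FALSE]
  truth <- tree$abundance[taxids, "truth"]
  eps <- opts$epsilon
  tool_present <- apply(tools > eps, 1, any)
  truth_present <- truth > eps
  status <- ifelse(truth_present & tool_present, "TP",
            ifelse(truth_present, "FN",
            ifelse(tool_present, "FP", "both-absent")))
  rel_err <- rep(NA_real_, length(taxids))
  tp <- status == "TP"
  rel_err[tp] <- abs(rowMeans(tools[tp, , drop = FALSE]) - truth[tp]) / truth[tp]
  maxdiff <- apply(abs(tools - truth), 1, max)
  data.frame(taxid = taxids, status = status, relative_error = rel_err,
             highlighted = maxdiff > opts$highlight_threshold,
             stringsAsFactors = FALSE, row.names = taxids)
}

#' Clades whose sources disagree beyond a threshold
#'
#' Returns the taxids where the maximum pairwise absolute difference between
#' source abundances (in percentage points) strictly exceeds
#' `opts$highlight_threshold`. A difference exactly equal to the threshold is
#' never highlighted.
#'
#' @param tree A comparison tree with at least two sources.
#' @param opts A [comparison_options].
#' @return Character vector of taxids.
#' @export
highlight_pairwise <- function(tree, opts = comparison_options()) {
  if (length(tree$sources) < 2) {
    stop("highlight_pairwise needs at least 2 sources")
  }
  taxids <- setdiff(rownames(tree$abundance), tree$root_id)
  ab <- tree$abundance[taxids, , drop = FALSE]
  maxdiff <- apply(ab, 1, function(v) max(v) - min(v))
  taxids[maxdiff > opts$highlight_threshold]
}

#' Per-rank L1 error between two sources
#'
#' Sum over all tree nodes at the given rank of the absolute difference
#' between the two sources' percentage abundances. Identical profiles give
#' 0; disjoint per-rank-normalized profiles give 200.
#'
#' @param tree A comparison tree.
#' @param source_a,source_b Source labels present in `tree$sources`.
#' @param rank Rank name present in `tree$rank_order`.
#' @return Non-negative L1 error in percentage points.
#' @export
l1_error <- function(tree, source_a, source_b, rank) {
  rank <- tolower(trim(rank))
  if (!rank %in% tree$rank_order) {
    stop("unknown rank '", rank, "'; tree ranks: ",
         paste(tree$rank_order, collapse = ", "))
  }
  for (s in c(source_a, source_b)) {
    if (!s %in% tree$sources) {
      stop("unknown source '", s, "'; tree sources: ",
           paste(tree$sources, collapse = ", "))
    }
  }
  sel <- !is.na(tree$nodes$rank) & tree$nodes$rank == rank
  ids <- tree$nodes$taxid[sel]
  sum(abs(tree$abundance[ids, source_a] - tree$abundance[ids, source_b]))
}

#' Tabular per-clade abundance report
#'
#' One row per non-root node: taxid, rank, name, one abundance column per
#' source, plus (when a truth source is present) the TP/FP/FN status,
#' relative error and highlight flag from [assess_nodes()]. Rows are ordered
#' by rank order, then descending truth abundance (or first-source abundance
#' without truth), with ties broken by lexicographic taxid, so repeated
#' serializations are identical.
#'
#' @param tree A comparison tree.
#' @param opts A [comparison_options] (classification thresholds).
#' @return A data frame.
#' @export
abundance_summary <- function(tree, opts = comparison_options()) {
  taxids <- setdiff(tree$nodes$taxid, tree$root_id)
  nd <- tree$nodes[taxids, , drop = FALSE]
  out <- data.frame(taxid = nd$taxid, rank = nd$rank, name = nd$name,
                    stringsAsFactors = FALSE)
  for (s in tree$sources) out[[s]] <- unname(tree$abundance[taxids, s])
  sort_ab <- if (tree$has_truth) tree$abundance[taxids, "truth"]
             else tree$abundance[taxids, tree$sources[1]]
  if (tree$has_truth) {
    a <- assess_nodes(tree, opts)[taxids, , drop = FALSE]
    out$status <- a$status
    out$relative_error <- a$relative_error
    out$highlighted <- a$highlighted
  } else if (length(tree$sources) >= 2) {
    out$highlighted <- out$taxid %in% highlight_pairwise(tree, opts)
  }
  ord <- order(match(out$rank, tree$rank_order), -sort_ab, out$taxid)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an abundance summary as deterministic TSV
#'
#' Numeric columns are printed with six decimals so repeated runs are
#' byte-identical.
#'
#' @param summary A data frame from [abundance_summary()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_summary_tsv <- function(summary, file) {
  df <- summary
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), "NA",
                          formatC(df[[col]], format = "f", digits = 6))
    } else if (is.logical(df[[col]])) {
      df[[col]] <- ifelse(df[[col]], "TRUE", "FALSE")
    }
  }
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(file)
}
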