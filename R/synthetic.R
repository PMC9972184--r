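# Synthetic study-condition generator: miniature taxonomy dumps and
# profile sets with a known record of injected and dropped taxa, so the
# whole pipeline is testable without external downloads.

#' Specification for a synthetic taxonomy and profile set
#'
#' Defines a balanced three-rank taxonomy (superkingdom / phylum / class)
#' and the perturbation model used to derive tool profiles from a simulated
#' ground truth: each tool independently drops true taxa (false negatives),
#' injects absent taxa at low abundance (false positives), and reports the
#' rest with multiplicative lognormal noise, after which each rank is
#' renormalized to 100%.
#'
#' Defaults emulate a moderately difficult profiling benchmark: a community
#' of 8 active class-level taxa with symmetric-Dirichlet(1) abundances, 30%
#' per-taxon dropout, 20% spurious-injection probability over absent taxa,
#' and 20% multiplicative noise — error rates in the range reported for
#' shotgun profilers on community benchmarks.
#'
#' @param n_superkingdoms,n_phyla_per,n_classes_per Branching counts of the
#'   balanced taxonomy.
#' @param n_taxa_active Number of class-level taxa with positive truth
#'   abundance.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for truth
#'   abundances.
#' @param dropout_prob Probability a tool omits a true taxon.
#' @param spurious_prob Probability a tool reports a taxon absent from the
#'   truth.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on reported abundances.
#' @param seed Integer seed; all generator randomness flows from it (one
#'   derived stream per tool: tool `t` uses `seed + t`).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_superkingdoms = 2, n_phyla_per = 3,
                           n_classes_per = 3, n_taxa_active = 8,
                           dirichlet_alpha = 1, dropout_prob = 0.3,
                           spurious_prob = 0.2, noise_cv = 0.2, seed = 42) {
  stopifnot(n_superkingdoms >= 1, n_phyla_per >= 1, n_classes_per >= 1,
            n_taxa_active >= 1, dirichlet_alpha > 0,
            dropout_prob >= 0, dropout_prob <= 1,
            spurious_prob >= 0, spurious_prob <= 1, noise_cv >= 0)
  structure(list(n_superkingdoms = n_superkingdoms,
                 n_phyla_per = n_phyla_per, n_classes_per = n_classes_per,
                 n_taxa_active = n_taxa_active,
                 dirichlet_alpha = dirichlet_alpha,
                 dropout_prob = dropout_prob, spurious_prob = spurious_prob,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synthetic_spec")
}

SYNTH_RANKS <- c("superkingdom", "phylum", "class")

#' Generate a miniature taxonomy dump
#'
#' Writes `nodes.dmp` and `names.dmp` in the NCBI dmp dialect for a balanced
#' superkingdom/phylum/class tree with the branching counts in `spec`, and
#' returns the loaded database. Output is deterministic.
#'
#' @param spec A [synthetic_spec].
#' @param out_dir Directory to write the dump into (created if needed).
#' @return A list with `db` (the loaded [taxonomy_db]), `dir`, `nodes_path`,
#'   `names_path`.
#' @export
generate_taxdump <- function(spec, out_dir = tempfile("taxdump")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  taxid <- "1"; parent <- "1"; rank <- "no rank"; name <- "root"
  nxt <- 2L
  for (i in seq_len(spec$n_superkingdoms)) {
    sk <- as.character(nxt); nxt <- nxt + 1L
    taxid <- c(taxid, sk); parent <- c(parent, "1")
    rank <- c(rank, "superkingdom")
    name <- c(name, sprintf("Superkingdom_%d", i))
    for (j in seq_len(spec$n_phyla_per)) {
      ph <- as.character(nxt); nxt <- nxt + 1L
      taxid <- c(taxid, ph); parent <- c(parent, sk)
      rank <- c(rank, "phylum")
      name <- c(name, sprintf("Phylum_%d_%d", i, j))
      for (k in seq_len(spec$n_classes_per)) {
        cl <- as.character(nxt); nxt <- nxt + 1L
        taxid <- c(taxid, cl); parent <- c(parent, ph)
        rank <- c(rank, "class")
        name <- c(name, sprintf("Class_%d_%d_%d", i, j, k))
      }
    }
  }
  nodes_path <- file.path(out_dir, "nodes.dmp")
  names_path <- file.path(out_dir, "names.dmp")
  writeLines(sprintf("%s\t|\t%s\t|\t%s\t|", taxid, parent, rank), nodes_path)
  writeLines(sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|", taxid, name),
             names_path)
  list(db = load_taxdump(nodes_path, names_path), dir = out_dir,
       nodes_path = nodes_path, names_path = names_path)
}

# abundance map (leaf taxid -> value) propagated to all ancestors by summation
propagate_up <- function(leaf_ab, db) {
  ab <- leaf_ab
  for (tid in names(leaf_ab)) {
    cur <- unname(db$parent[[tid]])
    while (cur != db$root_id) {
      ab[cur] <- (if (cur %in% names(ab)) ab[[cur]] else 0) + leaf_ab[[tid]]
      cur <- unname(db$parent[[cur]])
    }
  }
  ab
}

# per-rank renormalization of an abundance map to sum 100 at every rank
renormalize_map <- function(ab, db) {
  rk <- db$rank[names(ab)]
  for (r in unique(rk)) {
    sel <- rk == r
    tot <- sum(ab[sel])
    if (tot > 0) ab[sel] <- ab[sel] * 100 / tot
  }
  ab
}

map_to_profile <- function(ab, db, sample_id, source_label) {
  if (length(ab) == 0) {
    return(taxonomic_profile(sample_id, NULL, ranks = SYNTH_RANKS,
                             taxonomy_id = "synthetic", version = "0.9.1",
                             source_label = source_label))
  }
  ids <- names(ab)
  ord <- order(match(unname(db$rank[ids]), SYNTH_RANKS), ids)
  ids <- ids[ord]
  rows <- lapply(ids, function(tid) {
    lin <- lineage_of(db, tid, SYNTH_RANKS)
    data.frame(taxid = tid, rank = unname(db$rank[[tid]]),
               taxpath = paste(lin$taxid, collapse = "|"),
               taxpathsn = paste(lin$name, collapse = "|"),
               percentage = unname(ab[[tid]]), stringsAsFactors = FALSE)
  })
  taxonomic_profile(sample_id, do.call(rbind, rows), ranks = SYNTH_RANKS,
                    taxonomy_id = "synthetic", version = "0.9.1",
                    source_label = source_label)
}

support_of <- function(ab) names(ab)[ab > 0]

#' Generate a synthetic profile set with a known perturbation record
#'
#' Truth abundances are drawn symmetric-Dirichlet over the active class-level
#' taxa, scaled to percentages, and propagated up the ranks by summation
#' (every parent equals the sum of its children exactly). Each tool profile
#' is then derived from the truth by per-taxon dropout, spurious injection
#' (abundance uniform in (0, 5]%), multiplicative lognormal noise, upward
#' propagation, and per-rank renormalization (which preserves support, so
#' the record of intended false positives / negatives stays exact).
#'
#' The returned `record` logs, per tool, the leaf-level dropped/injected
#' taxids and the rank-propagated support differences, plus the derived
#' `expected_fp` (taxa any tool reports that the truth lacks — the union of
#' injections) and `expected_fn` (truth taxa no tool reports — the
#' intersection of propagated dropouts), computed by set algebra on the
#' generator's own abundance maps.
#'
#' @param spec A [synthetic_spec].
#' @param db A [taxonomy_db] from [generate_taxdump()] with the same spec.
#' @param n_tools Number of tool profiles to derive (1-3).
#' @param sample_id Sample identifier stamped on every profile.
#' @return A list with `set` (a [profile_set] with truth) and `record`.
#' @export
generate_profile_set <- function(spec, db, n_tools = 2, sample_id = "S1") {
  stopifnot(n_tools >= 1, n_tools <= 3)
  leaves <- names(db$rank)[db$rank == "class"]
  if (spec$n_taxa_active > length(leaves)) {
    stop("n_taxa_active (", spec$n_taxa_active, ") exceeds available class-",
         "level taxa (", length(leaves), ")")
  }
  truth_leaf <- with_seed(spec$seed, {
    active <- sort(sample(leaves, spec$n_taxa_active))
    w <- stats::rgamma(length(active), shape = spec$dirichlet_alpha)
    while (sum(w) == 0) w <- stats::rgamma(length(active), spec$dirichlet_alpha)
    stats::setNames(100 * w / sum(w), active)
  })
  truth_ab <- propagate_up(truth_leaf, db)
  truth_support <- support_of(truth_ab)
  truth_profile <- map_to_profile(truth_ab, db, sample_id, "truth")

  sdlog <- if (spec$noise_cv > 0) sqrt(log1p(spec$noise_cv^2)) else 0
  tools <- vector("list", n_tools)
  rec_tools <- vector("list", n_tools)
  for (t in seq_len(n_tools)) {
    res <- with_seed(spec$seed + t, {
      active <- names(truth_leaf)
      dropped <- active[stats::runif(length(active)) < spec$dropout_prob]
      absent <- setdiff(leaves, active)
      injected <- absent[stats::runif(length(absent)) < spec$spurious_prob]
      kept <- setdiff(active, dropped)
      ab <- truth_leaf[kept]
      if (sdlog > 0 && length(ab) > 0) {
        ab <- ab * stats::rlnorm(length(ab), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
      }
      inj_ab <- stats::setNames(stats::runif(length(injected), 0, 5), injected)
      list(leaf_ab = c(ab, inj_ab), dropped = dropped, injected = injected)
    })
    tool_ab <- renormalize_map(propagate_up(res$leaf_ab, db), db)
    tool_support <- support_of(tool_ab)
    tools[[t]] <- map_to_profile(tool_ab, db, sample_id, sprintf("tool%d", t))
    rec_tools[[t]] <- list(
      dropped_leaves = res$dropped,
      injected_leaves = res$injected,
      dropped = sort(setdiff(truth_support, tool_support)),
      injected = sort(setdiff(tool_support, truth_support)),
      support = tool_support)
  }
  names(rec_tools) <- vapply(tools, function(p) p$source_label, character(1))
  expected_fp <- sort(unique(unlist(lapply(rec_tools, `[[`, "injected"))))
  expected_fn <- sort(Reduce(intersect, lapply(rec_tools, `[[`, "dropped")))
  record <- list(truth_abundance = truth_ab, truth_support = sort(truth_support),
                 tools = rec_tools,
                 expected_fp = expected_fp, expected_fn = expected_fn)
  list(set = profile_set(tools, truth = truth_profile), record = record)
}
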