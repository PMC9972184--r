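# NCBI-style taxonomy dump loading and lineage resolution.

#' Load an NCBI-style taxonomy dump
#'
#' Reads `nodes.dmp` (taxid, parent, rank), `names.dmp` (taxid, name, ...,
#' name class) and optionally `merged.dmp` (old taxid, new taxid) in the
#' NCBI dmp dialect: fields separated by `\t|\t`, rows terminated by `\t|`.
#' Only `names.dmp` rows whose name class is `scientific name` are used;
#' a taxid without one falls back to its taxid string, with a warning.
#' Alternate (non-NCBI) dumps in the same dialect are accepted.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @param merged_path Optional path to `merged.dmp`.
#' @return An object of class `taxonomy_db`: named character vectors
#'   `parent`, `rank`, `name` keyed by taxid, `merged` keyed by old taxid,
#'   and `root_id`.
#' @export
load_taxdump <- function(nodes_path, names_path, merged_path = NULL) {
  nodes <- read_dmp(nodes_path)
  if (length(nodes) == 0) stop("empty nodes.dmp: ", nodes_path)
  taxid <- vapply(nodes, `[`, character(1), 1)
  parent <- vapply(nodes, `[`, character(1), 2)
  rank <- tolower(trim(vapply(nodes, `[`, character(1), 3)))
  names(parent) <- taxid
  names(rank) <- taxid

  undefined <- setdiff(unique(parent), taxid)
  if (length(undefined) > 0) {
    stop("taxid(s) referenced as parent but never defined: ",
         paste(undefined, collapse = ", "))
  }
  root <- taxid[parent == taxid]
  if (length(root) != 1) {
    stop("expected exactly one root (parent == self), found ", length(root))
  }

  # cycle check: iterative depth assignment; a non-converging pass means a loop
  depth <- stats::setNames(rep(NA_integer_, length(taxid)), taxid)
  depth[root] <- 0L
  repeat {
    todo <- names(depth)[is.na(depth)]
    if (length(todo) == 0) break
    ready <- todo[!is.na(depth[parent[todo]])]
    if (length(ready) == 0) {
      stop("taxonomy contains a cycle involving taxid(s): ",
           paste(utils::head(todo, 5), collapse = ", "))
    }
    depth[ready] <- depth[parent[ready]] + 1L
  }

  nm <- stats::setNames(rep(NA_character_, length(taxid)), taxid)
  for (row in read_dmp(names_path)) {
    if (length(row) >= 4 && tolower(trim(row[4])) == "scientific name") {
      nm[row[1]] <- trim(row[2])
    }
  }
  unnamed <- names(nm)[is.na(nm)]
  if (length(unnamed) > 0) {
    warning("no scientific name for taxid(s) ",
            paste(unnamed, collapse = ", "),
            "; falling back to the taxid string", call. = FALSE)
    nm[unnamed] <- unnamed
  }

  merged <- character(0)
  if (!is.null(merged_path)) {
    mrows <- read_dmp(merged_path)
    if (length(mrows) > 0) {
      merged <- stats::setNames(vapply(mrows, `[`, character(1), 2),
                                vapply(mrows, `[`, character(1), 1))
    }
  }
  structure(list(parent = parent, rank = rank, name = nm,
                 merged = merged, root_id = unname(root)),
            class = "taxonomy_db")
}

read_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat(sprintf("<taxonomy_db> %d taxa, root '%s', %d merged ids\n",
              length(x$parent), x$root_id, length(x$merged)))
  invisible(x)
}

#' Resolve a possibly merged (deprecated) taxid to its current id
#'
#' Follows the merged-id map to a fixed point (chained merges are resolved
#' transitively). Does not verify that the result exists in the taxonomy.
#'
#' @param db A [taxonomy_db].
#' @param taxid Taxonomy identifier (string).
#' @return The current taxid.
#' @export
resolve_taxid <- function(db, taxid) {
  taxid <- as.character(taxid)
  seen <- character()
  while (taxid %in% names(db$merged)) {
    if (taxid %in% seen) stop("cyclic merged.dmp chain at taxid ", taxid)
    seen <- c(seen, taxid)
    taxid <- unname(db$merged[[taxid]])
  }
  taxid
}

#' Ranked lineage of a taxid
#'
#' Walks parent pointers from the (merged-resolved) taxid to the root and
#' keeps only nodes whose rank appears in `rank_order`; unranked or
#' undeclared intermediate nodes are dropped. Returned root-most first.
#'
#' @param db A [taxonomy_db].
#' @param taxid Taxonomy identifier.
#' @param rank_order Ranks to keep, root-most first.
#' @return A data frame with columns `taxid`, `rank`, `name`, root-first.
#' @export
lineage_of <- function(db, taxid, rank_order = DEFAULT_RANKS) {
  orig <- as.character(taxid)
  taxid <- resolve_taxid(db, orig)
  if (!taxid %in% names(db$parent)) {
    if (orig %in% names(db$merged)) {
      stop("taxid '", orig, "' is deprecated and its merge target '", taxid,
           "' is unknown to the taxonomy")
    }
    stop("unknown taxid '", orig, "'")
  }
  rank_order <- tolower(trim(rank_order))
  chain <- character()
  cur <- taxid
  repeat {
    chain <- c(cur, chain)
    if (cur == db$root_id) break
    cur <- unname(db$parent[[cur]])
  }
  keep <- db$rank[chain] %in% rank_order
  chain <- chain[keep]
  data.frame(taxid = chain,
             rank = unname(db$rank[chain]),
             name = unname(db$name[chain]),
             stringsAsFactors = FALSE)
}

#' Lineage from a CAMI TAXPATH string
#'
#' Builds a lineage directly from the `|`-separated `TAXPATH`/`TAXPATHSN`
#' columns. Empty placeholder segments (`||`, marking unknown intermediate
#' ranks) are skipped, with ranks assigned by position against the declared
#' rank order. When a taxonomy database is supplied, each taxid is
#' merged-resolved and its rank and name are cross-checked; on conflict the
#' database wins and a warning names both values.
#'
#' @param taxpath `|`-separated root-to-taxon taxid list.
#' @param taxpathsn Parallel `|`-separated scientific-name list (may be
#'   empty).
#' @param ranks Declared rank order of the profile (positions of `taxpath`
#'   segments map onto it).
#' @param db Optional [taxonomy_db].
#' @return A data frame with columns `taxid`, `rank`, `name`, root-first.
#' @export
lineage_from_taxpath <- function(taxpath, taxpathsn = "", ranks = DEFAULT_RANKS,
                                 db = NULL) {
  ids <- trim(strsplit(as.character(taxpath), "|", fixed = TRUE)[[1]])
  if (length(ids) == 0 || !any(nzchar(ids))) {
    stop("empty TAXPATH")
  }
  nms <- trim(strsplit(as.character(taxpathsn), "|", fixed = TRUE)[[1]])
  length(nms) <- length(ids)   # pad with NA if shorter
  nms[is.na(nms)] <- ""
  ranks <- tolower(trim(ranks))
  pos <- which(nzchar(ids))
  if (max(pos) > length(ranks)) {
    stop("TAXPATH has ", max(pos), " segments but only ", length(ranks),
         " ranks are declared")
  }
  out <- data.frame(taxid = ids[pos], rank = ranks[pos],
                    name = ifelse(nzchar(nms[pos]), nms[pos], ids[pos]),
                    stringsAsFactors = FALSE)
  if (!is.null(db)) {
    for (i in seq_len(nrow(out))) {
      tid <- resolve_taxid(db, out$taxid[i])
      if (!tid %in% names(db$parent)) next
      db_rank <- unname(db$rank[[tid]])
      db_name <- unname(db$name[[tid]])
      if (db_rank %in% ranks && !identical(db_rank, out$rank[i])) {
        warning("taxid ", tid, ": TAXPATH implies rank '", out$rank[i],
                "' but the taxonomy says '", db_rank, "'; using the taxonomy",
                call. = FALSE)
        out$rank[i] <- db_rank
      }
      if (nzchar(nms[pos][i]) && !identical(db_name, out$name[i])) {
        warning("taxid ", tid, ": TAXPATHSN name '", out$name[i],
                "' differs from the taxonomy's '", db_name,
                "'; using the taxonomy", call. = FALSE)
      }
      out$name[i] <- db_name
      out$taxid[i] <- tid
    }
  }
  out
}
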