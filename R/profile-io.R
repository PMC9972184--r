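# Reading, validating and writing taxonomic profiles
# (CAMI/Bioboxes profiling format and BIOM 1.0 JSON).

#' Canonical taxonomic rank order
#'
#' The eight ranks conventionally declared in the `@Ranks` header of a
#' CAMI/Bioboxes profile, root-most first. Used as the default whenever a
#' profile does not declare its own rank list.
#' @export
DEFAULT_RANKS <- c("superkingdom", "phylum", "class", "order",
                   "family", "genus", "species", "strain")

CAMI_COLUMNS <- c("TAXID", "RANK", "TAXPATH", "TAXPATHSN", "PERCENTAGE")

#' Construct a taxonomic profile
#'
#' A taxonomic profile is one sample's per-taxon relative abundances (in
#' percent, 0-100 scale) together with the lineage strings that place each
#' taxon on the taxonomy tree.
#'
#' @param sample_id Sample identifier (string).
#' @param entries A data frame with columns `taxid`, `rank`, `taxpath`,
#'   `taxpathsn`, `percentage`. `taxpath`/`taxpathsn` are `|`-separated
#'   root-to-taxon identifier/name lists; empty segments mark unknown
#'   intermediate ranks.
#' @param ranks Ordered rank names covering every entry's rank.
#' @param taxonomy_id Free-text taxonomy version tag (`@TaxonomyID` header).
#' @param version Format version tag (`@Version` header).
#' @param source_label Display name of the profiler that produced the profile;
#'   defaults to the sample id.
#' @return An object of class `taxonomic_profile`.
#' @export
taxonomic_profile <- function(sample_id, entries = NULL, ranks = DEFAULT_RANKS,
                              taxonomy_id = "", version = "",
                              source_label = sample_id) {
  if (is.null(entries) || nrow(entries) == 0) {
    entries <- data.frame(taxid = character(), rank = character(),
                          taxpath = character(), taxpathsn = character(),
                          percentage = numeric(), stringsAsFactors = FALSE)
  }
  needed <- c("taxid", "rank", "taxpath", "taxpathsn", "percentage")
  if (!all(needed %in% names(entries))) {
    stop("profile entries must have columns ", paste(needed, collapse = ", "))
  }
  entries <- entries[, needed, drop = FALSE]
  entries$taxid <- as.character(entries$taxid)
  entries$rank <- tolower(trim(as.character(entries$rank)))
  entries$taxpath <- as.character(entries$taxpath)
  entries$taxpathsn <- as.character(entries$taxpathsn)
  entries$percentage <- as.numeric(entries$percentage)
  rownames(entries) <- NULL
  ranks <- tolower(trim(ranks))
  p <- structure(list(sample_id = as.character(sample_id),
                      ranks = ranks,
                      taxonomy_id = as.character(taxonomy_id),
                      version = as.character(version),
                      entries = entries,
                      source_label = as.character(source_label)),
                 class = "taxonomic_profile")
  validate_profile(p)
}

validate_profile <- function(p) {
  e <- p$entries
  if (nrow(e) > 0) {
    if (any(e$percentage < 0)) {
      stop("profile '", p$sample_id, "': negative percentage abundance")
    }
    bad <- setdiff(unique(e$rank), p$ranks)
    if (length(bad) > 0) {
      stop("profile '", p$sample_id, "': entry rank(s) not in declared rank ",
           "order: ", paste(bad, collapse = ", "))
    }
    key <- paste(e$taxid, e$rank)
    if (anyDuplicated(key)) {
      stop("profile '", p$sample_id, "': duplicate (taxid, rank) keys: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    }
  }
  p
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat(sprintf("<taxonomic_profile> sample '%s' (%s): %d entries over ranks %s\n",
              x$sample_id, x$source_label, nrow(x$entries),
              paste(x$ranks, collapse = "|")))
  invisible(x)
}

#' Bundle tool profiles with an optional ground truth
#'
#' @param profiles List of 1-3 [taxonomic_profile] objects (profiler outputs).
#' @param truth Optional [taxonomic_profile] holding the gold-standard
#'   composition of the same sample.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(profiles, truth = NULL) {
  if (inherits(profiles, "taxonomic_profile")) profiles <- list(profiles)
  if (length(profiles) < 1 || length(profiles) > 3) {
    stop("a profile set holds between 1 and 3 tool profiles, got ",
         length(profiles))
  }
  ok <- vapply(profiles, inherits, logical(1), "taxonomic_profile")
  if (!all(ok)) stop("all elements of 'profiles' must be taxonomic_profile")
  if (!is.null(truth) && !inherits(truth, "taxonomic_profile")) {
    stop("'truth' must be a taxonomic_profile or NULL")
  }
  structure(list(profiles = profiles, truth = truth), class = "profile_set")
}

#' Read CAMI/Bioboxes profiling files
#'
#' Parses one or more `@SampleID` blocks from a profile file in the
#' CAMI/Bioboxes profiling format: `@`-prefixed header lines
#' (`@SampleID`, `@Version`, `@Ranks`, `@TaxonomyID`), a `@@`-prefixed
#' column header declaring `TAXID RANK TAXPATH TAXPATHSN PERCENTAGE`, and
#' tab-separated data rows. Comment lines (`#`) and blank lines are skipped;
#' Windows line endings and trailing whitespace are tolerated. Header keys
#' are matched case-insensitively; extra columns beyond the five canonical
#' ones are ignored with a warning; duplicate `(taxid, rank)` rows within a
#' block have their percentages summed, with a warning.
#'
#' @param file Path to a profile file, or a connection.
#' @param source_label Optional display name applied to every parsed profile;
#'   defaults to each profile's sample id.
#' @return A list of [taxonomic_profile] objects, in file order.
#' @export
read_cami_profiles <- function(file, source_label = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("\r$", "", lines)

  profiles <- list()
  cur <- NULL

  new_block <- function() {
    list(sample_id = "", version = "", ranks = NULL, taxonomy_id = "",
         have_cols = FALSE,
         taxid = character(), rank = character(), taxpath = character(),
         taxpathsn = character(), percentage = numeric())
  }

  finalize <- function(b) {
    ranks <- b$ranks %||% DEFAULT_RANKS
    e <- data.frame(taxid = b$taxid, rank = b$rank, taxpath = b$taxpath,
                    taxpathsn = b$taxpathsn, percentage = b$percentage,
                    stringsAsFactors = FALSE)
    key <- paste(e$taxid, e$rank)
    if (anyDuplicated(key)) {
      dups <- unique(key[duplicated(key)])
      warning("sample '", b$sample_id, "': summing duplicate (taxid, rank) ",
              "rows: ", paste(dups, collapse = ", "), call. = FALSE)
      agg <- stats::aggregate(percentage ~ key, data = cbind(e, key = key), sum)
      first <- !duplicated(key)
      e <- e[first, , drop = FALSE]
      e$percentage <- agg$percentage[match(paste(e$taxid, e$rank), agg$key)]
    }
    if (nrow(e) > 0 && all(e$percentage <= 1) && any(e$percentage > 0)) {
      warning("sample '", b$sample_id, "': every abundance is <= 1; values ",
              "look like fractions, but are stored as given (percent scale ",
              "assumed; use normalize_profile() to rescale)", call. = FALSE)
    }
    lbl <- source_label %||% b$sample_id
    taxonomic_profile(b$sample_id, e, ranks = ranks,
                      taxonomy_id = b$taxonomy_id, version = b$version,
                      source_label = lbl)
  }

  for (i in seq_along(lines)) {
    line <- sub("[ \t]+$", "", lines[[i]])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, "@@")) {
      if (is.null(cur)) cur <- new_block()
      cols <- toupper(trim(strsplit(sub("^@@", "", line), "\t", fixed = FALSE)[[1]]))
      if (length(cols) < 5 || !identical(cols[1:5], CAMI_COLUMNS)) {
        stop("line ", i, ": column header must declare exactly ",
             paste(CAMI_COLUMNS, collapse = ", "),
             " (in that order); got '", line, "'")
      }
      if (length(cols) > 5) {
        warning("line ", i, ": ignoring ", length(cols) - 5,
                " extra column(s): ", paste(cols[-(1:5)], collapse = ", "),
                call. = FALSE)
      }
      cur$have_cols <- TRUE
    } else if (startsWith(line, "@")) {
      kv <- sub("^@", "", line)
      if (!grepl(":", kv, fixed = TRUE)) next
      key <- tolower(trim(sub(":.*$", "", kv)))
      val <- trim(sub("^[^:]*:", "", kv))
      if (key == "sampleid") {
        if (!is.null(cur)) profiles[[length(profiles) + 1L]] <- finalize(cur)
        cur <- new_block()
        cur$sample_id <- val
      } else {
        if (is.null(cur)) cur <- new_block()
        if (key == "version") cur$version <- val
        else if (key == "ranks") cur$ranks <- tolower(trim(strsplit(val, "|", fixed = TRUE)[[1]]))
        else if (key == "taxonomyid") cur$taxonomy_id <- val
        # unknown header keys are ignored
      }
    } else {
      if (is.null(cur) || !cur$have_cols) {
        stop("line ", i, ": data row before any '@@' column header line")
      }
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 5) {
        stop("line ", i, ": expected at least 5 tab-separated fields, found ",
             length(fields))
      }
      pct <- suppressWarnings(as.numeric(trim(fields[5])))
      if (is.na(pct)) {
        stop("line ", i, ": PERCENTAGE is not numeric: '", fields[5], "'")
      }
      if (pct < 0) stop("line ", i, ": negative PERCENTAGE: ", pct)
      n <- length(cur$taxid) + 1L
      cur$taxid[n] <- trim(fields[1])
      cur$rank[n] <- tolower(trim(fields[2]))
      cur$taxpath[n] <- trim(fields[3])
      cur$taxpathsn[n] <- trim(fields[4])
      cur$percentage[n] <- pct
    }
  }
  if (!is.null(cur)) profiles[[length(profiles) + 1L]] <- finalize(cur)
  profiles
}

#' Write a profile in the CAMI/Bioboxes profiling format
#'
#' The emitted text re-parses through [read_cami_profiles()] to an equal
#' profile; percentages are printed with six decimals. Rows are ordered by
#' declared rank order, then lexicographic taxid, for reproducible output.
#'
#' @param profile A [taxonomic_profile].
#' @param file Path or connection to write to. Use `append = TRUE` to
#'   concatenate several sample blocks into one file.
#' @param append Append to an existing file rather than overwrite.
#' @return `file`, invisibly.
#' @export
write_cami_profile <- function(profile, file, append = FALSE) {
  stopifnot(inherits(profile, "taxonomic_profile"))
  hdr <- sprintf("@SampleID:%s", profile$sample_id)
  if (nzchar(profile$version)) {
    hdr <- c(hdr, sprintf("@Version:%s", profile$version))
  }
  hdr <- c(hdr, sprintf("@Ranks:%s", paste(profile$ranks, collapse = "|")))
  if (nzchar(profile$taxonomy_id)) {
    hdr <- c(hdr, sprintf("@TaxonomyID:%s", profile$taxonomy_id))
  }
  hdr <- c(hdr, paste0("@@", paste(CAMI_COLUMNS, collapse = "\t")))
  e <- profile$entries
  if (nrow(e) > 0) {
    ord <- order(match(e$rank, profile$ranks), e$taxid)
    e <- e[ord, , drop = FALSE]
    rows <- sprintf("%s\t%s\t%s\t%s\t%s", e$taxid, e$rank, e$taxpath,
                    e$taxpathsn, formatC(e$percentage, format = "f", digits = 6))
  } else {
    rows <- character()
  }
  if (is.character(file)) {
    con <- base::file(file, if (append) "a" else "w")
    on.exit(close(con))
  } else {
    con <- file
  }
  writeLines(c(hdr, rows), con)
  invisible(file)
}

#' Read a BIOM 1.0 JSON table as taxonomic profiles
#'
#' Loads a BIOM 1.0 (JSON) table via the `biomformat` package, sums counts per
#' observation, maps each observation to its lineage (the per-observation
#' metadata list under `taxonomy_key`, ordered root-most first), aggregates
#' counts per (lineage prefix, rank), and converts to percentages of the
#' sample's total count. Ranks are inferred from list position against
#' `ranks`. When a taxonomy database is supplied, lineage names are resolved
#' to taxids by scientific name; otherwise the names themselves serve as
#' identifiers.
#'
#' @param file Path to a BIOM 1.0 JSON file.
#' @param sample_id Sample column to extract; may be empty when the table has
#'   a single sample.
#' @param taxonomy_key Observation-metadata key holding the lineage
#'   (default `"taxonomy"`).
#' @param ranks Declared rank order used to assign ranks by lineage position.
#' @param db Optional [taxonomy_db] used to resolve names to taxids.
#' @param source_label Display name for the resulting profile.
#' @return A [taxonomic_profile] for the selected sample.
#' @export
read_biom_profile <- function(file, sample_id = "", taxonomy_key = "taxonomy",
                              ranks = DEFAULT_RANKS, db = NULL,
                              source_label = NULL) {
  b <- biomformat::read_biom(file)
  m <- as(biomformat::biom_data(b), "matrix")
  obs_ids <- vapply(b$rows, function(r) r$id, character(1))
  samp_ids <- vapply(b$columns, function(s) s$id, character(1))
  # biom_data orientation/labels are unreliable for degenerate shapes;
  # orient observations-on-rows by the declared table shape
  if (nrow(m) != length(obs_ids) || ncol(m) != length(samp_ids)) m <- t(m)
  if (nrow(m) != length(obs_ids) || ncol(m) != length(samp_ids)) {
    stop("BIOM data matrix shape ", nrow(m), "x", ncol(m),
         " does not match declared shape ", length(obs_ids), "x",
         length(samp_ids))
  }
  dimnames(m) <- list(obs_ids, samp_ids)

  om <- biomformat::observation_metadata(b)
  lineages <- extract_lineages(om, obs_ids, taxonomy_key)
  missing <- obs_ids[vapply(lineages, function(x) length(x) == 0, logical(1))]
  if (length(missing) > 0) {
    stop("observation(s) without '", taxonomy_key, "' metadata: ",
         paste(missing, collapse = ", "))
  }

  if (!nzchar(sample_id)) {
    if (length(samp_ids) != 1) {
      stop("BIOM table has ", length(samp_ids), " samples (",
           paste(samp_ids, collapse = ", "), "); specify sample_id")
    }
    sample_id <- samp_ids[1]
  }
  if (!sample_id %in% samp_ids) {
    stop("sample '", sample_id, "' not in BIOM table; available: ",
         paste(samp_ids, collapse = ", "))
  }
  counts <- m[, sample_id]
  total <- sum(counts)
  if (total <= 0) stop("sample '", sample_id, "' has zero total count")

  ranks <- tolower(trim(ranks))
  # aggregate count share per (lineage prefix, rank)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(obs_ids)) {
    lin <- lineages[[i]]
    lin <- lin[nzchar(trim(lin))]
    if (length(lin) == 0) next
    if (length(lin) > length(ranks)) {
      warning("observation '", obs_ids[i], "': lineage deeper than declared ",
              "rank order; truncating", call. = FALSE)
      lin <- lin[seq_along(ranks)]
    }
    for (d in seq_along(lin)) {
      key <- paste(lin[1:d], collapse = "|")
      prev <- if (!is.null(acc[[key]])) acc[[key]]$count else 0
      acc[[key]] <- list(names = lin[1:d], rank = ranks[d],
                         count = prev + counts[i])
    }
  }
  keys <- sort(ls(acc))
  rows <- lapply(keys, function(k) acc[[k]])
  name_to_id <- function(nm) {
    if (is.null(db)) return(nm)
    hit <- names(db$name)[match(nm, db$name)]
    ifelse(is.na(hit), nm, hit)
  }
  e <- do.call(rbind, lapply(rows, function(r) {
    ids <- name_to_id(r$names)
    data.frame(taxid = ids[length(ids)], rank = r$rank,
               taxpath = paste(ids, collapse = "|"),
               taxpathsn = paste(r$names, collapse = "|"),
               percentage = 100 * r$count / total,
               stringsAsFactors = FALSE)
  }))
  taxonomic_profile(sample_id, e, ranks = ranks,
                    taxonomy_id = "biom",
                    source_label = source_label %||% sample_id)
}

# normalize the various shapes biomformat returns for observation metadata
extract_lineages <- function(om, obs_ids, taxonomy_key) {
  get_one <- function(x) {
    if (is.null(x)) return(character())
    if (is.list(x)) {
      if (!is.null(x[[taxonomy_key]])) x <- x[[taxonomy_key]]
      return(as.character(unlist(x)))
    }
    nm <- names(x)
    if (!is.null(nm) && any(startsWith(nm, taxonomy_key))) {
      x <- x[startsWith(nm, taxonomy_key)]
    }
    as.character(x)
  }
  if (is.data.frame(om)) {
    cols <- grep(paste0("^", taxonomy_key), names(om))
    if (length(cols) == 0) {
      return(stats::setNames(rep(list(character()), length(obs_ids)), obs_ids))
    }
    out <- lapply(seq_len(nrow(om)), function(i) {
      v <- as.character(unlist(om[i, cols]))
      v[!is.na(v)]
    })
    names(out) <- rownames(om)
    return(out[obs_ids])
  }
  out <- lapply(om, get_one)
  out[obs_ids]
}

#' Select one sample's profile from a parsed list
#'
#' @param profiles Nonempty list of [taxonomic_profile] objects.
#' @param sample_id Sample to pick; an empty string selects the sole profile
#'   when exactly one is present.
#' @return The matching [taxonomic_profile].
#' @export
select_sample <- function(profiles, sample_id = "") {
  if (length(profiles) == 0) stop("no profiles to select from")
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (!nzchar(sample_id)) {
    if (length(profiles) == 1) return(profiles[[1]])
    stop("multiple samples present; specify one of: ",
         paste(ids, collapse = ", "))
  }
  hit <- which(ids == sample_id)
  if (length(hit) == 0) {
    stop("sample '", sample_id, "' not found; available: ",
         paste(ids, collapse = ", "))
  }
  if (length(hit) > 1) {
    stop("sample '", sample_id, "' matches ", length(hit), " profiles")
  }
  profiles[[hit]]
}
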