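#' Gene-set collections
#'
#' A pathway collection is a tibble with one row per gene set and columns
#' `name` (unique set name), `source` (curation source label), `genes`
#' (list-column of unique gene identifiers) and `provenance` (free-text merge
#' history). All pathway-level analyses in the package take such a tibble.
#'
#' @param name Character vector of set names.
#' @param source Character vector of source labels.
#' @param genes List of character vectors of gene identifiers.
#' @param provenance Optional character vector of notes.
#' @return A `pathway_collection` tibble.
#' @examples
#' pathway_collection("glycolysis", "PID", list(c("HK1", "PFKM", "PKM")))
#' @export
pathway_collection <- function(name, source, genes, provenance = "") {
  check_that(length(name) == length(genes) && length(name) == length(source),
             "name, source and genes must have equal length")
  check_that(all(nzchar(name)), "gene-set names must be non-empty")
  genes <- purrr::map(genes, as.character)
  check_that(all(lengths(genes) >= 1L), "every gene set must contain >= 1 gene")
  dup_in <- purrr::map_int(genes, anyDuplicated) > 0L
  if (any(dup_in)) {
    warn(paste0("duplicate genes within set(s) ",
                paste(name[dup_in], collapse = ", "), "; deduplicated"))
    genes <- purrr::map(genes, unique)
  }
  out <- tibble(
    name = as.character(name),
    source = as.character(source),
    genes = genes,
    provenance = rep_len(as.character(provenance), length(name))
  )
  class(out) <- c("pathway_collection", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' Each GMT line holds a set name, a description (stored as the curation
#' source) and one or more gene identifiers, tab-separated. Duplicate genes
#' within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()] tibble.
#' @export
read_gmt <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  check_that(length(lines) > 0, paste0("empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    abort(paste0("malformed GMT line ", bad[1], " in ", path,
                 ": fewer than 3 tab-separated fields"),
          class = "pathmeta_parse_error")
  }
  pathway_collection(
    name = purrr::map_chr(fields, 1),
    source = purrr::map_chr(fields, 2),
    genes = purrr::map(fields, ~ .x[-(1:2)])
  )
}

#' Write a pathway collection to a GMT file
#'
#' Genes are written in sorted order so that round-trips are stable.
#'
#' @param collection A [pathway_collection()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  check_that(nrow(collection) > 0, "cannot write an empty collection")
  lines <- purrr::pmap_chr(
    list(collection$name, collection$source, collection$genes),
    function(nm, src, gg) paste(c(nm, src, sort(gg)), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

normalize_name <- function(x) tolower(trimws(x))

#' Merge same-name gene sets across curation sources
#'
#' Sets sharing a normalized name (case-insensitive, whitespace-trimmed) are
#' merged into the largest set of the group (the primary). A secondary set
#' contributes its genes only if more than `share_threshold` of its members
#' are already in the primary; otherwise its extra genes are discarded. Merge
#' decisions are recorded in the `provenance` column.
#'
#' @param collection A [pathway_collection()] tibble.
#' @param share_threshold Fraction of a secondary set's genes that must be
#'   shared with the primary for its genes to be absorbed. Default 0.7.
#' @return A merged `pathway_collection` with unique names.
#' @export
merge_same_name <- function(collection, share_threshold = 0.7) {
  key <- normalize_name(collection$name)
  merged <- purrr::map(split(seq_len(nrow(collection)), key), function(idx) {
    rows <- collection[idx, ]
    if (nrow(rows) == 1) return(rows)
    ord <- order(-lengths(rows$genes), rows$source, rows$name)
    rows <- rows[ord, ]
    primary_genes <- rows$genes[[1]]
    notes <- character(0)
    for (j in seq(2, nrow(rows))) {
      sec <- rows$genes[[j]]
      shared <- length(intersect(sec, primary_genes)) / length(sec)
      if (shared > share_threshold) {
        primary_genes <- union(primary_genes, sec)
        notes <- c(notes, sprintf(
          "absorbed %s (%s): shared %.3f > %.2f", rows$name[j],
          rows$source[j], shared, share_threshold))
      } else {
        notes <- c(notes, sprintf(
          "discarded %s (%s): shared %.3f <= %.2f", rows$name[j],
          rows$source[j], shared, share_threshold))
      }
    }
    out <- rows[1, ]
    out$genes <- list(primary_genes)
    out$provenance <- paste(c(out$provenance[out$provenance != ""], notes),
                            collapse = "; ")
    out
  })
  out <- dplyr::bind_rows(merged)
  # restore first-appearance order of the surviving names
  first <- match(unique(key), key)
  out <- out[order(match(normalize_name(out$name),
                         normalize_name(collection$name[first]))), ]
  class(out) <- c("pathway_collection", class(out))
  out
}

#' Enforce a pairwise overlap limit across gene sets
#'
#' Overlap between two sets is `|A ∩ B| / min(|A|, |B|)`. Pairs exceeding
#' `threshold` are reported; with `action = "drop_smaller"` the smaller set of
#' each violating pair (ties broken by dropping the lexicographically later
#' name) is removed, repeatedly, until no violations remain.
#'
#' @param collection A merged [pathway_collection()] tibble.
#' @param threshold Maximum allowed overlap fraction, in (0, 1]. Default 0.7.
#' @param action `"report"` (default; collection returned unchanged) or
#'   `"drop_smaller"`.
#' @return A list with `collection` (the possibly reduced collection) and
#'   `violations` (a tibble with columns `set_a`, `set_b`, `overlap`,
#'   `dropped`).
#' @export
enforce_pairwise_overlap <- function(collection, threshold = 0.7,
                                     action = c("report", "drop_smaller")) {
  action <- match.arg(action)
  check_that(is.numeric(threshold) && threshold > 0 && threshold <= 1,
             "threshold must lie in (0, 1]")
  violations <- tibble(set_a = character(), set_b = character(),
                       overlap = numeric(), dropped = character())
  keep <- collection
  repeat {
    pairs <- pairwise_overlaps(keep)
    viol <- pairs[pairs$overlap > threshold, , drop = FALSE]
    if (nrow(viol) == 0) break
    if (action == "report") {
      viol$dropped <- NA_character_
      violations <- dplyr::bind_rows(violations, viol)
      break
    }
    # drop the smaller set of the worst violating pair, then rescan
    worst <- viol[order(-viol$overlap, viol$set_a, viol$set_b)[1], ]
    na <- lengths(keep$genes[keep$name == worst$set_a])
    nb <- lengths(keep$genes[keep$name == worst$set_b])
    drop_name <- if (na < nb) worst$set_a
      else if (nb < na) worst$set_b
      else max(worst$set_a, worst$set_b)
    worst$dropped <- drop_name
    violations <- dplyr::bind_rows(violations, worst)
    keep <- keep[keep$name != drop_name, ]
  }
  class(keep) <- unique(c("pathway_collection", class(keep)))
  list(collection = keep, violations = violations)
}

pairwise_overlaps <- function(collection) {
  n <- nrow(collection)
  if (n < 2) {
    return(tibble(set_a = character(), set_b = character(),
                  overlap = numeric()))
  }
  idx <- utils::combn(n, 2)
  tibble(
    set_a = collection$name[idx[1, ]],
    set_b = collection$name[idx[2, ]],
    overlap = purrr::map2_dbl(idx[1, ], idx[2, ], function(i, j) {
      a <- collection$genes[[i]]; b <- collection$genes[[j]]
      length(intersect(a, b)) / min(length(a), length(b))
    })
  )
}
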