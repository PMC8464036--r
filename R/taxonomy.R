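#' Load a taxonomy tree
#'
#' Reads a taxonomy in either the NCBI `nodes.dmp`/`names.dmp` dialect
#' (13-column, `"|"`-separated, genetic code id in field 7) or a simplified
#' TSV with columns `taxid, parent_taxid, rank, name[, genetic_code_id]`.
#' The dialect is auto-detected from the separator of the first line.
#'
#' The tree must have exactly one root (a node whose parent is itself) and
#' every parent chain must reach the root: cycles and orphan parents are
#' structural errors.
#'
#' @param nodes_source Path to the nodes file (dmp or TSV).
#' @param names_source Optional path to `names.dmp`; ignored for the TSV
#'   dialect (names are inline there). Scientific names are attached; nodes
#'   missing a name get `"taxid:<id>"`.
#' @return An object of class `taxonomy`: a data frame of nodes plus a
#'   taxid index, usable by [lca()], [ancestor_at_rank()] and the
#'   classification functions.
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL) {
  lines <- readLines(nodes_source)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty taxonomy nodes source")
  if (grepl("|", lines[[1]], fixed = TRUE)) {
    fields <- strsplit(lines, "\t?\\|\t?")
    taxid <- as.integer(vapply(fields, `[`, "", 1L))
    parent <- as.integer(vapply(fields, `[`, "", 2L))
    rank <- trimws(vapply(fields, `[`, "", 3L))
    gcid <- suppressWarnings(as.integer(vapply(fields, function(f)
      if (length(f) >= 7) f[[7]] else NA_character_, "")))
    name <- rep(NA_character_, length(taxid))
    if (!is.null(names_source)) {
      nl <- readLines(names_source)
      nl <- nl[nzchar(nl)]
      nf <- strsplit(nl, "\t?\\|\t?")
      cls <- trimws(vapply(nf, function(f)
        if (length(f) >= 4) f[[4]] else "", ""))
      sci <- nf[cls == "scientific name"]
      nm <- setNames(vapply(sci, `[`, "", 2L), vapply(sci, `[`, "", 1L))
      name <- unname(nm[as.character(taxid)])
    }
  } else {
    # header optional: detect a non-numeric first field
    first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (is.na(suppressWarnings(as.integer(first[[1]])))) lines <- lines[-1]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4)) {
      stop("taxonomy TSV row ", which(nf < 4)[[1]], " has fewer than 4 fields")
    }
    taxid <- as.integer(vapply(fields, `[`, "", 1L))
    parent <- as.integer(vapply(fields, `[`, "", 2L))
    rank <- vapply(fields, `[`, "", 3L)
    name <- vapply(fields, `[`, "", 4L)
    gcid <- suppressWarnings(as.integer(vapply(fields, function(f)
      if (length(f) >= 5) f[[5]] else NA_character_, "")))
  }
  if (anyNA(taxid) || anyNA(parent)) stop("non-integer taxid in nodes source")
  if (anyDuplicated(taxid)) {
    stop("duplicate taxid in nodes source: ",
         taxid[duplicated(taxid)][[1]])
  }
  gcid[is.na(gcid)] <- 1L
  name[is.na(name)] <- paste0("taxid:", taxid[is.na(name)])
  nodes <- data.frame(taxid = taxid, parent_taxid = parent, rank = rank,
                      name = name, genetic_code_id = gcid,
                      stringsAsFactors = FALSE)
  validate_taxonomy(nodes)
}

validate_taxonomy <- function(nodes) {
  root <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(root) != 1) {
    stop("taxonomy must have exactly one root, found ", length(root))
  }
  missing <- setdiff(nodes$parent_taxid, nodes$taxid)
  if (length(missing) > 0) {
    stop("orphan parent taxid(s) not present as nodes: ",
         paste(missing, collapse = ", "))
  }
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$taxid)
  # cycle check: walk each node to the root, bounded by node count
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    cur <- nodes$taxid[[i]]
    steps <- 0L
    while (cur != root) {
      cur <- nodes$parent_taxid[[idx[[as.character(cur)]]]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxid ", nodes$taxid[[i]])
    }
  }
  structure(list(nodes = nodes, index = idx, root = root), class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy tree:", nrow(x$nodes), "nodes, root taxid", x$root, "\n")
  invisible(x)
}

tax_has <- function(taxonomy, taxid) {
  as.character(taxid) %in% names(taxonomy$index)
}

tax_field <- function(taxonomy, taxid, field) {
  taxonomy$nodes[[field]][taxonomy$index[as.character(taxid)]]
}

#' Root path of a taxon
#'
#' @return Integer vector of taxids from the root down to `taxid` (inclusive).
#' @keywords internal
tax_path <- function(taxonomy, taxid) {
  if (!tax_has(taxonomy, taxid)) stop("unknown taxid: ", taxid)
  path <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    path <- c(cur, path)
    if (cur == taxonomy$root) break
    cur <- tax_field(taxonomy, cur, "parent_taxid")
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon.
#'
#' @param taxids Non-empty vector of taxids, all present in the tree.
#' @param taxonomy A `taxonomy` object.
#' @return A single taxid.
#' @examples
#' # lca(c(species1, species2), tax) on two congeneric species returns
#' # their genus
#' @export
lca <- function(taxids, taxonomy) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0) stop("lca() needs at least one taxid")
  paths <- lapply(taxids, tax_path, taxonomy = taxonomy)
  minlen <- min(lengths(paths))
  common <- taxonomy$root
  for (d in seq_len(minlen)) {
    level <- vapply(paths, `[[`, 0L, d)
    if (all(level == level[[1]])) common <- level[[1]] else break
  }
  common
}

#' Ancestor of a taxon at a given rank
#'
#' Walks the path from the root to `taxid` and returns the node whose rank
#' matches, or `NA` when the lineage has no node of that rank (including
#' taxa classified above it).
#'
#' @export
ancestor_at_rank <- function(taxid, rank, taxonomy) {
  path <- tax_path(taxonomy, taxid)
  ranks <- vapply(path, function(t) tax_field(taxonomy, t, "rank"), "")
  hit <- path[ranks == rank]
  if (length(hit) == 0) NA_integer_ else hit[[length(hit)]]
}

#' All descendant taxids of a clade (including the clade itself)
#' @keywords internal
tax_descendants <- function(taxonomy, clade_taxid) {
  if (!tax_has(taxonomy, clade_taxid)) stop("unknown taxid: ", clade_taxid)
  clade_taxid <- as.integer(clade_taxid)
  keep <- clade_taxid
  repeat {
    children <- taxonomy$nodes$taxid[
      taxonomy$nodes$parent_taxid %in% keep &
        !(taxonomy$nodes$taxid %in% keep)]
    if (length(children) == 0) break
    keep <- c(keep, children)
  }
  keep
}

#' Write a taxonomy as the simplified TSV dialect
#' @keywords internal
write_taxonomy_tsv <- function(taxonomy, path) {
  utils::write.table(taxonomy$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
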