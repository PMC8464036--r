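#' Load a reference database bundle
#'
#' Assembles the backbone used by every annotation transfer: reference
#' proteins, their precomputed homologous gene families (GFs), their
#' functional labels (GO / InterPro / KO), and the species taxonomy.
#'
#' @param protein_fasta Path to a protein FASTA file. Sequences may contain
#'   `X` and `U`; `*` characters are stripped with a warning.
#' @param gf_table Path to a TSV with columns `gene_id, gf_id,
#'   species_taxid` (no header). Every reference gene must appear here (a
#'   gene may have an empty `gf_id`, meaning it belongs to no family).
#' @param label_table Path to a TSV with columns `gene_id, namespace,
#'   identifier[, description]` (no header); namespace is one of
#'   `GO`, `InterPro`, `KO`, `RfamGO`.
#' @param taxonomy A `taxonomy` object from [load_taxonomy()].
#' @return An object of class `reference_bundle` with elements `proteins`
#'   (named character vector), `genes` (data frame gene_id / species_taxid /
#'   gf_id / length_aa), `families` (list gf_id -> member gene ids),
#'   `labels` (data frame) and `taxonomy`.
#' @export
load_reference <- function(protein_fasta, gf_table, label_table, taxonomy) {
  aa <- Biostrings::readAAStringSet(protein_fasta)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in protein FASTA: ", ids[duplicated(ids)][[1]])
  }
  seqs <- as.character(aa)
  names(seqs) <- ids
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' characters from reference protein sequences")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty protein sequence: ", ids[nchar(seqs) == 0][[1]])
  }
  gf <- utils::read.table(gf_table, sep = "\t", header = FALSE,
                          colClasses = c("character", "character", "integer"),
                          col.names = c("gene_id", "gf_id", "species_taxid"),
                          na.strings = "", quote = "", comment.char = "")
  unknown <- setdiff(gf$gene_id, ids)
  if (length(unknown) > 0) {
    stop("gene family table references unknown gene id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  missing_sp <- unique(gf$species_taxid[!tax_has(taxonomy, gf$species_taxid)])
  if (length(missing_sp) > 0) {
    stop("species taxid(s) absent from taxonomy: ",
         paste(missing_sp, collapse = ", "))
  }
  no_row <- setdiff(ids, gf$gene_id)
  if (length(no_row) > 0) {
    stop("protein(s) missing from gene family table: ",
         paste(utils::head(no_row, 5), collapse = ", "))
  }
  labels <- read_label_table(label_table)
  unknown_lab <- setdiff(labels$gene_id, ids)
  if (length(unknown_lab) > 0) {
    stop("label table references unknown gene id(s): ",
         paste(utils::head(unknown_lab, 5), collapse = ", "))
  }
  genes <- data.frame(gene_id = gf$gene_id,
                      species_taxid = gf$species_taxid,
                      gf_id = gf$gf_id,
                      length_aa = unname(nchar(seqs[gf$gene_id])),
                      stringsAsFactors = FALSE)
  fam_rows <- genes[!is.na(genes$gf_id), ]
  families <- split(fam_rows$gene_id, fam_rows$gf_id)
  structure(
    list(proteins = seqs, genes = genes, families = families,
         labels = labels, taxonomy = taxonomy),
    class = "reference_bundle"
  )
}

read_label_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(0), namespace = character(0),
                      identifier = character(0), description = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("label table row ", which(nf < 3)[[1]], " has fewer than 3 fields")
  }
  ns <- vapply(fields, `[`, "", 2L)
  bad <- !ns %in% c("GO", "InterPro", "KO", "RfamGO")
  if (any(bad)) {
    stop("label table row ", which(bad)[[1]], " has unknown namespace '",
         ns[bad][[1]], "'")
  }
  data.frame(
    gene_id = vapply(fields, `[`, "", 1L),
    namespace = ns,
    identifier = vapply(fields, `[`, "", 3L),
    description = vapply(fields, function(f)
      if (length(f) >= 4) f[[4]] else "", ""),
    stringsAsFactors = FALSE)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("reference bundle:", length(x$proteins), "proteins,",
      length(x$families), "gene families,",
      length(unique(x$genes$species_taxid)), "species,",
      nrow(x$labels), "label assignments\n")
  invisible(x)
}

#' Species set of a gene family
#' @export
gf_species <- function(bundle, gf_id) {
  members <- bundle$families[[gf_id]]
  if (is.null(members)) stop("unknown gene family: ", gf_id)
  unique(bundle$genes$species_taxid[match(members, bundle$genes$gene_id)])
}

#' Gene family of a gene (NA when family-less)
#' @export
gene_gf <- function(bundle, gene_id) {
  i <- match(gene_id, bundle$genes$gene_id)
  if (anyNA(i)) stop("unknown gene id: ", gene_id[is.na(i)][[1]])
  bundle$genes$gf_id[i]
}

#' Protein length (aa) of a gene
#' @export
gene_length <- function(bundle, gene_id) {
  i <- match(gene_id, bundle$genes$gene_id)
  if (anyNA(i)) stop("unknown gene id: ", gene_id[is.na(i)][[1]])
  bundle$genes$length_aa[i]
}

#' Functional labels of one gene
#' @export
gene_labels <- function(bundle, gene_id) {
  bundle$labels[bundle$labels$gene_id == gene_id, , drop = FALSE]
}

#' Write a reference bundle to a directory
#'
#' Writes the four plain-text components (protein FASTA, gene family TSV,
#' label TSV, taxonomy TSV) so that [read_reference_dir()] round-trips the
#' bundle byte-identically.
#' @export
write_reference_dir <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(bundle$proteins)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"), width = 60)
  utils::write.table(
    bundle$genes[, c("gene_id", "gf_id", "species_taxid")],
    file.path(dir, "gf.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    na = "")
  lab <- bundle$labels
  writeLines(paste(lab$gene_id, lab$namespace, lab$identifier,
                   lab$description, sep = "\t"),
             file.path(dir, "labels.tsv"))
  write_taxonomy_tsv(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

#' Read a reference bundle from a directory written by [write_reference_dir()]
#' @export
read_reference_dir <- function(dir) {
  taxonomy <- load_taxonomy(file.path(dir, "taxonomy.tsv"))
  load_reference(file.path(dir, "proteins.fasta"),
                 file.path(dir, "gf.tsv"),
                 file.path(dir, "labels.tsv"),
                 taxonomy)
}
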