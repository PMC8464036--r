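#' Parse a tabular translated similarity-search result
#'
#' Reads the 12-column BLAST/DIAMOND tabular dialect (`outfmt 6`):
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`. Rows with E-value above the cutoff are discarded
#' (default cutoff 1e-5); remaining rows keep their file order. Plain and
#' gzip-compressed files are both accepted.
#'
#' @param path Path to the hit table.
#' @param evalue_cutoff Maximum E-value retained (default `1e-5`).
#' @return Data frame of hits with the 12 canonical columns; the applied
#'   cutoff is stored in attribute `evalue_cutoff`.
#' @export
parse_hits <- function(path, evalue_cutoff = 1e-5) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0) {
    df <- data.frame(qseqid = character(0), sseqid = character(0),
                     pident = numeric(0), length = integer(0),
                     mismatch = integer(0), gapopen = integer(0),
                     qstart = integer(0), qend = integer(0),
                     sstart = integer(0), send = integer(0),
                     evalue = numeric(0), bitscore = numeric(0),
                     stringsAsFactors = FALSE)
    attr(df, "evalue_cutoff") <- evalue_cutoff
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop("hit table line ", which(nf < 12)[[1]], ": expected 12 fields, got ",
         nf[nf < 12][[1]])
  }
  get <- function(i) vapply(fields, `[`, "", i)
  evalue <- suppressWarnings(as.numeric(get(11)))
  if (anyNA(evalue)) {
    stop("hit table line ", which(is.na(evalue))[[1]], ": non-numeric evalue")
  }
  df <- data.frame(
    qseqid = get(1), sseqid = get(2),
    pident = as.numeric(get(3)), length = as.integer(get(4)),
    mismatch = as.integer(get(5)), gapopen = as.integer(get(6)),
    qstart = as.integer(get(7)), qend = as.integer(get(8)),
    sstart = as.integer(get(9)), send = as.integer(get(10)),
    evalue = evalue, bitscore = as.numeric(get(12)),
    stringsAsFactors = FALSE)
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "evalue_cutoff") <- evalue_cutoff
  df
}

#' Write hits in the 12-column tabular dialect
#' @export
write_hits <- function(hits, path) {
  writeLines(paste(hits$qseqid, hits$sseqid,
                   format_num(hits$pident), hits$length, hits$mismatch,
                   hits$gapopen, hits$qstart, hits$qend, hits$sstart,
                   hits$send, format_num(hits$evalue),
                   format_num(hits$bitscore), sep = "\t"),
             path)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, scientific = abs(v) < 1e-3 && v != 0,
                               trim = TRUE), "")
}

#' Split a hit table by query, preserving file order within groups
#' @export
hits_by_query <- function(hits) {
  split(hits, factor(hits$qseqid, levels = unique(hits$qseqid)))
}

# total top-hit order: lowest evalue, then highest bitscore, then subject id
order_hits <- function(hits) {
  order(hits$evalue, -hits$bitscore, hits$sseqid)
}

#' Select the top similarity hit of one query
#'
#' The best hit under the total order (lowest E-value, then highest
#' bitscore, then subject id lexicographic); all HSPs of the winning
#' query--subject pair are retained for frame analysis.
#'
#' @param hits_of_query Data frame of cutoff-filtered hits of one query.
#' @return A list of class `top_hit` with `query_id`, `hit` (one-row data
#'   frame) and `hsps` (all HSPs of the winning pair), or `NULL` when the
#'   query has no hits.
#' @export
select_top_hit <- function(hits_of_query) {
  if (is.null(hits_of_query) || nrow(hits_of_query) == 0) return(NULL)
  o <- order_hits(hits_of_query)
  best <- hits_of_query[o[[1]], , drop = FALSE]
  hsps <- hits_of_query[hits_of_query$qseqid == best$qseqid &
                          hits_of_query$sseqid == best$sseqid, , drop = FALSE]
  structure(list(query_id = best$qseqid, hit = best, hsps = hsps),
            class = "top_hit")
}

#' Gene family of a top hit
#'
#' The gene family of the top-hit subject is assigned to the transcript;
#' a family-less subject yields no assignment, and transcripts without any
#' protein hit receive neither a family nor transferred annotation.
#'
#' @param top A `top_hit` (or `NULL`).
#' @param bundle A `reference_bundle`.
#' @return The `gf_id` string, or `NA` for a family-less subject or missing
#'   top hit.
#' @export
assign_gf <- function(top, bundle) {
  if (is.null(top)) return(NA_character_)
  gene_gf(bundle, top$hit$sseqid)
}

#' Strand and reading frame implied by a translated-search hit
#'
#' Translated searches report query coordinates such that `qstart > qend`
#' on the minus strand. The frame (1..3) is the position of the alignment
#' start within its codon: on the plus strand
#' `((qstart - 1) mod 3) + 1`, on the minus strand
#' `((query_length - qstart) mod 3) + 1` (the alignment start measured on
#' the reverse complement).
#'
#' @param qstart,qend 1-based inclusive nucleotide coordinates on the query.
#' @param query_length Query length in nt.
#' @return List with `strand` ("+"/"-") and `frame` (integer 1..3).
#' @export
hit_frame <- function(qstart, qend, query_length) {
  stopifnot(qstart >= 1, qend >= 1, qstart <= query_length,
            qend <= query_length)
  qstart <- as.integer(qstart)
  query_length <- as.integer(query_length)
  if (qstart == qend) stop("degenerate hit: qstart == qend")
  if (qstart < qend) {
    list(strand = "+", frame = ((qstart - 1L) %% 3L) + 1L)
  } else {
    list(strand = "-", frame = ((query_length - qstart) %% 3L) + 1L)
  }
}

#' Restrict hits to subjects from a taxonomic clade
#'
#' Subject-side filter implementing a taxonomy-constrained search on parsed
#' results: only hits whose subject gene belongs to a species inside the
#' clade are kept.
#' @export
filter_hits_by_clade <- function(hits, clade_taxid, bundle) {
  species <- tax_descendants(bundle$taxonomy, clade_taxid)
  sp <- bundle$genes$species_taxid[match(hits$sseqid, bundle$genes$gene_id)]
  out <- hits[!is.na(sp) & sp %in% species, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the protein FASTA of a taxonomy-constrained reference subset
#'
#' Pre-filter for running an external aligner against one clade only.
#' @export
write_clade_proteins <- function(bundle, clade_taxid, path) {
  species <- tax_descendants(bundle$taxonomy, clade_taxid)
  keep <- bundle$genes$gene_id[bundle$genes$species_taxid %in% species]
  aa <- Biostrings::AAStringSet(bundle$proteins[keep])
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}
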