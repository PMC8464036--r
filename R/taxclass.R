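#' Classifier configuration
#'
#' Mirrors the MEM-mode protein-level classifier settings: a minimum exact
#' amino-acid match length (default 11) and a low-complexity fragment
#' filter (default on).
#'
#' @param min_match_length Positive integer; matches shorter than this are
#'   ignored (default 11 aa).
#' @param low_complexity_filter Suppress low-complexity translated
#'   fragments before matching (default `TRUE`).
#' @export
classifier_config <- function(min_match_length = 11L,
                              low_complexity_filter = TRUE) {
  stopifnot(min_match_length >= 1)
  structure(list(min_match_length = as.integer(min_match_length),
                 low_complexity_filter = isTRUE(low_complexity_filter)),
            class = "classifier_config")
}

#' Six-frame translated fragments of a transcript
#'
#' Translates a DNA sequence in all six frames and splits each translation
#' at stop codons; the stop-free fragments are the search units for
#' maximal-exact-match classification. Codons containing N translate to X.
#'
#' @param seq DNA string (ACGTN), length >= 3.
#' @param code A `genetic_code` object.
#' @param min_length Fragments shorter than this many aa are dropped
#'   (default 1).
#' @return Data frame with columns `strand` ("+"/"-"), `frame` (1..3),
#'   `fragment` (aa string).
#' @export
six_frame_fragments <- function(seq, code, min_length = 1L) {
  if (!nzchar(seq) || nchar(seq) < 3) stop("sequence must be at least 3 nt")
  if (grepl("[^ACGTNacgtn]", seq)) stop("sequence alphabet must be ACGTN")
  seq <- toupper(seq)
  rc <- revcomp(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (frame in 1:3) {
      aa <- translate_codons(frame_codons(s, frame - 1L), code)
      if (length(aa) == 0) next
      runs <- split_at_stops(aa)
      for (fr in runs) {
        if (nchar(fr) >= min_length) {
          out[[length(out) + 1L]] <- list(strand = strand, frame = frame,
                                          fragment = fr)
        }
      }
    }
  }
  data.frame(
    strand = vapply(out, `[[`, "", "strand"),
    frame = vapply(out, function(x) as.integer(x$frame), 0L),
    fragment = vapply(out, `[[`, "", "fragment"),
    stringsAsFactors = FALSE)
}

# stop-free runs of an amino-acid vector, in order
split_at_stops <- function(aa) {
  s <- paste(aa, collapse = "")
  runs <- strsplit(s, "*", fixed = TRUE)[[1]]
  runs[nzchar(runs)]
}

#' Low-complexity test for a translated fragment
#'
#' A fragment is flagged low-complexity when a single residue makes up more
#' than half of it, or its Shannon entropy falls below 1.5 bits. This is a
#' simple documented stand-in for the masking performed by the `-x` option
#' of MEM classifiers (whose exact filter algorithm is unspecified).
#' @export
is_low_complexity <- function(fragment, max_residue_frac = 0.5,
                              min_entropy_bits = 1.5) {
  chars <- strsplit(fragment, "")[[1]]
  tab <- table(chars)
  p <- as.numeric(tab) / length(chars)
  max(p) > max_residue_frac || -sum(p * log2(p)) < min_entropy_bits
}

all_kmers <- function(strings, k) {
  strings <- strings[nchar(strings) >= k]
  if (length(strings) == 0) return(character(0))
  unlist(lapply(strings, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
}

#' Classify a transcript by maximal exact amino-acid matches
#'
#' Finds the longest exact amino-acid substring shared between any
#' six-frame stop-free fragment of the query and any reference protein.
#' The transcript is assigned to the taxon of the protein(s) achieving that
#' maximum; when several distinct taxa tie at the maximal length, the
#' lowest common ancestor of those taxa is returned. Matches shorter than
#' `cfg$min_match_length` leave the transcript unclassified.
#'
#' @param seq DNA string.
#' @param reference_proteins Named character vector of protein sequences.
#' @param reference_taxids Integer vector of species taxids, parallel to
#'   `reference_proteins`.
#' @param cfg A [classifier_config()].
#' @param taxonomy A `taxonomy` object.
#' @param code Genetic code used for the six-frame translation (default
#'   table 1).
#' @param query_id Identifier copied into the result.
#' @return A one-row data frame: `query_id`, `status` ("classified" /
#'   "unclassified"), `taxid` (NA when unclassified), `match_length` (aa).
#' @export
classify_transcript <- function(seq, reference_proteins, reference_taxids,
                                cfg = classifier_config(), taxonomy,
                                code = get_genetic_code(1),
                                query_id = "query") {
  stopifnot(length(reference_proteins) > 0,
            length(reference_proteins) == length(reference_taxids))
  frags <- six_frame_fragments(seq, code, min_length = cfg$min_match_length)
  frag_seqs <- frags$fragment
  if (cfg$low_complexity_filter && length(frag_seqs) > 0) {
    frag_seqs <- frag_seqs[!vapply(frag_seqs, is_low_complexity, TRUE)]
  }
  unclassified <- data.frame(query_id = query_id, status = "unclassified",
                             taxid = NA_integer_, match_length = 0L,
                             stringsAsFactors = FALSE)
  if (length(frag_seqs) == 0) return(unclassified)
  frag_seqs <- unique(frag_seqs)
  prots <- as.character(reference_proteins)
  m <- cfg$min_match_length
  has_match <- function(k) {
    fk <- unique(all_kmers(frag_seqs, k))
    if (length(fk) == 0) return(FALSE)
    any(fk %in% all_kmers(prots, k))
  }
  if (!has_match(m)) return(unclassified)
  # binary search for the maximal shared substring length
  lo <- m
  hi <- max(nchar(frag_seqs))
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (has_match(mid)) lo <- mid else hi <- mid - 1L
  }
  best <- lo
  fk <- unique(all_kmers(frag_seqs, best))
  hit_prot <- vapply(prots, function(p) {
    pk <- all_kmers(p, best)
    length(pk) > 0 && any(fk %in% pk)
  }, TRUE, USE.NAMES = FALSE)
  taxa <- unique(reference_taxids[hit_prot])
  assigned <- if (length(taxa) == 1) taxa else lca(taxa, taxonomy)
  data.frame(query_id = query_id, status = "classified",
             taxid = as.integer(assigned), match_length = as.integer(best),
             stringsAsFactors = FALSE)
}

#' Classify many transcripts
#'
#' @param seqs Named character vector of DNA sequences.
#' @inheritParams classify_transcript
#' @return Data frame, one row per transcript, in input order.
#' @export
classify_transcripts <- function(seqs, reference_proteins, reference_taxids,
                                 cfg = classifier_config(), taxonomy,
                                 code = get_genetic_code(1)) {
  res <- lapply(seq_along(seqs), function(i) {
    classify_transcript(seqs[[i]], reference_proteins, reference_taxids,
                        cfg, taxonomy, code, query_id = names(seqs)[[i]])
  })
  do.call(rbind, res)
}

#' Merge per-split classification results for one query
#'
#' When the reference index is searched in splits, the per-split results
#' are merged by keeping the strictly longest match; equally long maximal
#' matches from different taxa resolve to their lowest common ancestor.
#' All-unclassified inputs stay unclassified.
#'
#' @param results Data frame of classifications sharing one `query_id`.
#' @param taxonomy A `taxonomy` object.
#' @return One-row classification data frame.
#' @export
merge_split_results <- function(results, taxonomy) {
  if (length(unique(results$query_id)) != 1) {
    stop("merge_split_results() requires results of a single query")
  }
  qid <- results$query_id[[1]]
  hit <- results[results$status == "classified", , drop = FALSE]
  if (nrow(hit) == 0) {
    return(data.frame(query_id = qid, status = "unclassified",
                      taxid = NA_integer_, match_length = 0L,
                      stringsAsFactors = FALSE))
  }
  best <- max(hit$match_length)
  taxa <- unique(hit$taxid[hit$match_length == best])
  assigned <- if (length(taxa) == 1) taxa else lca(taxa, taxonomy)
  data.frame(query_id = qid, status = "classified",
             taxid = as.integer(assigned), match_length = as.integer(best),
             stringsAsFactors = FALSE)
}

#' Parse a Kaiju-style classification file
#'
#' Three tab-separated columns (`C`/`U`, read name, taxid), with an
#' optional fourth column carrying the match length.
#'
#' @param path Path to the file.
#' @return Data frame `query_id, status, taxid, match_length`, input order
#'   preserved.
#' @export
parse_kaiju <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(0), status = character(0),
                      taxid = integer(0), match_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("kaiju line ", which(nf < 3)[[1]], ": fewer than 3 fields")
  }
  st <- vapply(fields, `[`, "", 1L)
  bad <- !st %in% c("C", "U")
  if (any(bad)) {
    stop("kaiju line ", which(bad)[[1]], ": malformed status character '",
         st[bad][[1]], "'")
  }
  taxid <- as.integer(vapply(fields, `[`, "", 3L))
  ml <- vapply(fields, function(f)
    if (length(f) >= 4) suppressWarnings(as.integer(f[[4]])) else 0L, 0L)
  ml[is.na(ml)] <- 0L
  data.frame(
    query_id = vapply(fields, `[`, "", 2L),
    status = ifelse(st == "C", "classified", "unclassified"),
    taxid = ifelse(st == "C", taxid, NA_integer_),
    match_length = ifelse(st == "C", ml, 0L),
    stringsAsFactors = FALSE)
}

#' Summarize classifications at a taxonomic rank
#'
#' Lifts every classified transcript to its ancestor at the requested rank
#' (transcripts classified above the rank, or in a lineage lacking it, are
#' excluded from the depicted set), counts transcripts per clade, keeps at
#' most `top_n` clades, and aggregates both non-top clades and kept clades
#' below `other_floor` of the depicted transcripts into `"Other"`.
#' Unclassified transcripts are counted separately.
#'
#' @param classifications Classification data frame.
#' @param taxonomy A `taxonomy` object.
#' @param rank Rank name present in the taxonomy (e.g. "genus").
#' @param top_n Maximum number of named clades (default 10).
#' @param other_floor Minimum fraction of depicted transcripts for a named
#'   clade (default 0.01).
#' @return List of class `rank_summary`: `clades` (data frame taxid / name /
#'   count), `other`, `excluded`, `unclassified`, `total`.
#' @export
summarize_rank <- function(classifications, taxonomy, rank,
                           top_n = 10L, other_floor = 0.01) {
  if (!rank %in% taxonomy$nodes$rank) stop("unknown rank: ", rank)
  cls <- classifications
  n_total <- nrow(cls)
  n_uncls <- sum(cls$status != "classified")
  hit <- cls[cls$status == "classified", , drop = FALSE]
  lifted <- vapply(hit$taxid, ancestor_at_rank, 0L,
                   rank = rank, taxonomy = taxonomy)
  n_excluded <- sum(is.na(lifted))
  lifted <- lifted[!is.na(lifted)]
  depicted <- length(lifted)
  if (depicted == 0) {
    return(structure(list(
      clades = data.frame(taxid = integer(0), name = character(0),
                          count = integer(0), stringsAsFactors = FALSE),
      other = 0L, excluded = n_excluded, unclassified = n_uncls,
      total = n_total, rank = rank), class = "rank_summary"))
  }
  counts <- sort(table(lifted), decreasing = TRUE)
  taxids <- as.integer(names(counts))
  counts <- as.integer(counts)
  keep <- seq_along(counts) <= top_n & counts / depicted >= other_floor
  clades <- data.frame(
    taxid = taxids[keep],
    name = vapply(taxids[keep], function(t) tax_field(taxonomy, t, "name"), ""),
    count = counts[keep],
    stringsAsFactors = FALSE)
  structure(list(clades = clades, other = sum(counts[!keep]),
                 excluded = n_excluded, unclassified = n_uncls,
                 total = n_total, rank = rank),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat("rank summary (", x$rank, "): ", nrow(x$clades), " named clades, ",
      x$other, " in Other, ", x$excluded, " excluded, ",
      x$unclassified, " unclassified of ", x$total, "\n", sep = "")
  if (nrow(x$clades) > 0) print(x$clades, row.names = FALSE)
  invisible(x)
}

#' Write classifications as a Kaiju-style TSV (plus match length)
#' @export
write_classification_tsv <- function(classifications, path) {
  st <- ifelse(classifications$status == "classified", "C", "U")
  taxid <- ifelse(is.na(classifications$taxid), 0L, classifications$taxid)
  writeLines(paste(st, classifications$query_id, taxid,
                   classifications$match_length, sep = "\t"), path)
}
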