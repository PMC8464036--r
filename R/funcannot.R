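#' Annotation transfer configuration
#'
#' @param source Where transferred labels come from: the top protein hit
#'   (`"best_hit"`), the assigned gene family majority vote (`"gf"`), or
#'   the union of both (`"both"`, default).
#' @param gf_vote_threshold Fraction of family members that must carry a
#'   label for it to transfer (default 0.5, i.e. at least 50%).
#' @export
transfer_config <- function(source = c("both", "gf", "best_hit"),
                            gf_vote_threshold = 0.5) {
  source <- match.arg(source)
  stopifnot(gf_vote_threshold > 0, gf_vote_threshold <= 1)
  structure(list(source = source, gf_vote_threshold = gf_vote_threshold),
            class = "transfer_config")
}

#' Majority-vote labels of a gene family
#'
#' A label transfers from a family when the fraction of family members
#' carrying it (over all members, annotated or not) is at least the
#' threshold.
#'
#' @param gf_id Gene family identifier.
#' @param bundle A `reference_bundle`.
#' @param threshold Vote threshold (default 0.5).
#' @return Data frame `namespace, identifier, description, frequency`.
#' @export
gf_majority_labels <- function(gf_id, bundle, threshold = 0.5) {
  members <- bundle$families[[gf_id]]
  if (is.null(members)) stop("unknown gene family: ", gf_id)
  n <- length(members)
  lab <- bundle$labels[bundle$labels$gene_id %in% members, , drop = FALSE]
  empty <- data.frame(namespace = character(0), identifier = character(0),
                      description = character(0), frequency = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(lab) == 0) return(empty)
  key <- paste(lab$namespace, lab$identifier, sep = "\r")
  per_label <- tapply(lab$gene_id, key, function(g) length(unique(g)))
  freq <- as.numeric(per_label) / n
  keep <- freq >= threshold
  if (!any(keep)) return(empty)
  keys <- names(per_label)[keep]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  desc <- vapply(keys, function(k) {
    i <- which(key == k)[[1]]
    lab$description[[i]]
  }, "", USE.NAMES = FALSE)
  out <- data.frame(
    namespace = vapply(parts, `[`, "", 1L),
    identifier = vapply(parts, `[`, "", 2L),
    description = desc,
    frequency = freq[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$namespace, out$identifier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transfer functional labels to a transcript
#'
#' Labels come from the top-hit subject, the assigned gene family's
#' majority vote, or the union of both; each transferred label is tagged
#' with its provenance (`hit`, `gf`, or `both`). A transcript without a
#' protein hit receives no labels.
#'
#' @param top A `top_hit` or `NULL`.
#' @param gf_id Assigned gene family, or `NA`.
#' @param cfg A [transfer_config()].
#' @param bundle A `reference_bundle`.
#' @return Data frame `namespace, identifier, description, provenance`.
#' @export
transfer_labels <- function(top, gf_id, cfg = transfer_config(), bundle) {
  empty <- data.frame(namespace = character(0), identifier = character(0),
                      description = character(0), provenance = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(top)) return(empty)
  hit_lab <- empty[0, 1:3]
  gf_lab <- empty[0, 1:3]
  if (cfg$source %in% c("best_hit", "both")) {
    h <- gene_labels(bundle, top$hit$sseqid)
    hit_lab <- unique(h[, c("namespace", "identifier", "description"),
                        drop = FALSE])
  }
  if (cfg$source %in% c("gf", "both") && !is.na(gf_id)) {
    g <- gf_majority_labels(gf_id, bundle, cfg$gf_vote_threshold)
    gf_lab <- g[, c("namespace", "identifier", "description"), drop = FALSE]
  }
  key <- function(d) paste(d$namespace, d$identifier, sep = "\r")
  all_lab <- unique(rbind(hit_lab, gf_lab))
  if (nrow(all_lab) == 0) return(empty)
  in_hit <- key(all_lab) %in% key(hit_lab)
  in_gf <- key(all_lab) %in% key(gf_lab)
  all_lab$provenance <- ifelse(in_hit & in_gf, "both",
                               ifelse(in_hit, "hit", "gf"))
  all_lab <- all_lab[order(all_lab$namespace, all_lab$identifier), ,
                     drop = FALSE]
  rownames(all_lab) <- NULL
  all_lab
}

#' Parse Infernal `cmsearch --tblout` output
#'
#' Whitespace-separated records, `#` comment lines skipped. Relevant
#' fields: target name (1), query accession = Rfam family (4), truncation
#' flag (11), bitscore (15), E-value (16).
#'
#' @param path Path to the tblout file.
#' @return Data frame `transcript_id, rfam_id, bitscore, evalue, truncated`.
#' @export
parse_infernal_tblout <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(transcript_id = character(0), rfam_id = character(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      truncated = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 17)) {
    stop("tblout line ", idx[nf < 17][[1]],
         ": expected at least 17 fields, got ", nf[nf < 17][[1]])
  }
  bitscore <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 15L)))
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 16L)))
  if (anyNA(bitscore) || anyNA(evalue)) {
    bad <- which(is.na(bitscore) | is.na(evalue))[[1]]
    stop("tblout line ", idx[[bad]], ": non-numeric score or E-value")
  }
  data.frame(
    transcript_id = vapply(fields, `[`, "", 1L),
    rfam_id = vapply(fields, `[`, "", 4L),
    bitscore = bitscore, evalue = evalue,
    truncated = vapply(fields, `[`, "", 11L),
    stringsAsFactors = FALSE)
}

#' Load an Rfam family -> clan / GO mapping
#'
#' TSV with columns `rfam_id, clan_id, go_id` (one row per family-GO pair;
#' empty clan allowed).
#' @export
load_rfam_map <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    col.names = c("rfam_id", "clan_id", "go_id"),
                    colClasses = "character", na.strings = "",
                    comment.char = "")
}

#' Assign a transcript to its top Rfam family
#'
#' Among the Infernal hits of one transcript, the family with the highest
#' bitscore wins (ties: lower E-value, then accession lexicographic); its
#' clan and curated GO terms are attached from the Rfam mapping. Families
#' absent from the mapping keep their assignment with an empty GO set and
#' a warning.
#'
#' @param hits Data frame of parsed Infernal hits of one transcript.
#' @param rfam_map Data frame from [load_rfam_map()].
#' @return List of class `rna_assignment`: `transcript_id`, `rfam_id`,
#'   `clan_id` (NA if none), `bitscore`, `evalue`, `go_labels` (data frame
#'   namespace/identifier).
#' @export
assign_rfam <- function(hits, rfam_map) {
  stopifnot(nrow(hits) >= 1)
  o <- order(-hits$bitscore, hits$evalue, hits$rfam_id)
  top <- hits[o[[1]], , drop = FALSE]
  rows <- rfam_map[rfam_map$rfam_id == top$rfam_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("Rfam family ", top$rfam_id, " absent from family map; ",
            "no GO terms transferred")
    clan <- NA_character_
    go <- character(0)
  } else {
    clan <- rows$clan_id[[1]]
    go <- unique(rows$go_id[!is.na(rows$go_id)])
  }
  structure(list(
    transcript_id = top$transcript_id,
    rfam_id = top$rfam_id,
    clan_id = clan,
    bitscore = top$bitscore,
    evalue = top$evalue,
    go_labels = data.frame(namespace = rep("GO", length(go)),
                           identifier = go, stringsAsFactors = FALSE)),
    class = "rna_assignment")
}

#' Assign every transcript with Infernal hits to its top Rfam family
#'
#' @param tblout_hits Data frame from [parse_infernal_tblout()].
#' @param rfam_map Data frame from [load_rfam_map()].
#' @param clans Optional character vector of clan ids; when given, only
#'   hits to families belonging to these clans are considered.
#' @return Named list of `rna_assignment` objects, one per transcript.
#' @export
assign_rfam_all <- function(tblout_hits, rfam_map, clans = NULL) {
  if (!is.null(clans)) {
    fams <- unique(rfam_map$rfam_id[rfam_map$clan_id %in% clans])
    tblout_hits <- tblout_hits[tblout_hits$rfam_id %in% fams, , drop = FALSE]
  }
  groups <- split(tblout_hits,
                  factor(tblout_hits$transcript_id,
                         levels = unique(tblout_hits$transcript_id)))
  lapply(groups, assign_rfam, rfam_map = rfam_map)
}

#' Default ubiquitous non-coding RNA clans
#'
#' tRNA, RNase P, SRP RNA, SSU rRNA, LSU rRNA and 5S rRNA.
#' @export
default_rfam_clans <- function() {
  c("CL00001", "CL00002", "CL00003", "CL00111", "CL00112", "CL00113")
}
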