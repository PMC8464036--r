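#' Frame evidence from the HSPs of a top-hit subject
#'
#' Derives strand/frame evidence from the retained HSPs of one query:
#' the chosen frame is that of the highest-bitscore HSP, and a putative
#' frameshift is flagged when two or more distinct frames are observed on
#' the chosen strand (typically HSPs split across a small insertion or
#' deletion). Frames on the opposite strand are recorded as a strand
#' conflict, not a frameshift.
#'
#' @param hsps Data frame of HSPs of one query--subject pair.
#' @param query_length Query length in nt.
#' @return List of class `frame_evidence`: `transcript_id`,
#'   `frames_observed` (data frame strand/frame), `chosen` (list
#'   strand/frame), `source`, `frameshift`, `strand_conflict`.
#' @export
frame_from_hits <- function(hsps, query_length) {
  stopifnot(nrow(hsps) >= 1, length(unique(hsps$qseqid)) == 1)
  fr <- lapply(seq_len(nrow(hsps)), function(i)
    hit_frame(hsps$qstart[[i]], hsps$qend[[i]], query_length))
  obs <- unique(data.frame(
    strand = vapply(fr, `[[`, "", "strand"),
    frame = vapply(fr, `[[`, 0L, "frame"),
    stringsAsFactors = FALSE))
  best <- order(-hsps$bitscore, hsps$evalue)[[1]]
  chosen <- fr[[best]]
  on_chosen <- obs[obs$strand == chosen$strand, , drop = FALSE]
  structure(list(
    transcript_id = hsps$qseqid[[1]],
    frames_observed = obs,
    chosen = chosen,
    source = "homology",
    frameshift = nrow(on_chosen) >= 2,
    strand_conflict = length(unique(obs$strand)) > 1),
    class = "frame_evidence")
}

# longest stop-free codon run of one oriented frame; returns NULL or a list
# with codon indices (c1, c2, 1-based among the frame's codons) and aa string
longest_run_in_frame <- function(oriented, offset, code) {
  codons <- frame_codons(oriented, offset)
  if (length(codons) == 0) return(NULL)
  aa <- translate_codons(codons, code)
  is_stop <- aa == "*"
  bounds <- c(0L, which(is_stop), length(aa) + 1L)
  best <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    c1 <- bounds[[i]] + 1L
    c2 <- bounds[[i + 1L]] - 1L
    if (c2 < c1) next
    len <- c2 - c1 + 1L
    if (is.null(best) || len > best$len) {   # ties: leftmost run wins
      best <- list(c1 = c1, c2 = c2, len = len,
                   aa = paste(aa[c1:c2], collapse = ""),
                   has_stop_after = c2 < length(aa) && is_stop[[c2 + 1L]],
                   first_codon = codons[[c1]])
    }
  }
  best
}

orf_from_run <- function(run, seq_len_nt, strand, frame, code, transcript_id) {
  offset <- frame - 1L
  o1 <- offset + 3L * (run$c1 - 1L) + 1L
  o2 <- offset + 3L * run$c2
  if (strand == "+") {
    nt_start <- o1; nt_end <- o2
  } else {
    nt_start <- seq_len_nt - o2 + 1L
    nt_end <- seq_len_nt - o1 + 1L
  }
  structure(list(
    transcript_id = transcript_id,
    strand = strand, frame = frame,
    nt_start = nt_start, nt_end = nt_end,
    aa_seq = run$aa,
    has_start = run$first_codon %in% code$start_codons,
    has_stop = run$has_stop_after,
    genetic_code_id = code$table_id),
    class = "orf_prediction")
}

#' @export
print.orf_prediction <- function(x, ...) {
  cat(sprintf("ORF %s: %s%d nt %d-%d, %d aa, start=%s stop=%s (table %d)\n",
              x$transcript_id, x$strand, x$frame, x$nt_start, x$nt_end,
              nchar(x$aa_seq), x$has_start, x$has_stop, x$genetic_code_id))
  invisible(x)
}

#' Predict the ORF of a transcript
#'
#' With homology-derived frame evidence, the ORF is the longest stop-free
#' codon run within the chosen strand and frame (extending to the sequence
#' edges when no stop bounds it). Without evidence, and for transcripts not
#' identified as non-coding RNA, it is the longest such run over all six
#' frames. RNA transcripts without evidence get no ORF. The stop codon is
#' excluded from both `aa_seq` and the nucleotide coordinates; `has_stop`
#' records whether one immediately follows in frame, `has_start` whether
#' the first codon is a start codon of the genetic code.
#'
#' @param seq DNA string (length >= 3).
#' @param evidence A `frame_evidence` object, or `NULL` for de novo search.
#' @param is_rna Was the transcript assigned to an RNA family?
#' @param code A `genetic_code`.
#' @param transcript_id Identifier copied into the prediction.
#' @return An `orf_prediction`, or `NULL` (RNA without evidence, or no
#'   codon fits the frame).
#' @examples
#' code <- get_genetic_code(1)
#' predict_orf("ATGAAATGA", code = code)  # MK, start and stop present
#' @export
predict_orf <- function(seq, evidence = NULL, is_rna = FALSE,
                        code = get_genetic_code(1),
                        transcript_id = "transcript") {
  if (nchar(seq) < 3) stop("sequence must be at least 3 nt")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (!is.null(evidence)) {
    strand <- evidence$chosen$strand
    frame <- evidence$chosen$frame
    oriented <- if (strand == "+") seq else revcomp(seq)
    run <- longest_run_in_frame(oriented, frame - 1L, code)
    if (is.null(run)) return(NULL)
    return(orf_from_run(run, L, strand, frame, code, transcript_id))
  }
  if (is_rna) return(NULL)
  best <- NULL
  for (strand in c("+", "-")) {       # plus strand, then lower frame, wins ties
    oriented <- if (strand == "+") seq else revcomp(seq)
    for (frame in 1:3) {
      run <- longest_run_in_frame(oriented, frame - 1L, code)
      if (!is.null(run) && (is.null(best) || run$len > best$run$len)) {
        best <- list(run = run, strand = strand, frame = frame)
      }
    }
  }
  if (is.null(best)) return(NULL)
  orf_from_run(best$run, L, best$strand, best$frame, code, transcript_id)
}

#' Translate a coding sequence as-is (CDS mode)
#'
#' For inputs that are untranslated coding sequences rather than assembled
#' transcripts, ORF search is skipped: every sequence is translated on
#' strand `+`, frame 1, truncating at the first stop codon if any.
#'
#' @inheritParams predict_orf
#' @return An `orf_prediction` with strand "+" and frame 1.
#' @export
cds_mode_translate <- function(seq, code = get_genetic_code(1),
                               transcript_id = "transcript") {
  if (nchar(seq) < 3) stop("sequence must be at least 3 nt")
  seq <- toupper(seq)
  codons <- frame_codons(seq, 0L)
  aa <- translate_codons(codons, code)
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0 && stop_at[[1]] == 1L) {
    # leading stop: empty coding run is degenerate; keep a zero-length ORF
    run <- list(c1 = 1L, c2 = 0L, len = 0L, aa = "",
                has_stop_after = TRUE, first_codon = codons[[1]])
  } else if (length(stop_at) > 0) {
    end <- stop_at[[1]] - 1L
    run <- list(c1 = 1L, c2 = end, len = end,
                aa = paste(aa[1:end], collapse = ""),
                has_stop_after = TRUE, first_codon = codons[[1]])
  } else {
    run <- list(c1 = 1L, c2 = length(aa), len = length(aa),
                aa = paste(aa, collapse = ""),
                has_stop_after = FALSE, first_codon = codons[[1]])
  }
  out <- orf_from_run(run, nchar(seq), "+", 1L, code, transcript_id)
  out$source <- "cds_mode"
  out
}

#' Best-hit recovery ratio
#'
#' Predicted ORF length (aa) divided by the best-hit protein length (aa).
#' Values near 1 indicate recovery of the full protein; systematically low
#' values across a transcriptome are diagnostic of genetic-code
#' misspecification (internal reassigned stops truncating predictions).
#'
#' @param orf An `orf_prediction` or `NULL`.
#' @param subject_protein_length Best-hit protein length in aa (> 0).
#' @return A number, or `NA` when there is no ORF.
#' @export
best_hit_recovery_ratio <- function(orf, subject_protein_length) {
  stopifnot(subject_protein_length > 0)
  if (is.null(orf)) return(NA_real_)
  nchar(orf$aa_seq) / subject_protein_length
}

#' Meta-annotate the full-length status of a transcript
#'
#' Compares the predicted ORF length with the protein lengths of the
#' members of the transcript's gene family: with length ratio
#' `rho = aa length / median(member lengths)`, the transcript is
#' `full_length` when both start and stop codons are present and
#' `rho >= rho_threshold`; `quasi_full_length` when only the length test
#' passes; `partial` when `rho < rho_threshold`; and `no_information` when
#' the transcript has no gene family.
#'
#' @param orf An `orf_prediction` or `NULL`.
#' @param gf_member_lengths Integer vector of member protein lengths (aa),
#'   or `NULL` when the transcript has no gene family.
#' @param rho_threshold Length-ratio threshold (default 0.8).
#' @return List of class `meta_annotation`: `status`, `length_ratio`.
#' @export
meta_annotate <- function(orf, gf_member_lengths = NULL,
                          rho_threshold = 0.8) {
  if (is.null(gf_member_lengths)) {
    return(structure(list(status = "no_information", length_ratio = NA_real_),
                     class = "meta_annotation"))
  }
  if (length(gf_member_lengths) == 0) {
    stop("gene family present but member length list is empty")
  }
  len <- if (is.null(orf)) 0L else nchar(orf$aa_seq)
  rho <- len / stats::median(gf_member_lengths)
  complete_ends <- !is.null(orf) && orf$has_start && orf$has_stop
  status <- if (rho < rho_threshold) {
    "partial"
  } else if (complete_ends) {
    "full_length"
  } else {
    "quasi_full_length"
  }
  structure(list(status = status, length_ratio = rho),
            class = "meta_annotation")
}
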