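#' Experiment configuration
#'
#' Parameters of the initial-processing phase. Defaults mirror the
#' standard run: E-value cutoff 1e-5, annotation transfer from both the
#' top hit and the gene family, genetic code table 1, taxonomic
#' classification enabled, and the six ubiquitous non-coding RNA clans.
#'
#' @param evalue_cutoff Maximum similarity-search E-value (default 1e-5).
#' @param transfer A [transfer_config()].
#' @param genetic_code_id NCBI translation table (default 1).
#' @param run_taxclass Run/ingest taxonomic classification (default TRUE).
#' @param cds_mode Inputs are untranslated coding sequences: skip ORF
#'   search and translate everything on strand/frame +1 (default FALSE).
#' @param clade_constraint Optional taxid restricting similarity hits to
#'   subjects from one clade.
#' @param rfam_clans Clans whose families count as non-coding RNA
#'   (default [default_rfam_clans()]).
#' @param rho_threshold Meta-annotation length-ratio threshold
#'   (default 0.8).
#' @export
experiment_config <- function(evalue_cutoff = 1e-5,
                              transfer = transfer_config(),
                              genetic_code_id = 1L,
                              run_taxclass = TRUE,
                              cds_mode = FALSE,
                              clade_constraint = NULL,
                              rfam_clans = default_rfam_clans(),
                              rho_threshold = 0.8) {
  stopifnot(evalue_cutoff > 0)
  if (!all(grepl("^CL\\d{5}$", rfam_clans))) {
    stop("malformed Rfam clan id(s): ",
         paste(rfam_clans[!grepl("^CL\\d{5}$", rfam_clans)], collapse = ", "))
  }
  structure(list(evalue_cutoff = evalue_cutoff, transfer = transfer,
                 genetic_code_id = as.integer(genetic_code_id),
                 run_taxclass = isTRUE(run_taxclass),
                 cds_mode = isTRUE(cds_mode),
                 clade_constraint = clade_constraint,
                 rfam_clans = rfam_clans,
                 rho_threshold = rho_threshold),
            class = "experiment_config")
}

#' Run the initial-processing phase end to end
#'
#' Ordered stages: taxonomic classification (parsed Kaiju-style input),
#' RNA family assignment (parsed Infernal input), top-hit / gene-family /
#' label transfer, frame and frameshift inference plus ORF prediction (or
#' +1 translation in CDS mode), meta-annotation, and default subsets.
#' Per-stage TSVs, ORF FASTAs and an append-only parameter-echoing log are
#' written to `outdir`.
#'
#' @param transcripts_fasta Path to the transcript FASTA.
#' @param reference_dir Directory written by [write_reference_dir()]
#'   (with `rfam_go.tsv` alongside).
#' @param cfg An [experiment_config()].
#' @param hits_path,kaiju_path,infernal_path Side-input files; a missing
#'   side input for an enabled stage is an error naming the stage.
#' @param outdir Output directory.
#' @return Invisibly, a list with all in-memory stage results
#'   (`classifications`, `rna`, `annotations`, `orfs`, `structural`,
#'   `subsets`, `stats`).
#' @export
run_initial_processing <- function(transcripts_fasta, reference_dir, cfg,
                                   hits_path = NULL, kaiju_path = NULL,
                                   infernal_path = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "experiment_log.tsv")
  unlink(log_path)
  log_step <- function(step, params, counts) {
    line <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), step,
                  params, counts, sep = "\t")
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  bundle <- read_reference_dir(reference_dir)
  rfam_map_path <- file.path(reference_dir, "rfam_go.tsv")
  rfam_map <- if (file.exists(rfam_map_path)) load_rfam_map(rfam_map_path)
              else make_rfam_map()
  dna <- Biostrings::readDNAStringSet(transcripts_fasta)
  seqs <- as.character(dna)
  names(seqs) <- sub("\\s.*$", "", names(dna))
  ids <- names(seqs)
  code <- get_genetic_code(cfg$genetic_code_id)
  log_step("load", sprintf("transcripts=%s reference=%s code=%d",
                           transcripts_fasta, reference_dir,
                           cfg$genetic_code_id),
           sprintf("n_transcripts=%d n_ref_proteins=%d",
                   length(seqs), length(bundle$proteins)))

  # 1. taxonomic classification
  cls <- NULL
  if (cfg$run_taxclass) {
    if (is.null(kaiju_path)) {
      stop("stage 'taxonomic classification' is enabled but no ",
           "classification side input was provided")
    }
    cls <- parse_kaiju(kaiju_path)
    write_classification_tsv(cls, file.path(outdir, "taxclass.tsv"))
    log_step("taxclass", sprintf("source=%s", kaiju_path),
             sprintf("classified=%d unclassified=%d",
                     sum(cls$status == "classified"),
                     sum(cls$status != "classified")))
  }

  # 2. RNA family assignment
  rna <- list()
  if (!is.null(infernal_path)) {
    tbl <- parse_infernal_tblout(infernal_path)
    rna <- assign_rfam_all(tbl, rfam_map, clans = cfg$rfam_clans)
  }
  rna_ids <- vapply(rna, `[[`, "", "transcript_id")
  rna_tab <- data.frame(
    transcript_id = rna_ids,
    rfam_id = vapply(rna, `[[`, "", "rfam_id"),
    clan_id = vapply(rna, function(x)
      if (is.na(x$clan_id)) "" else x$clan_id, ""),
    bitscore = vapply(rna, `[[`, 0, "bitscore"),
    go = vapply(rna, function(x)
      paste(x$go_labels$identifier, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(rna_tab, file.path(outdir, "rna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_step("rna", sprintf("clans=%s source=%s",
                          paste(cfg$rfam_clans, collapse = ","),
                          if (is.null(infernal_path)) "-" else infernal_path),
           sprintf("rna_assigned=%d", length(rna)))

  # 3. top hit, gene family, label transfer
  if (is.null(hits_path)) {
    stop("stage 'similarity annotation' is enabled but no hit table ",
         "side input was provided")
  }
  hits <- parse_hits(hits_path, cfg$evalue_cutoff)
  if (!is.null(cfg$clade_constraint)) {
    hits <- filter_hits_by_clade(hits, cfg$clade_constraint, bundle)
  }
  by_query <- hits_by_query(hits)
  tops <- lapply(by_query, select_top_hit)
  ann_rows <- list(); lab_rows <- list()
  for (id in ids) {
    top <- tops[[id]]
    gf <- if (is.null(top)) NA_character_ else assign_gf(top, bundle)
    ann_rows[[id]] <- data.frame(
      transcript_id = id,
      subject = if (is.null(top)) NA_character_ else top$hit$sseqid,
      evalue = if (is.null(top)) NA_real_ else top$hit$evalue,
      gf_id = gf,
      rfam_id = if (id %in% rna_ids)
        rna[[match(id, rna_ids)]]$rfam_id else NA_character_,
      stringsAsFactors = FALSE)
    lab <- transfer_labels(top, gf, cfg$transfer, bundle)
    if (id %in% rna_ids) {
      go <- rna[[match(id, rna_ids)]]$go_labels
      if (nrow(go) > 0) {
        lab <- rbind(lab, data.frame(namespace = go$namespace,
                                     identifier = go$identifier,
                                     description = "",
                                     provenance = "rfam",
                                     stringsAsFactors = FALSE))
      }
    }
    if (nrow(lab) > 0) {
      lab$transcript_id <- id
      lab_rows[[id]] <- lab
    }
  }
  annotations <- do.call(rbind, ann_rows)
  rownames(annotations) <- NULL
  labels <- if (length(lab_rows) > 0) do.call(rbind, lab_rows)
            else data.frame(namespace = character(0),
                            identifier = character(0),
                            description = character(0),
                            provenance = character(0),
                            transcript_id = character(0),
                            stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  utils::write.table(
    annotations, file.path(outdir, "annotations.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(
    labels[, c("transcript_id", "namespace", "identifier", "description",
               "provenance")],
    file.path(outdir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  log_step("annotation",
           sprintf("evalue<=%g transfer=%s vote>=%g", cfg$evalue_cutoff,
                   cfg$transfer$source, cfg$transfer$gf_vote_threshold),
           sprintf("gf_assigned=%d labelled=%d",
                   sum(!is.na(annotations$gf_id)),
                   length(unique(labels$transcript_id))))

  # 4. frame / frameshift / ORF (or +1 translation in CDS mode)
  orfs <- list(); struct_rows <- list()
  for (id in ids) {
    top <- tops[[id]]
    evidence <- NULL
    if (!cfg$cds_mode && !is.null(top)) {
      evidence <- frame_from_hits(top$hsps, nchar(seqs[[id]]))
    }
    orf <- if (cfg$cds_mode) {
      cds_mode_translate(seqs[[id]], code, transcript_id = id)
    } else {
      predict_orf(seqs[[id]], evidence, is_rna = id %in% rna_ids,
                  code = code, transcript_id = id)
    }
    orfs[id] <- list(orf)   # keeps NULL entries (no-ORF transcripts)
    struct_rows[[id]] <- data.frame(
      transcript_id = id,
      strand = if (is.null(orf)) "" else orf$strand,
      frame = if (is.null(orf)) NA_integer_ else orf$frame,
      nt_start = if (is.null(orf)) NA_integer_ else orf$nt_start,
      nt_end = if (is.null(orf)) NA_integer_ else orf$nt_end,
      orf_aa_length = if (is.null(orf)) 0L else nchar(orf$aa_seq),
      has_start = if (is.null(orf)) NA else orf$has_start,
      has_stop = if (is.null(orf)) NA else orf$has_stop,
      frameshift = if (is.null(evidence)) FALSE else evidence$frameshift,
      strand_conflict = if (is.null(evidence)) FALSE
                        else evidence$strand_conflict,
      genetic_code_id = cfg$genetic_code_id,
      stringsAsFactors = FALSE)
  }
  log_step("orf", sprintf("code=%d cds_mode=%s", cfg$genetic_code_id,
                          cfg$cds_mode),
           sprintf("orfs=%d frameshifts=%d",
                   sum(!vapply(orfs, is.null, TRUE)),
                   sum(vapply(struct_rows, `[[`, TRUE, "frameshift"))))

  # 5. meta-annotation
  meta <- character(length(ids)); ratio <- rep(NA_real_, length(ids))
  names(meta) <- ids
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    gf <- annotations$gf_id[[match(id, annotations$transcript_id)]]
    lens <- if (is.na(gf)) NULL
            else gene_length(bundle, bundle$families[[gf]])
    ma <- meta_annotate(orfs[[id]], lens, cfg$rho_threshold)
    meta[[i]] <- ma$status
    ratio[[i]] <- ma$length_ratio
  }
  structural <- do.call(rbind, struct_rows)
  structural$meta_annotation <- unname(meta)
  structural$length_ratio <- ratio
  rownames(structural) <- NULL
  utils::write.table(structural, file.path(outdir, "structural.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  aa_set <- Biostrings::AAStringSet(
    vapply(orfs[!vapply(orfs, is.null, TRUE)], `[[`, "", "aa_seq"))
  Biostrings::writeXStringSet(aa_set, file.path(outdir, "orf_proteins.fasta"),
                              width = 60)
  orf_nt <- vapply(ids[!vapply(orfs, is.null, TRUE)], function(id) {
    o <- orfs[[id]]
    sub <- substr(seqs[[id]], o$nt_start, o$nt_end)
    if (o$strand == "-") revcomp(sub) else sub
  }, "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(orf_nt),
                              file.path(outdir, "orf_transcripts.fasta"),
                              width = 70)
  log_step("meta", sprintf("rho>=%g", cfg$rho_threshold),
           paste(names(table(meta)), as.integer(table(meta)),
                 sep = "=", collapse = " "))

  # 6. default subsets
  subs <- default_subsets(annotations)
  subset_tab <- do.call(rbind, lapply(subs, function(s) {
    if (length(s$transcript_ids) == 0) return(NULL)
    data.frame(transcript_id = s$transcript_ids, subset = s$name,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(subset_tab, file.path(outdir, "subsets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_step("subsets", "defaults=protein_coding,rna,ambiguous",
           paste(names(subs), vapply(subs, function(s)
             length(s$transcript_ids), 0L), sep = "=", collapse = " "))

  result <- list(transcript_ids = ids, seqs = seqs,
                 classifications = cls, rna = rna,
                 annotations = annotations, labels = labels,
                 orfs = orfs, structural = structural, subsets = subs,
                 bundle = bundle, config = cfg)
  invisible(result)
}

#' Summary statistics of a processed experiment
#'
#' Annotation counts plus transcript and predicted-ORF length
#' distributions (min / median / N50 / max).
#'
#' @param result The list returned by [run_initial_processing()].
#' @export
experiment_stats <- function(result) {
  if (is.null(result$structural)) stop("experiment is incomplete")
  tx_len <- nchar(result$seqs)
  orf_len <- result$structural$orf_aa_length
  labs <- result$labels
  per_ns <- vapply(c("GO", "InterPro", "KO"), function(ns)
    length(unique(labs$transcript_id[labs$namespace == ns])), 0L)
  list(
    n_transcripts = length(result$transcript_ids),
    n_gf_assigned = sum(!is.na(result$annotations$gf_id)),
    n_rna_assigned = length(result$rna),
    n_classified = if (is.null(result$classifications)) NA_integer_
                   else sum(result$classifications$status == "classified"),
    n_labelled = per_ns,
    transcript_length = length_summary(tx_len),
    orf_length_aa = length_summary(orf_len[orf_len > 0]))
}

length_summary <- function(x) {
  if (length(x) == 0) {
    return(c(min = NA_real_, median = NA_real_, n50 = NA_real_,
             max = NA_real_))
  }
  c(min = min(x), median = stats::median(x), n50 = n50(x), max = max(x))
}

#' N50 of a set of lengths
#'
#' The largest length L such that lengths >= L cover at least half of the
#' total: sorting decreasingly, the first length at which the cumulative
#' sum reaches half the total.
#' @export
n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= sum(s) / 2)[[1]]])
}
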