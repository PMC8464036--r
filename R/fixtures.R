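#' @name fixtures
#' @title Deterministic synthetic fixtures
#' @description
#' Generators producing a self-contained reference bundle, transcripts,
#' similarity hits, Infernal and Kaiju outputs with recorded ground truth,
#' so the whole engine is testable without downloading any database.
#' Everything is a pure function of its arguments and the seed:
#' regeneration is byte-identical.
#'
#' Random proteins use a uniform residue model; simulated E-values are
#' rank-consistent labels rather than model-derived probabilities. Both
#' are sufficient because every assertion made on fixtures is structural.
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# synonymous DNA codons per amino acid under the standard code, excluding
# the alternative initiation codons TTG/CTG so that internal codons are
# never start codons (keeps meta-annotation fixture truth exact)
codon_choices <- function() {
  code <- get_genetic_code(1)
  map <- code$codon_to_aa
  codons <- names(map)[map != "*" & !names(map) %in% c("TTG", "CTG")]
  split(codons, map[codons])
}

random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1, replace = TRUE)), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# reverse-translate a protein; Q residues listed in stop_q (1-based
# positions) are encoded as TAA/TAG (ciliate-style reassigned stops)
reverse_translate <- function(protein, choices, stop_q = integer(0)) {
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- choices[[a]]
    opts[[sample.int(length(opts), 1)]]
  }, "", USE.NAMES = FALSE)
  if (length(stop_q) > 0) {
    codons[stop_q] <- sample(c("TAA", "TAG"), length(stop_q), replace = TRUE)
  }
  paste(codons, collapse = "")
}

#' Generate a synthetic reference bundle with recorded truth
#'
#' Builds a taxonomy (one main clade of `n_species` species paired under
#' genera, plus a small outgroup clade), random proteins (per-family
#' common length, 80-400 aa), gene families with a controlled
#' species-coverage profile (so core/non-core status at the 90% threshold
#' is known by construction), planted functional labels at controlled
#' member frequencies (1, ~0.5 and ~0.25, exercising the majority-vote
#' boundary), family-less orphan genes, and an outgroup family usable as
#' contaminant source.
#'
#' @param seed Integer seed; the bundle is a pure function of the
#'   arguments and this seed.
#' @param n_species Species in the main clade (default 10).
#' @param n_families Gene families in the main clade (default 10).
#' @param n_outgroup Outgroup species (default 2).
#' @param coverage Optional integer vector of per-family species coverage;
#'   defaults to a profile spanning full coverage down to 30%.
#' @return List with `bundle` (a `reference_bundle`), `rfam_map`, and
#'   `truth` (family table with s_f / n_f / weight / core status, label
#'   frequencies, clade taxids).
#' @export
make_bundle <- function(seed, n_species = 10L, n_families = 10L,
                        n_outgroup = 2L, coverage = NULL) {
  stopifnot(n_species >= 2)
  set.seed(seed)
  choices <- codon_choices()

  # taxonomy: root(1) > main clade(2)/outgroup(3) > genera > species
  n_genera <- ceiling(n_species / 2)
  genera <- 10L + seq_len(n_genera)
  species <- 100L + seq_len(n_species)
  out_species <- 900L + seq_len(n_outgroup)
  nodes <- data.frame(
    taxid = c(1L, 2L, 3L, genera, 90L, species, out_species),
    parent_taxid = c(1L, 1L, 1L, rep(2L, n_genera), 3L,
                     genera[ceiling(seq_len(n_species) / 2)],
                     rep(90L, n_outgroup)),
    rank = c("no rank", "kingdom", "kingdom", rep("genus", n_genera),
             "genus", rep("species", n_species + n_outgroup)),
    name = c("root", "MainClade", "Outgroup",
             paste0("Genus", seq_len(n_genera)), "OutGenus",
             paste0("Species", seq_len(n_species)),
             paste0("OutSpecies", seq_len(n_outgroup))),
    genetic_code_id = 1L,
    stringsAsFactors = FALSE)
  taxonomy <- validate_taxonomy(nodes)

  if (is.null(coverage)) {
    base <- c(1, 1, 0.9, 0.9, 0.9, 0.8, 0.8, 0.7, 0.5, 0.3)
    coverage <- pmax(2L, round(n_species *
                                 rep_len(base, n_families)))
  }
  stopifnot(length(coverage) == n_families, all(coverage <= n_species))

  genes <- list(); prots <- character(0)
  fam_truth <- list()
  for (f in seq_len(n_families)) {
    gf_id <- sprintf("GF%03d", f)
    s_f <- coverage[[f]]
    sp <- sort(sample(species, s_f))
    plen <- sample(80:400, 1)
    member_sp <- sp
    # families 1 and 6 carry one paralog in their first species
    if (f %in% c(1L, 6L) && s_f >= 1) member_sp <- c(sp, sp[[1]])
    copy_no <- as.integer(stats::ave(member_sp, member_sp, FUN = seq_along))
    gid <- sprintf("%s_s%d_c%d", gf_id, member_sp, copy_no)
    for (i in seq_along(gid)) {
      prots[gid[[i]]] <- random_protein(plen)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid[[i]], gf_id = gf_id,
        species_taxid = member_sp[[i]], stringsAsFactors = FALSE)
    }
    n_f <- length(gid)
    fam_truth[[f]] <- data.frame(
      gf_id = gf_id, s_f = s_f, n_f = n_f, protein_len = plen,
      weight = gf_weight(s_f, n_species, n_f),
      core_at_0.9 = s_f * 10 >= 9 * n_species,
      stringsAsFactors = FALSE)
  }
  # orphan (family-less) genes, one per two species
  for (s in species[seq(1, n_species, by = 2)]) {
    gid <- sprintf("orphan_s%d", s)
    prots[gid] <- random_protein(sample(80:400, 1))
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, gf_id = NA_character_, species_taxid = s,
      stringsAsFactors = FALSE)
  }
  # outgroup family (contaminant source)
  out_len <- sample(80:400, 1)
  for (s in out_species) {
    gid <- sprintf("GFOUT_s%d", s)
    prots[gid] <- random_protein(out_len)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, gf_id = "GFOUT", species_taxid = s,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)

  # planted labels: GO on all members, InterPro on floor(n/2), KO on
  # max(1, floor(n/4)) members of each family
  labels <- list()
  for (f in seq_len(n_families)) {
    gf_id <- sprintf("GF%03d", f)
    members <- genes$gene_id[!is.na(genes$gf_id) & genes$gf_id == gf_id]
    n <- length(members)
    add <- function(g, ns, id, desc) {
      labels[[length(labels) + 1L]] <<- data.frame(
        gene_id = g, namespace = ns, identifier = id, description = desc,
        stringsAsFactors = FALSE)
    }
    add(members, "GO", sprintf("GO:%07d", f * 100L),
        sprintf("process %d", f))
    half <- members[seq_len(n %/% 2)]
    if (length(half) > 0) {
      add(half, "InterPro", sprintf("IPR%06d", f * 100L + 50L),
          sprintf("domain %d", f))
    }
    quarter <- members[seq_len(max(1L, n %/% 4L))]
    add(quarter, "KO", sprintf("K%05d", f * 100L + 25L),
        sprintf("ortholog %d", f))
  }
  labels <- do.call(rbind, labels)

  bundle <- structure(
    list(proteins = prots,
         genes = data.frame(gene_id = genes$gene_id,
                            species_taxid = genes$species_taxid,
                            gf_id = genes$gf_id,
                            length_aa = unname(nchar(prots[genes$gene_id])),
                            stringsAsFactors = FALSE),
         families = split(genes$gene_id[!is.na(genes$gf_id)],
                          genes$gf_id[!is.na(genes$gf_id)]),
         labels = labels, taxonomy = taxonomy),
    class = "reference_bundle")

  truth <- list(
    families = do.call(rbind, fam_truth),
    main_clade = 2L, outgroup_clade = 3L,
    species = species, out_species = out_species,
    n_species = n_species)
  list(bundle = bundle, rfam_map = make_rfam_map(), truth = truth)
}

#' Synthetic Rfam family -> clan / GO mapping
#'
#' Small fixed table in the shape of Rfam's database_link export; the
#' family/clan/GO combinations are synthetic stand-ins chosen for testing.
#' @export
make_rfam_map <- function() {
  data.frame(
    rfam_id = c("RF00001", "RF00005", "RF00010", "RF00169",
                "RF00177", "RF00177", "RF01960"),
    clan_id = c("CL00113", "CL00001", "CL00002", "CL00003",
                "CL00111", "CL00111", "CL00112"),
    go_id = c("GO:0005840", "GO:0030533", "GO:0004526", "GO:0048501",
              "GO:0003735", "GO:0005840", "GO:0005840"),
    stringsAsFactors = FALSE)
}

# build one transcript around a reference gene CDS; returns sequence plus
# coordinate truth. kept_from/kept_to restrict to a codon subrange
# (5'-truncation fixtures); insert_at plants a single-nt insertion after
# that CDS nucleotide (frameshift fixtures); stop_q encodes those Q
# positions as TAA/TAG (ciliate fixtures)
build_transcript <- function(protein, choices, strand, frame,
                             kept_from = 1L, kept_to = nchar(protein),
                             insert_at = NA_integer_,
                             stop_q = integer(0), bare = FALSE) {
  cds <- reverse_translate(protein, choices, stop_q)
  cds <- substr(cds, 3L * (kept_from - 1L) + 1L, 3L * kept_to)
  truncated5 <- kept_from > 1L
  if (bare || truncated5) {
    utr5 <- ""
    frame <- 1L
  } else {
    k <- sample(1:10, 1)
    utr5 <- random_dna(frame - 1L + 3L * k)
    # in-frame TGA just before the CDS bounds the ORF run under both the
    # standard and the ciliate code
    substr(utr5, nchar(utr5) - 2L, nchar(utr5)) <- "TGA"
  }
  utr3 <- if (bare) "" else random_dna(sample(10:40, 1))
  sense <- paste0(utr5, cds, "TGA", utr3)
  cds_start <- nchar(utr5) + 1L
  cds_end <- nchar(utr5) + nchar(cds)
  if (!is.na(insert_at)) {
    pos <- cds_start + insert_at - 1L
    sense <- paste0(substr(sense, 1, pos),
                    sample(c("A", "C", "G", "T"), 1),
                    substr(sense, pos + 1L, nchar(sense)))
    cds_end <- cds_end + 1L
  }
  L <- nchar(sense)
  seq <- if (strand == "+") sense else revcomp(sense)
  list(seq = seq, length = L, strand = strand, frame = frame,
       cds_start_sense = cds_start, cds_end_sense = cds_end,
       kept_from = kept_from, kept_to = kept_to,
       insert_at = if (is.na(insert_at)) NA_integer_ else insert_at,
       n_kept_aa = kept_to - kept_from + 1L)
}

# query coordinates of an alignment covering sense positions a..b, on the
# final transcript orientation (qstart > qend on the minus strand)
query_coords <- function(a, b, strand, L) {
  if (strand == "+") c(a, b) else c(L - a + 1L, L - b + 1L)
}

#' Generate synthetic transcripts with recorded ground truth
#'
#' Builds transcripts of controlled types from a [make_bundle()] result:
#' \describe{
#'   \item{coding}{full CDS with UTRs, random strand/frame; expected
#'     meta-annotation `full_length`.}
#'   \item{quasi}{5'-truncated by a few codons (start codon lost, >= 80%
#'     of the length kept); expected `quasi_full_length`.}
#'   \item{partial}{5'-truncated by 30% of the codons; expected `partial`.}
#'   \item{frameshift}{full CDS with one planted single-nt insertion about
#'     a third of the way in; two HSPs in adjacent frames.}
#'   \item{contaminant}{coding transcript from an outgroup species.}
#'   \item{rna}{random sequence flagged as non-coding, with Infernal hits.}
#'   \item{ambiguous}{coding transcript that also has Infernal hits.}
#'   \item{ciliate}{bare CDS (plus strand, frame 1) in which every
#'     glutamine is encoded as TAA/TAG, meaningful only under genetic code
#'     table 6; genes are chosen so that the longest table-1 run is below
#'     80% of the protein length.}
#'   \item{no_hit}{random sequence with no hits at all.}
#' }
#'
#' @param fix A [make_bundle()] result.
#' @param seed Integer seed.
#' @param counts Named integer vector of transcripts per type.
#' @return List with `seqs` (named character vector) and `truth` (data
#'   frame, one row per transcript).
#' @export
make_transcripts <- function(fix, seed,
                             counts = c(coding = 40, quasi = 8, partial = 12,
                                        frameshift = 15, contaminant = 8,
                                        rna = 8, ambiguous = 4, ciliate = 0,
                                        no_hit = 5)) {
  set.seed(seed + 1L)
  bundle <- fix$bundle
  choices <- codon_choices()
  fam_genes <- bundle$genes[!is.na(bundle$genes$gf_id) &
                              bundle$genes$gf_id != "GFOUT", , drop = FALSE]
  out_genes <- bundle$genes[!is.na(bundle$genes$gf_id) &
                              bundle$genes$gf_id == "GFOUT", , drop = FALSE]
  seqs <- character(0)
  rows <- list()
  idx <- 0L
  emit <- function(type, tr, gene_row, is_rna, expected_meta,
                   frame2 = NA_integer_) {
    idx <<- idx + 1L
    id <- sprintf("t%04d_%s", idx, type)
    seqs[id] <<- tr$seq
    rows[[length(rows) + 1L]] <<- data.frame(
      transcript_id = id, type = type,
      gene_id = if (is.null(gene_row)) NA_character_ else gene_row$gene_id,
      gf_id = if (is.null(gene_row)) NA_character_ else gene_row$gf_id,
      species_taxid = if (is.null(gene_row)) NA_integer_
                      else gene_row$species_taxid,
      strand = if (is.null(gene_row)) NA_character_ else tr$strand,
      frame = if (is.null(gene_row)) NA_integer_ else tr$frame,
      length = nchar(tr$seq),
      cds_start_sense = if (is.null(gene_row)) NA_integer_
                        else tr$cds_start_sense,
      cds_end_sense = if (is.null(gene_row)) NA_integer_ else tr$cds_end_sense,
      kept_from = if (is.null(gene_row)) NA_integer_ else tr$kept_from,
      kept_to = if (is.null(gene_row)) NA_integer_ else tr$kept_to,
      n_kept_aa = if (is.null(gene_row)) NA_integer_ else tr$n_kept_aa,
      insert_at = if (is.null(gene_row)) NA_integer_ else tr$insert_at,
      frame2 = frame2,
      frameshift = identical(type, "frameshift"),
      is_rna = is_rna,
      expected_meta = expected_meta,
      stringsAsFactors = FALSE)
  }
  pick_gene <- function(pool) pool[sample.int(nrow(pool), 1), , drop = FALSE]
  rand_placement <- function() {
    list(strand = sample(c("+", "-"), 1), frame = sample(1:3, 1))
  }

  for (type in names(counts)) {
    for (i in seq_len(counts[[type]])) {
      if (type %in% c("coding", "ambiguous")) {
        g <- pick_gene(fam_genes)
        pl <- rand_placement()
        tr <- build_transcript(bundle$proteins[[g$gene_id]], choices,
                               pl$strand, pl$frame)
        emit(type, tr, g, is_rna = identical(type, "ambiguous"),
             expected_meta = "full_length")
      } else if (type == "quasi") {
        g <- pick_gene(fam_genes)
        aas <- strsplit(bundle$proteins[[g$gene_id]], "")[[1]]
        # drop leading codons until the first kept codon is not ATG
        j <- 2L
        while (j <= 6L && aas[[j]] == "M") j <- j + 1L
        tr <- build_transcript(bundle$proteins[[g$gene_id]], choices,
                               "+", 1L, kept_from = j)
        emit(type, tr, g, FALSE, "quasi_full_length")
      } else if (type == "partial") {
        g <- pick_gene(fam_genes)
        n <- nchar(bundle$proteins[[g$gene_id]])
        tr <- build_transcript(bundle$proteins[[g$gene_id]], choices,
                               "+", 1L, kept_from = floor(0.3 * n) + 1L)
        emit(type, tr, g, FALSE, "partial")
      } else if (type == "frameshift") {
        g <- pick_gene(fam_genes)
        n <- nchar(bundle$proteins[[g$gene_id]])
        pl <- rand_placement()
        ins <- 3L * floor(n / 3) + 1L  # ~1/3 in, just after a codon boundary
        tr <- build_transcript(bundle$proteins[[g$gene_id]], choices,
                               pl$strand, pl$frame, insert_at = ins)
        # frame of the post-insertion HSP (the longer, higher-scoring one)
        m <- ins %/% 3L
        mB <- if (ins %% 3L == 0L) m + 1L else m + 2L
        a2 <- tr$cds_start_sense + 3L * (mB - 1L) + 1L
        emit(type, tr, g, FALSE, NA_character_,
             frame2 = ((a2 - 1L) %% 3L) + 1L)
      } else if (type == "contaminant") {
        g <- pick_gene(out_genes)
        pl <- rand_placement()
        tr <- build_transcript(bundle$proteins[[g$gene_id]], choices,
                               pl$strand, pl$frame)
        emit(type, tr, g, FALSE, "full_length")
      } else if (type == "rna") {
        tr <- list(seq = random_dna(sample(120:200, 1)))
        emit(type, tr, NULL, TRUE, NA_character_)
      } else if (type == "ciliate") {
        # pick a gene whose Q positions break the table-1 run below 80%
        repeat {
          g <- pick_gene(fam_genes)
          aas <- strsplit(bundle$proteins[[g$gene_id]], "")[[1]]
          qpos <- which(aas == "Q")
          n <- length(aas)
          gaps <- diff(c(0L, qpos, n + 1L)) - 1L
          if (length(qpos) >= 1 && max(gaps) < 0.8 * n) break
        }
        tr <- build_transcript(bundle$proteins[[g$gene_id]], choices,
                               "+", 1L, stop_q = qpos, bare = TRUE)
        emit(type, tr, g, FALSE, "full_length")  # expected under table 6
      } else if (type == "no_hit") {
        tr <- list(seq = random_dna(sample(150:300, 1)))
        emit(type, tr, NULL, FALSE, NA_character_)
      } else {
        stop("unknown transcript type: ", type)
      }
    }
  }
  list(seqs = seqs, truth = do.call(rbind, rows))
}

#' Simulate a tabular hit file consistent with fixture truth
#'
#' Emits HSPs whose query coordinates reproduce the generator's
#' strand/frame placement (split into two adjacent-frame HSPs across a
#' planted insertion), with E-values and bitscores arranged so the source
#' gene always wins top-hit selection; every fifth coding transcript also
#' receives a worse-scoring decoy hit to another member of its family.
#'
#' @param tx A [make_transcripts()] result.
#' @param fix A [make_bundle()] result.
#' @param seed Integer seed.
#' @return Hit data frame in the 12-column dialect (already cutoff-clean).
#' @export
make_hits <- function(tx, fix, seed) {
  set.seed(seed + 2L)
  bundle <- fix$bundle
  truth <- tx$truth
  rows <- list()
  add_hsp <- function(qid, sid, a, b, s1, s2, strand, L, evalue, bitscore) {
    qc <- query_coords(a, b, strand, L)
    rows[[length(rows) + 1L]] <<- data.frame(
      qseqid = qid, sseqid = sid,
      pident = round(100 - stats::runif(1, 0, 2), 1),
      length = s2 - s1 + 1L, mismatch = 0L, gapopen = 0L,
      qstart = qc[[1]], qend = qc[[2]], sstart = s1, send = s2,
      evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
  }
  coding_seen <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (is.na(tr$gene_id)) next
    L <- tr$length
    plen <- bundle$genes$length_aa[[match(tr$gene_id, bundle$genes$gene_id)]]
    ev <- function(aalen) max(10^(-(aalen %/% 2)), 1e-180)
    if (isTRUE(tr$frameshift)) {
      d <- tr$insert_at
      m <- d %/% 3L                       # intact codons before insertion
      mB <- if (d %% 3L == 0L) m + 1L else m + 2L
      a1 <- tr$cds_start_sense
      add_hsp(tr$transcript_id, tr$gene_id,
              a1, a1 + 3L * m - 1L, 1L, m, tr$strand, L,
              ev(m), 2 * m)
      a2 <- tr$cds_start_sense + 3L * (mB - 1L) + 1L
      add_hsp(tr$transcript_id, tr$gene_id,
              a2, tr$cds_end_sense, mB, plen, tr$strand, L,
              ev(plen - mB + 1L), 2 * (plen - mB + 1L))
    } else {
      naa <- tr$n_kept_aa
      add_hsp(tr$transcript_id, tr$gene_id,
              tr$cds_start_sense, tr$cds_end_sense,
              tr$kept_from, tr$kept_to, tr$strand, L, ev(naa), 2 * naa)
      if (tr$type == "coding") {
        coding_seen <- coding_seen + 1L
        if (coding_seen %% 5L == 0L) {
          sibs <- setdiff(bundle$families[[tr$gf_id]], tr$gene_id)
          if (length(sibs) > 0) {
            decoy <- sibs[[sample.int(length(sibs), 1)]]
            add_hsp(tr$transcript_id, decoy,
                    tr$cds_start_sense, tr$cds_end_sense,
                    tr$kept_from, tr$kept_to, tr$strand, L,
                    min(ev(naa) * 1e3, 1e-6), 2 * naa - 30)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate Infernal `cmsearch --tblout` output for RNA-flagged fixtures
#'
#' RNA and ambiguous transcripts get a strong hit to RF00005 (tRNA clan)
#' and a weaker secondary hit to RF00001, exercising top-family selection.
#' @param tx A [make_transcripts()] result.
#' @param seed Integer seed.
#' @return Character vector of tblout lines (with comment header/footer).
#' @export
make_infernal_tblout <- function(tx, seed) {
  set.seed(seed + 3L)
  truth <- tx$truth
  rna <- truth[truth$is_rna, , drop = FALSE]
  lines <- c("#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description of target")
  fmt <- function(id, fam, acc, score, evalue, len) {
    sprintf("%s - %s %s cm 1 71 1 %d + no 1 0.45 0.0 %.1f %.2g ! synthetic fixture hit",
            id, fam, acc, len, score, evalue)
  }
  for (i in seq_len(nrow(rna))) {
    id <- rna$transcript_id[[i]]
    len <- rna$length[[i]]
    lines <- c(lines,
               fmt(id, "tRNA", "RF00005", 60 + stats::runif(1, 0, 5),
                   1e-12, min(len, 71L)),
               fmt(id, "5S_rRNA", "RF00001", 30 + stats::runif(1, 0, 3),
                   1e-4, min(len, 71L)))
  }
  c(lines, "#")
}

#' Simulate Kaiju-style classification output for fixture transcripts
#'
#' Coding-derived transcripts are reported classified at their source
#' species with the protein length as match length; RNA and random
#' transcripts are unclassified.
#' @export
make_kaiju_output <- function(tx, fix) {
  truth <- tx$truth
  vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    if (is.na(tr$gene_id)) {
      paste("U", tr$transcript_id, 0, sep = "\t")
    } else {
      paste("C", tr$transcript_id, tr$species_taxid, tr$n_kept_aa,
            sep = "\t")
    }
  }, "")
}

#' Generate a complete fixture set
#'
#' Bundle, transcripts, hit table, Infernal and Kaiju outputs plus truth,
#' all deterministic under the seed.
#' @inheritParams make_bundle
#' @inheritParams make_transcripts
#' @export
make_fixture_set <- function(seed, n_species = 10L, n_families = 10L,
                             counts = c(coding = 40, quasi = 8, partial = 12,
                                        frameshift = 15, contaminant = 8,
                                        rna = 8, ambiguous = 4, ciliate = 0,
                                        no_hit = 5)) {
  fix <- make_bundle(seed, n_species = n_species, n_families = n_families)
  tx <- make_transcripts(fix, seed, counts = counts)
  hits <- make_hits(tx, fix, seed)
  list(bundle = fix$bundle, rfam_map = fix$rfam_map,
       bundle_truth = fix$truth, seqs = tx$seqs, truth = tx$truth,
       hits = hits, infernal = make_infernal_tblout(tx, seed),
       kaiju = make_kaiju_output(tx, fix))
}

#' Write a fixture set to disk as a real input directory
#'
#' Lays out `reference/` (proteins.fasta, gf.tsv, labels.tsv,
#' taxonomy.tsv, rfam_go.tsv), `transcripts.fasta`, `hits.tsv`,
#' `infernal.tblout`, `kaiju.tsv` and `truth.json`.
#' @export
write_fixture_dir <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_dir(fixture$bundle, file.path(dir, "reference"))
  utils::write.table(fixture$rfam_map,
                     file.path(dir, "reference", "rfam_go.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, na = "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fixture$seqs),
                              file.path(dir, "transcripts.fasta"),
                              width = 70)
  write_hits(fixture$hits, file.path(dir, "hits.tsv"))
  writeLines(fixture$infernal, file.path(dir, "infernal.tblout"))
  writeLines(fixture$kaiju, file.path(dir, "kaiju.tsv"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
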