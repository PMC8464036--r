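code1 <- get_genetic_code(1)

test_that("six-frame fragments split at stops and translate N to X", {
  # frame +1: M K * M G -> two fragments on that frame
  fr <- six_frame_fragments("ATGAAATGAATGGGG", code1)
  plus1 <- fr[fr$strand == "+" & fr$frame == 1, ]
  expect_equal(plus1$fragment, c("MK", "MG"))
  # no stop in any frame: 60 nt give 20 + 19 + 19 codons per strand
  s <- strrep("GCA", 20)
  fr2 <- six_frame_fragments(s, code1)
  expect_equal(nrow(fr2), 6)
  expect_setequal(nchar(fr2$fragment), c(20L, 19L))
  # N-containing codon
  fr3 <- six_frame_fragments("ATGANATGG", code1)
  expect_true(grepl("X", fr3$fragment[fr3$strand == "+" & fr3$frame == 1]))
  expect_error(six_frame_fragments("AT", code1))
  expect_error(six_frame_fragments("ATGAUG", code1), "alphabet")
})

test_that("a minus-strand CDS reappears verbatim among reverse frames", {
  pep <- "MKWYHEDCIGFANPQRSTVL"
  cds <- encode_peptide(pep)
  seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0("TGA", cds, "TGA"))))
  fr <- six_frame_fragments(seq, code1)
  expect_true(pep %in% fr$fragment[fr$strand == "-"])
})

test_that("low-complexity fragments are recognized", {
  expect_true(is_low_complexity("AAAAAAAAAAAA"))
  expect_true(is_low_complexity("ABABABABABAB"))      # entropy 1 bit
  expect_false(is_low_complexity("MKWYHEDCIGFANPQRSTVL"))
})

test_that("classification assigns the taxon of the longest exact match", {
  tax <- tiny_taxonomy()
  pepA <- "WYHEDCIGFANP"                               # 12 aa, unique to A
  prots <- c(a = paste0("MMM", pepA, "KKK"), c = "MDDDEEEKKKRRRHHHAACW")
  taxids <- c(3L, 6L)
  q <- encode_peptide(pepA)
  res <- classify_transcript(q, prots, taxids, classifier_config(), tax)
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 3L)
  expect_equal(res$match_length, 12L)
})

test_that("taxa tied at the maximal match length resolve to their LCA", {
  tax <- tiny_taxonomy()
  shared <- "WYHEDCIGFANP"
  prots <- c(a = paste0("MKL", shared), b = paste0("MDE", shared),
             c = "MHHHRRRKKKDDDEEEAACW")
  res <- classify_transcript(encode_peptide(shared), prots,
                             c(3L, 4L, 6L), classifier_config(), tax)
  expect_equal(res$taxid, 2L)            # genus G = lca(A, B)
  expect_equal(res$match_length, 12L)
  # ties among proteins of the same taxon need no LCA
  res2 <- classify_transcript(encode_peptide(shared),
                              c(a1 = paste0("MKL", shared),
                                a2 = paste0("MDE", shared)),
                              c(3L, 3L), classifier_config(), tax)
  expect_equal(res2$taxid, 3L)
})

test_that("matches below the minimum length leave the query unclassified", {
  tax <- tiny_taxonomy()
  pep10 <- "WYHEDCIGFA"                                # 10 aa < 11
  prots <- c(a = paste0("MMM", pep10))
  res <- classify_transcript(encode_peptide(pep10), prots, 3L,
                             classifier_config(min_match_length = 11), tax)
  expect_equal(res$status, "unclassified")
  expect_equal(res$match_length, 0L)
  res2 <- classify_transcript(encode_peptide(pep10), prots, 3L,
                              classifier_config(min_match_length = 10), tax)
  expect_equal(res2$status, "classified")
  expect_equal(res2$match_length, 10L)
})

test_that("the classifier agrees exactly with the all-substrings oracle", {
  fix <- make_fixture_set(31, n_species = 6, n_families = 4,
                          counts = c(coding = 12, contaminant = 3,
                                     no_hit = 10, rna = 5, quasi = 0,
                                     partial = 0, frameshift = 0,
                                     ambiguous = 0, ciliate = 0))
  b <- fix$bundle
  taxids <- b$genes$species_taxid[match(names(b$proteins),
                                        b$genes$gene_id)]
  for (id in names(fix$seqs)) {
    got <- classify_transcript(fix$seqs[[id]], b$proteins, taxids,
                               classifier_config(), b$taxonomy,
                               query_id = id)
    want <- oracle_classify(fix$seqs[[id]], b$proteins, taxids, b$taxonomy)
    expect_equal(got$status, want$status, label = id)
    expect_equal(got$match_length, want$match_length, label = id)
    expect_equal(got$taxid, want$taxid, label = id)
  }
})

test_that("split-index merging keeps the longest match or the LCA of ties", {
  tax <- tiny_taxonomy()
  row <- function(taxid, len) data.frame(
    query_id = "q", status = "classified", taxid = taxid,
    match_length = len, stringsAsFactors = FALSE)
  uncls <- data.frame(query_id = "q", status = "unclassified",
                      taxid = NA_integer_, match_length = 0L,
                      stringsAsFactors = FALSE)
  expect_equal(merge_split_results(rbind(row(3, 15), row(4, 12)), tax)$taxid, 3L)
  m <- merge_split_results(rbind(row(3, 12), row(4, 12)), tax)
  expect_equal(m$taxid, 2L)
  expect_equal(m$match_length, 12L)
  expect_equal(merge_split_results(rbind(uncls, row(3, 13)), tax)$taxid, 3L)
  expect_equal(merge_split_results(rbind(uncls, uncls), tax)$status,
               "unclassified")
  bad <- rbind(row(3, 5), transform(row(4, 5), query_id = "other"))
  expect_error(merge_split_results(bad, tax), "single query")
})

test_that("classifying against k splits then merging equals one search", {
  fix <- make_fixture_set(32, n_species = 6, n_families = 4,
                          counts = c(coding = 10, no_hit = 5, quasi = 0,
                                     partial = 0, frameshift = 0,
                                     contaminant = 0, rna = 0,
                                     ambiguous = 0, ciliate = 0))
  b <- fix$bundle
  taxids <- b$genes$species_taxid[match(names(b$proteins), b$genes$gene_id)]
  k <- 3L
  part <- rep_len(seq_len(k), length(b$proteins))
  for (id in names(fix$seqs)) {
    unified <- classify_transcript(fix$seqs[[id]], b$proteins, taxids,
                                   classifier_config(), b$taxonomy,
                                   query_id = id)
    splits <- do.call(rbind, lapply(seq_len(k), function(j) {
      classify_transcript(fix$seqs[[id]], b$proteins[part == j],
                          taxids[part == j], classifier_config(),
                          b$taxonomy, query_id = id)
    }))
    merged <- merge_split_results(splits, b$taxonomy)
    expect_equal(merged$taxid, unified$taxid, label = id)
    expect_equal(merged$match_length, unified$match_length, label = id)
    # order of splits must not matter
    merged2 <- merge_split_results(splits[sample(nrow(splits)), ], b$taxonomy)
    expect_equal(merged2$taxid, merged$taxid)
  }
})

test_that("kaiju-style output parses preserving order", {
  f <- tempfile()
  writeLines(c("C\tt1\t5693\t27", "U\tt2\t0", "C\tt3\t4"), f)
  k <- parse_kaiju(f)
  expect_equal(k$query_id, c("t1", "t2", "t3"))
  expect_equal(k$status, c("classified", "unclassified", "classified"))
  expect_equal(k$taxid, c(5693L, NA_integer_, 4L))
  expect_equal(k$match_length, c(27L, 0L, 0L))
  writeLines(c("C\tt1\t5693", "X\tt2\t0"), f)
  expect_error(parse_kaiju(f), "line 2")
})

test_that("rank summaries keep top clades, fold small ones, conserve counts", {
  tax <- tiny_taxonomy()
  cls <- data.frame(
    query_id = sprintf("t%03d", 1:100),
    status = c(rep("classified", 90), rep("unclassified", 10)),
    taxid = c(rep(3L, 60), rep(6L, 30), rep(NA_integer_, 10)),
    match_length = 20L, stringsAsFactors = FALSE)
  s <- summarize_rank(cls, tax, "genus")
  expect_equal(s$clades$count[s$clades$taxid == 2], 60)  # A lifts to G
  expect_equal(s$clades$count[s$clades$taxid == 5], 30)
  expect_equal(s$unclassified, 10)
  expect_equal(s$other, 0)
  expect_error(summarize_rank(cls, tax, "family"), "unknown rank")

  # 12 genera: 10 named + Other; one kept genus under 1% also folds
  n_gen <- 12L
  nodes <- c("1\t1\tno rank\troot",
             sprintf("%d\t1\tgenus\tg%d", 10 + 1:n_gen, 1:n_gen))
  f <- tempfile(); writeLines(nodes, f)
  tax2 <- load_taxonomy(f)
  counts <- c(400, 300, 200, 150, 100, 90, 80, 70, 60, 3, 2, 1)
  cls2 <- data.frame(
    query_id = sprintf("q%04d", seq_len(sum(counts))),
    status = "classified",
    taxid = rep(10 + 1:n_gen, counts),
    match_length = 15L, stringsAsFactors = FALSE)
  s2 <- summarize_rank(cls2, tax2, "genus")
  # the 10th-ranked genus holds 3/1456 < 1% of depicted and folds too
  expect_equal(nrow(s2$clades), 9)
  expect_equal(s2$other, 3 + 2 + 1)
  expect_equal(sum(s2$clades$count) + s2$other + s2$excluded +
                 s2$unclassified, s2$total)
})

test_that("transcripts classified above the requested rank are excluded", {
  tax <- tiny_taxonomy()
  cls <- data.frame(query_id = c("a", "b"), status = "classified",
                    taxid = c(1L, 3L), match_length = 12L,
                    stringsAsFactors = FALSE)
  s <- summarize_rank(cls, tax, "genus")
  expect_equal(s$excluded, 1)           # the root-classified transcript
  expect_equal(sum(s$clades$count), 1)
})
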