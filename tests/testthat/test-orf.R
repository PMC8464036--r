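code1 <- get_genetic_code(1)
code6 <- get_genetic_code(6)

test_that("frame evidence picks the best HSP and flags same-strand splits", {
  one <- data.frame(qseqid = "t", qstart = 2, qend = 31, evalue = 1e-30,
                    bitscore = 100, stringsAsFactors = FALSE)
  ev <- frame_from_hits(one, 60)
  expect_equal(ev$chosen, list(strand = "+", frame = 2L))
  expect_false(ev$frameshift)

  two <- data.frame(qseqid = "t", qstart = c(1, 92), qend = c(90, 181),
                    evalue = c(1e-30, 1e-40), bitscore = c(60, 90),
                    stringsAsFactors = FALSE)
  ev2 <- frame_from_hits(two, 200)
  expect_true(ev2$frameshift)
  expect_equal(ev2$chosen$frame, 2L)    # the higher-bitscore HSP
  expect_false(ev2$strand_conflict)

  cross <- data.frame(qseqid = "t", qstart = c(1, 90), qend = c(60, 31),
                      evalue = c(1e-30, 1e-10), bitscore = c(90, 40),
                      stringsAsFactors = FALSE)
  ev3 <- frame_from_hits(cross, 90)
  expect_false(ev3$frameshift)          # cross-strand is not a frameshift
  expect_true(ev3$strand_conflict)
  expect_equal(ev3$chosen$strand, "+")
})

plus1 <- structure(list(chosen = list(strand = "+", frame = 1L)),
                   class = "frame_evidence")

test_that("ORF prediction finds the longest stop-free run in a frame", {
  o <- predict_orf("ATGAAATGA", plus1, code = code1)
  expect_equal(o$aa_seq, "MK")
  expect_equal(c(o$nt_start, o$nt_end), c(1L, 6L))
  expect_true(o$has_start)
  expect_true(o$has_stop)
  expect_null(predict_orf("ATGAAATGA", is_rna = TRUE, code = code1))
  expect_error(predict_orf("AT", code = code1))
  # without evidence the search spans all six frames: here the reverse
  # strand holds a longer run (TCATTTCAT reads SFH)
  dn <- predict_orf("ATGAAATGA", code = code1)
  expect_equal(dn$strand, "-")
  expect_equal(nchar(dn$aa_seq), 3L)
})

test_that("stop-codon reassignment under table 6 lengthens the ORF", {
  o1 <- predict_orf("ATGTAAATGTGA", plus1, code = code1)
  expect_equal(o1$aa_seq, "M")          # leftmost of the two tied runs
  expect_equal(c(o1$nt_start, o1$nt_end), c(1L, 3L))
  o6 <- predict_orf("ATGTAAATGTGA", plus1, code = code6)
  expect_equal(o6$aa_seq, "MQM")        # TAA read as glutamine
  expect_equal(c(o6$nt_start, o6$nt_end), c(1L, 9L))
  expect_true(o6$has_stop)
})

test_that("de novo prediction equals the brute-force six-frame maximum", {
  set.seed(13)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:150, 1), TRUE),
               collapse = "")
    for (code in list(code1, code6)) {
      o <- predict_orf(s, code = code)
      want <- oracle_best_orf_len(s, code)
      got <- if (is.null(o)) 0L else nchar(o$aa_seq)
      expect_equal(got, want, label = paste("seq", i, "table", code$table_id))
    }
  }
})

test_that("homology-guided prediction is maximal within the chosen frame", {
  set.seed(14)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    ev <- structure(list(chosen = list(strand = sample(c("+", "-"), 1),
                                       frame = sample(1:3, 1))),
                    class = "frame_evidence")
    o <- predict_orf(s, ev, code = code1)
    want <- oracle_best_orf_len(s, code1, strand = ev$chosen$strand,
                                frame = ev$chosen$frame)
    expect_equal(if (is.null(o)) 0L else nchar(o$aa_seq), want)
  }
})

test_that("the reported coordinates reproduce the amino-acid sequence", {
  set.seed(15)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:200, 1), TRUE),
               collapse = "")
    o <- predict_orf(s, code = code1)
    if (is.null(o)) next
    expect_equal((o$nt_end - o$nt_start + 1L) %% 3L, 0L)
    sub <- substr(s, o$nt_start, o$nt_end)
    if (o$strand == "-") sub <- txannot:::revcomp(sub)
    back <- txannot:::translate_frame(sub, 0L, code1)
    expect_equal(back, o$aa_seq)
    expect_false(grepl("*", o$aa_seq, fixed = TRUE))
  }
})

test_that("relaxing the stop set never shortens the ORF in a fixed frame", {
  set.seed(16)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = "")
    ev <- structure(list(chosen = list(strand = "+", frame = 1L)),
                    class = "frame_evidence")
    o1 <- predict_orf(s, ev, code = code1)
    o6 <- predict_orf(s, ev, code = code6)
    l1 <- if (is.null(o1)) 0L else nchar(o1$aa_seq)
    l6 <- if (is.null(o6)) 0L else nchar(o6$aa_seq)
    expect_gte(l6, l1)
  }
})

test_that("CDS mode translates on +1 and truncates at the first stop", {
  o <- cds_mode_translate("ATGGCC", code1)
  expect_equal(o$aa_seq, "MA")
  expect_false(o$has_stop)
  o2 <- cds_mode_translate("ATGTGAGCC", code1)
  expect_equal(o2$aa_seq, "M")
  expect_true(o2$has_stop)
  set.seed(17)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    o <- cds_mode_translate(s, code1)
    expect_equal(o$strand, "+")
    expect_equal(o$frame, 1L)
  }
})

test_that("the best-hit recovery ratio is ORF length over subject length", {
  orf <- structure(list(aa_seq = strrep("A", 100)), class = "orf_prediction")
  expect_equal(best_hit_recovery_ratio(orf, 200), 0.5)
  expect_equal(best_hit_recovery_ratio(orf, 100), 1.0)
  expect_true(is.na(best_hit_recovery_ratio(NULL, 100)))
})

test_that("ciliate-style fixtures recover longer ORFs under table 6", {
  fix <- make_fixture_set(21, counts = c(ciliate = 10, coding = 10,
                                         quasi = 0, partial = 0,
                                         frameshift = 0, contaminant = 0,
                                         rna = 0, ambiguous = 0, no_hit = 0))
  ratios <- sapply(list(code1, code6), function(code) {
    sapply(unique(fix$hits$qseqid), function(id) {
      top <- select_top_hit(fix$hits[fix$hits$qseqid == id, ])
      ev <- frame_from_hits(top$hsps, nchar(fix$seqs[[id]]))
      o <- predict_orf(fix$seqs[[id]], ev, code = code, transcript_id = id)
      best_hit_recovery_ratio(o, gene_length(fix$bundle, top$hit$sseqid))
    })
  })
  expect_gt(mean(ratios[, 2]), mean(ratios[, 1]))
  # the standard code recovers full ORFs only for the stop-free transcripts
  cil <- grepl("ciliate", rownames(ratios))
  expect_true(all(ratios[cil, 1] < 0.8))
  expect_true(all(ratios[cil, 2] >= 0.99))
})

test_that("meta-annotation combines the length ratio with codon presence", {
  full <- structure(list(aa_seq = strrep("A", 100), has_start = TRUE,
                         has_stop = TRUE), class = "orf_prediction")
  expect_equal(meta_annotate(full, rep(100L, 5))$status, "full_length")
  noends <- structure(list(aa_seq = strrep("A", 90), has_start = FALSE,
                           has_stop = TRUE), class = "orf_prediction")
  expect_equal(meta_annotate(noends, rep(100L, 5))$status,
               "quasi_full_length")
  half <- structure(list(aa_seq = strrep("A", 50), has_start = TRUE,
                         has_stop = TRUE), class = "orf_prediction")
  ma <- meta_annotate(half, rep(100L, 5))
  expect_equal(ma$status, "partial")
  expect_equal(ma$length_ratio, 0.5)
  expect_equal(meta_annotate(full, NULL)$status, "no_information")
  expect_equal(meta_annotate(NULL, rep(100L, 3))$status, "partial")
  expect_error(meta_annotate(full, integer(0)), "empty")
})

test_that("frame and frameshift flags are fully recovered from fixtures", {
  fix <- make_fixture_set(23, counts = c(coding = 30, frameshift = 15,
                                         quasi = 5, partial = 5,
                                         contaminant = 5, rna = 0,
                                         ambiguous = 0, ciliate = 0,
                                         no_hit = 0))
  truth <- fix$truth
  for (id in unique(fix$hits$qseqid)) {
    tr <- truth[truth$transcript_id == id, ]
    top <- select_top_hit(fix$hits[fix$hits$qseqid == id, ])
    ev <- frame_from_hits(top$hsps, tr$length)
    expect_equal(ev$chosen$strand, tr$strand, label = id)
    expect_equal(ev$frameshift, tr$frameshift, label = id)
    expect_equal(ev$chosen$frame,
                 if (tr$frameshift) tr$frame2 else tr$frame, label = id)
  }
})
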