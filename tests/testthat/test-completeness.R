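test_that("family weights reward coverage and penalize copy number", {
  expect_equal(gf_weight(10, 10, 10), 1.0)
  expect_equal(gf_weight(8, 10, 16), 0.4)
  w1 <- gf_weight(6, 10, 7)
  expect_equal(gf_weight(6, 10, 14), w1 / 2)   # doubling members halves w
  expect_error(gf_weight(0, 10, 5))
  expect_error(gf_weight(5, 10, 4))            # n_f < s_f impossible
})

test_that("the 90% species threshold is an exact rational boundary", {
  fix <- make_bundle(71, n_species = 10, n_families = 4,
                     coverage = c(10, 9, 8, 5))
  core <- define_core_gfs(2, fix$bundle, t = 0.9)
  expect_setequal(core$entries$gf_id, c("GF001", "GF002"))  # 10/10, 9/10
  strict <- define_core_gfs(2, fix$bundle, t = 1.0)
  expect_equal(strict$entries$gf_id, "GF001")
  loose <- define_core_gfs(2, fix$bundle, t = 0.5)
  expect_setequal(loose$entries$gf_id, c("GF001", "GF002", "GF003", "GF004"))
  expect_error(define_core_gfs(3, fix$bundle),
               NA)  # outgroup clade has its own species: no error
  expect_error(define_core_gfs(90, make_bundle(72, n_outgroup = 0)$bundle))
})

test_that("raising the threshold never grows the core set", {
  fix <- make_bundle(73)
  prev <- Inf
  for (t in c(0.3, 0.5, 0.7, 0.9, 1.0)) {
    n <- nrow(define_core_gfs(2, fix$bundle, t)$entries)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("core weights match a direct recomputation from the bundle", {
  fix <- make_bundle(74)
  b <- fix$bundle
  core <- define_core_gfs(2, b, 0.9)
  clade_species <- fix$truth$species
  S <- length(clade_species)
  for (i in seq_len(nrow(core$entries))) {
    gf <- core$entries$gf_id[[i]]
    sp <- b$genes$species_taxid[match(b$families[[gf]], b$genes$gene_id)]
    sp <- sp[sp %in% clade_species]
    expect_equal(core$entries$s_f[[i]], length(unique(sp)))
    expect_equal(core$entries$n_f[[i]], length(sp))
    expect_equal(core$entries$weight[[i]],
                 (length(unique(sp)) / S) *
                   (length(unique(sp)) / length(sp)))
  }
})

mk_hit <- function(q, s, ev = 1e-20, bs = 100) {
  data.frame(qseqid = q, sseqid = s, pident = 99, length = 50, mismatch = 0,
             gapopen = 0, qstart = 1, qend = 150, sstart = 1, send = 50,
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

test_that("top-hit families are represented; non-core hits contribute nothing", {
  fix <- make_bundle(75, n_species = 10, n_families = 3,
                     coverage = c(10, 10, 5))       # GF003 not core
  b <- fix$bundle
  core <- define_core_gfs(2, b, 0.9)
  g <- function(gf) b$families[[gf]][[1]]
  hits <- rbind(mk_hit("t1", g("GF001")), mk_hit("t2", g("GF001")),
                mk_hit("t3", g("GF002")), mk_hit("t4", g("GF003")))
  expect_setequal(represented_core_gfs(hits, core, b, k = 1),
                  c("GF001", "GF002"))
})

test_that("with k > 1 only the best-scoring candidate family counts", {
  fix <- make_bundle(76, n_species = 10, n_families = 3,
                     coverage = c(10, 10, 10))
  b <- fix$bundle
  core <- define_core_gfs(2, b, 0.9)
  g <- function(gf) b$families[[gf]][[1]]
  hits <- rbind(mk_hit("t1", g("GF001"), ev = 1e-30, bs = 200),
                mk_hit("t1", g("GF002"), ev = 1e-20, bs = 150),
                mk_hit("t1", g("GF003"), ev = 1e-10, bs = 90))
  expect_equal(represented_core_gfs(hits, core, b, k = 3), "GF001")
  # k = 1 gives the same here (top hit's family)
  expect_equal(represented_core_gfs(hits, core, b, k = 1), "GF001")
})

test_that("completeness scores are weighted fractions with exact bounds", {
  fix <- make_bundle(77, n_species = 10, n_families = 10,
                     coverage = rep(c(10L, 9L), 5))
  b <- fix$bundle
  core <- define_core_gfs(2, b, 0.9)
  expect_equal(nrow(core$entries), 10)
  all_gf <- core$entries$gf_id
  expect_equal(score_completeness(core, all_gf)$score, 1.0)
  expect_equal(score_completeness(core, character(0))$score, 0.0)
  half <- all_gf[1:5]
  w <- stats::setNames(core$entries$weight, core$entries$gf_id)
  expect_equal(score_completeness(core, half)$score,
               sum(w[half]) / sum(w), tolerance = 1e-12)
  res <- score_completeness(core, half)
  expect_setequal(c(res$represented, res$missing), all_gf)
  expect_error(score_completeness(core, "GFX"), "not in the core set")
})

test_that("two core families with weights 1 and 0.5 score 2/3 when one hit", {
  tax <- tiny_taxonomy()
  fa <- tempfile()
  writeLines(c(">a1", "MKLVANPQRSTWYHEDCIGF", ">a2", "MKLVANPQRSTWYHEDCIGA",
               ">b1", "MDDDEEEKKKRRRHHHAAAC", ">b2", "MWYHAAACCCDDDEEEFFFG",
               ">b3", "MWYHAAACCCDDDEEEFFFA", ">b4", "MNPQRSTKLVHEDCIGFWYA"),
             fa)
  gf <- tempfile()
  # A: 2 species, single copy (w = 1); B: 2 species, 4 members (w = 0.5)
  writeLines(c("a1\tA\t3", "a2\tA\t4",
               "b1\tB\t3", "b2\tB\t3", "b3\tB\t4", "b4\tB\t4"), gf)
  lab <- tempfile(); writeLines("a1\tGO\tGO:1\t", lab)
  b <- load_reference(fa, gf, lab, tax)
  core <- define_core_gfs(2, b, 0.9)
  expect_equal(stats::setNames(core$entries$weight, core$entries$gf_id),
               c(A = 1.0, B = 0.5))
  res <- score_completeness(core, "A")
  expect_equal(res$score, 1.0 / 1.5, tolerance = 1e-12)
  expect_equal(res$missing, "B")
})

test_that("adding transcripts never decreases the completeness score", {
  fix <- make_fixture_set(78, counts = c(coding = 30, quasi = 0, partial = 0,
                                         frameshift = 0, contaminant = 0,
                                         rna = 0, ambiguous = 0, ciliate = 0,
                                         no_hit = 0))
  b <- fix$bundle
  core <- define_core_gfs(2, b, 0.9)
  qs <- unique(fix$hits$qseqid)
  prev <- 0
  for (n in c(5, 10, 20, 30)) {
    sub <- fix$hits[fix$hits$qseqid %in% qs[seq_len(min(n, length(qs)))], ]
    s <- score_completeness(core, represented_core_gfs(sub, core, b))$score
    expect_gte(s, prev)
    expect_gte(s, 0); expect_lte(s, 1)
    prev <- s
  }
})

test_that("the score equals an exhaustive recomputation from raw hits", {
  fix <- make_fixture_set(79, counts = c(coding = 25, quasi = 5, partial = 5,
                                         frameshift = 5, contaminant = 5,
                                         rna = 0, ambiguous = 0, ciliate = 0,
                                         no_hit = 0))
  b <- fix$bundle
  core <- define_core_gfs(2, b, 0.9)
  got <- score_completeness(core,
                            represented_core_gfs(fix$hits, core, b))$score
  # oracle: per query take the single best row by (evalue, -bitscore,
  # subject), collect families, intersect with core, sum weights
  oracle_rep <- unique(unlist(lapply(split(fix$hits, fix$hits$qseqid),
    function(h) {
      h <- h[order(h$evalue, -h$bitscore, h$sseqid), ]
      gf <- b$genes$gf_id[match(h$sseqid[[1]], b$genes$gene_id)]
      gf[!is.na(gf)]
    })))
  w <- stats::setNames(core$entries$weight, core$entries$gf_id)
  want <- sum(w[intersect(oracle_rep, names(w))]) / sum(w)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the completeness report serializes families and score", {
  fix <- make_fixture_set(80, counts = c(coding = 20, quasi = 0, partial = 0,
                                         frameshift = 0, contaminant = 0,
                                         rna = 0, ambiguous = 0, ciliate = 0,
                                         no_hit = 0))
  js <- tempfile(fileext = ".json"); tsv <- tempfile(fileext = ".tsv")
  rep <- completeness_report(2, fix$bundle, fix$hits, json_path = js,
                             missing_tsv_path = tsv)
  expect_true(file.exists(js))
  back <- jsonlite::read_json(js)
  expect_equal(back$score, rep$score)
  expect_equal(back$n_species, 10)
})
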