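# small hand-built inputs used across test files

# taxonomy: root(1) > genus G(2) > species A(3), B(4); genus H(5) > C(6)
tiny_taxonomy <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "1\t1\tno rank\troot",
    "2\t1\tgenus\tG",
    "3\t2\tspecies\tA",
    "4\t2\tspecies\tB",
    "5\t1\tgenus\tH",
    "6\t5\tspecies\tC"), f)
  load_taxonomy(f)
}

# 6 proteins, 2 families of 3 members, species 3/4/6
tiny_bundle <- function(taxonomy = tiny_taxonomy()) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">p1", "MKLVANPQRSTWYHEDCIGF",
    ">p2", "MKLVANPQRSTWYHEDCIGA",
    ">p3", "MDDDEEEKKKRRRHHHAAAC",
    ">p4", "MWYHAAACCCDDDEEEFFFG",
    ">p5", "MWYHAAACCCDDDEEEFFFA",
    ">p6", "MNPQRSTKLVHEDCIGFWYA"), fa)
  gf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "p1\tGF1\t3", "p2\tGF1\t4", "p3\tGF1\t6",
    "p4\tGF2\t3", "p5\tGF2\t4", "p6\tGF2\t6"), gf)
  lab <- tempfile(fileext = ".tsv")
  writeLines(c(
    "p1\tGO\tGO:0000001\tprocess one",
    "p2\tGO\tGO:0000001\tprocess one",
    "p3\tGO\tGO:0000002\tprocess two",
    "p4\tInterPro\tIPR000001\tdomain one",
    "p1\tKO\tK00001\tortholog one"), lab)
  load_reference(fa, gf, lab, taxonomy)
}

# reverse-translate a peptide deterministically (first synonymous codon,
# avoiding TTG/CTG) -- independent of the generator's random encoding
encode_peptide <- function(pep) {
  code <- Biostrings::getGeneticCode("1")
  codons <- names(code)[code != "*" & !names(code) %in% c("TTG", "CTG")]
  aas <- strsplit(pep, "")[[1]]
  paste(vapply(aas, function(a) codons[code[codons] == a][[1]], ""),
        collapse = "")
}
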