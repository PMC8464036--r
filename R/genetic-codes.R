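#' Retrieve an NCBI genetic code table
#'
#' Returns a translation table as a total map from the 64 DNA codons to
#' amino-acid letters, with `"*"` denoting a stop codon. Tables are those of
#' the NCBI taxonomy (standard = 1, ciliate/dasycladacean nuclear = 6, etc.),
#' served locally through \pkg{Biostrings}; no network access is involved.
#'
#' Under table 6 the standard stops TAA and TAG are reassigned to glutamine
#' (Q) and TGA is the sole stop — the reassignment that matters when
#' predicting ORFs from ciliate transcriptomes.
#'
#' @param table_id Positive integer, the NCBI translation table number.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector of length 64),
#'   `stop_codons` and `start_codons`.
#' @examples
#' gc1 <- get_genetic_code(1)
#' gc1$codon_to_aa[["TAA"]]  # "*"
#' gc6 <- get_genetic_code(6)
#' gc6$codon_to_aa[["TAA"]]  # "Q"
#' @export
get_genetic_code <- function(table_id) {
  stopifnot(length(table_id) == 1, is.numeric(table_id), table_id >= 1)
  table_id <- as.integer(table_id)
  available <- Biostrings::GENETIC_CODE_TABLE$id
  if (!as.character(table_id) %in% available) {
    stop("unknown genetic code table ", table_id, "; available tables: ",
         paste(available, collapse = ", "))
  }
  map <- Biostrings::getGeneticCode(as.character(table_id))
  alt_init <- attr(map, "alt_init_codons")
  codons <- names(map)
  aa <- as.character(map)
  names(aa) <- codons
  stops <- codons[aa == "*"]
  starts <- unique(c("ATG", alt_init))
  stopifnot(length(aa) == 64, length(stops) >= 1, length(starts) >= 1)
  structure(
    list(table_id = table_id, codon_to_aa = aa,
         stop_codons = stops, start_codons = starts),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("NCBI genetic code table", x$table_id, "\n")
  cat("  stop codons: ", paste(x$stop_codons, collapse = " "), "\n")
  cat("  start codons:", paste(x$start_codons, collapse = " "), "\n")
  invisible(x)
}

#' Split a sequence into codons for a given frame offset
#'
#' @param seq Single DNA string (ACGTN alphabet).
#' @param offset 0-based offset into the sequence (frame - 1).
#' @return Character vector of complete codons (trailing partial codon
#'   dropped); zero-length when no complete codon fits.
#' @keywords internal
frame_codons <- function(seq, offset = 0) {
  n <- nchar(seq)
  ncod <- (n - offset) %/% 3L
  if (ncod < 1L) return(character(0))
  starts <- offset + 3L * (seq_len(ncod) - 1L) + 1L
  substring(seq, starts, starts + 2L)
}

#' Translate codons under a genetic code
#'
#' Codons containing characters outside ACGT (e.g. N) translate to `"X"`.
#'
#' @param codons Character vector of 3-letter codons.
#' @param code A `genetic_code` object.
#' @return Character vector of single amino-acid letters (`"*"` = stop).
#' @keywords internal
translate_codons <- function(codons, code) {
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a DNA sequence in a fixed frame
#' @keywords internal
translate_frame <- function(seq, offset, code) {
  paste(translate_codons(frame_codons(seq, offset), code), collapse = "")
}

#' Reverse complement of a DNA string (keeps N)
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
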