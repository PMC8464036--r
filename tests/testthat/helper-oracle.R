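# independent brute-force oracles, kept free of the package's search paths

# largest k >= kmin such that a and b share a k-mer, growing k one at a
# time from kmin; 0 when no such k exists
pair_lcs_ge <- function(a, b, kmin) {
  best <- 0L
  k <- kmin
  repeat {
    if (k > min(nchar(a), nchar(b))) break
    ka <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
    kb <- substring(b, 1:(nchar(b) - k + 1), k:nchar(b))
    if (!any(ka %in% kb)) break
    best <- k
    k <- k + 1L
  }
  best
}

# LCA by explicit root-path walks over the node table
oracle_lca <- function(taxids, taxonomy) {
  nodes <- taxonomy$nodes
  path_of <- function(t) {
    p <- integer(0)
    while (TRUE) {
      p <- c(t, p)
      parent <- nodes$parent_taxid[nodes$taxid == t]
      if (parent == t) break
      t <- parent
    }
    p
  }
  paths <- lapply(unique(taxids), path_of)
  d <- 1L
  repeat {
    if (any(lengths(paths) < d)) break
    lev <- vapply(paths, `[[`, 0L, d)
    if (length(unique(lev)) > 1) break
    d <- d + 1L
  }
  paths[[1]][[d - 1L]]
}

# all-substrings MEM/LCA classification: every fragment against every
# protein, exhaustively
oracle_classify <- function(seq, prots, taxids, taxonomy,
                            min_match = 11L, low_complexity = TRUE) {
  frags <- six_frame_fragments(seq, get_genetic_code(1),
                               min_length = min_match)$fragment
  if (low_complexity && length(frags) > 0) {
    frags <- frags[!vapply(frags, is_low_complexity, TRUE)]
  }
  best <- 0L
  best_tax <- integer(0)
  for (fr in unique(frags)) {
    for (i in seq_along(prots)) {
      l <- pair_lcs_ge(fr, prots[[i]], max(min_match, best))
      if (l > best) {
        best <- l
        best_tax <- taxids[[i]]
      } else if (l > 0 && l == best) {
        best_tax <- union(best_tax, taxids[[i]])
      }
    }
  }
  if (best == 0) {
    list(status = "unclassified", taxid = NA_integer_, match_length = 0L)
  } else {
    tax <- if (length(best_tax) == 1) best_tax
           else oracle_lca(best_tax, taxonomy)
    list(status = "classified", taxid = as.integer(tax), match_length = best)
  }
}

# exhaustive upper-tail hypergeometric by direct term summation
oracle_hyper_tail <- function(k, n, K, N) {
  terms <- vapply(k:min(n, K), function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), 0)
  sum(terms)
}

# brute-force ORF search: enumerate stop-free codon runs in all 6 frames
oracle_best_orf_len <- function(seq, code, strand = NULL, frame = NULL) {
  seqs <- list("+" = toupper(seq),
               "-" = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(seq))))
  best <- 0L
  for (st in names(seqs)) {
    if (!is.null(strand) && st != strand) next
    s <- seqs[[st]]
    for (fr in 1:3) {
      if (!is.null(frame) && fr != frame) next
      n <- nchar(s)
      ncod <- (n - fr + 1L) %/% 3L
      if (ncod < 1) next
      starts <- fr + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      aa <- code$codon_to_aa[codons]
      aa[is.na(aa)] <- "X"
      run <- 0L
      for (a in aa) {
        if (identical(unname(a), "*")) run <- 0L
        else {
          run <- run + 1L
          if (run > best) best <- run
        }
      }
    }
  }
  best
}
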