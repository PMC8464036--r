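#' Construct a transcript subset
#'
#' @param name Subset name.
#' @param transcript_ids Character vector of transcript identifiers.
#' @param origin How the subset was defined: `default`, `taxonomy`, `user`.
#' @export
subset_of <- function(name, transcript_ids,
                      origin = c("user", "default", "taxonomy")) {
  origin <- match.arg(origin)
  structure(list(name = name, transcript_ids = unique(transcript_ids),
                 origin = origin),
            class = "transcript_subset")
}

#' Read a subset from a file of transcript ids (one per line)
#' @export
read_subset_file <- function(path, name = basename(path)) {
  ids <- readLines(path)
  subset_of(name, ids[nzchar(ids)], origin = "user")
}

#' Default annotation-derived subsets
#'
#' Three subsets built from the initial-processing results: transcripts
#' assigned to a gene family (protein-coding), transcripts assigned to an
#' RNA family (RNA), and transcripts assigned to both (ambiguous — the
#' intersection of the first two).
#'
#' @param annotations Data frame with columns `transcript_id`, `gf_id`
#'   (NA when none) and `rfam_id` (NA when none).
#' @return Named list of three `transcript_subset`s: `protein_coding`,
#'   `rna`, `ambiguous`.
#' @export
default_subsets <- function(annotations) {
  coding <- annotations$transcript_id[!is.na(annotations$gf_id)]
  rna <- annotations$transcript_id[!is.na(annotations$rfam_id)]
  list(
    protein_coding = subset_of("protein_coding", coding, origin = "default"),
    rna = subset_of("rna", rna, origin = "default"),
    ambiguous = subset_of("ambiguous", intersect(coding, rna),
                          origin = "default"))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` transcripts
#' from an experiment of `N`, of which `K` carry the label, the
#' probability of seeing `k` or more carriers.
#'
#' @param k Observed carriers in the subset.
#' @param n Subset size.
#' @param K Carriers in the background.
#' @param N Background size.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (!(k >= 0 && n >= 0 && K >= 0 && n <= N && K <= N && k <= min(n, K))) {
    stop("inconsistent hypergeometric counts: k=", k, " n=", n,
         " K=", K, " N=", N)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param m Number of hypotheses (default `length(p_values)`).
#' @export
bh_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH", n = m)
}

#' Subset functional enrichment
#'
#' Tests each functional label of a namespace for over-representation in a
#' transcript subset against the annotation of the whole experiment, using
#' the upper-tail hypergeometric distribution; q-values come from
#' Benjamini-Hochberg correction over all tested labels. The background is
#' the set of transcripts carrying at least one label in the namespace
#' (switchable to all transcripts via `background_ids`).
#'
#' @param subset A `transcript_subset` or character vector of ids.
#' @param annotations Data frame of transcript labels: `transcript_id`,
#'   `namespace`, `identifier`[, `description`].
#' @param namespace Label namespace to test (`GO`, `InterPro`, `KO`).
#' @param q_cutoff Maximum reported q-value; by convention between 1e-5
#'   and 0.05 (default 0.05). Set `strict = FALSE` to allow other values.
#' @param propagate_go Propagate GO labels to ancestors before counting
#'   (requires `go_parents`; applied identically to subset and background).
#' @param go_parents Optional two-column data frame `child, parent`.
#' @param background_ids Optional explicit background (defaults to all
#'   transcripts annotated in the namespace).
#' @param strict Enforce the conventional q-cutoff range (default `TRUE`).
#' @return Data frame, one row per enriched label: `namespace, identifier,
#'   description, k, n, K, N, fold, p_value, q_value`, sorted by q then
#'   decreasing fold then identifier.
#' @export
enrich_subset <- function(subset, annotations, namespace,
                          q_cutoff = 0.05, propagate_go = FALSE,
                          go_parents = NULL, background_ids = NULL,
                          strict = TRUE) {
  if (strict && (q_cutoff < 1e-5 || q_cutoff > 0.05)) {
    stop("q_cutoff ", q_cutoff, " outside the conventional range ",
         "[1e-5, 0.05]; pass strict = FALSE to override")
  }
  ids <- if (inherits(subset, "transcript_subset"))
    subset$transcript_ids else unique(subset)
  ann <- annotations[annotations$namespace == namespace, , drop = FALSE]
  if (propagate_go && namespace == "GO") {
    if (is.null(go_parents)) stop("propagate_go requires a go_parents table")
    ann <- propagate_go_labels(ann, go_parents)
  }
  if (nrow(ann) == 0) stop("empty background: no '", namespace,
                           "' labels in the experiment")
  background <- if (is.null(background_ids))
    unique(ann$transcript_id) else unique(background_ids)
  N <- length(background)
  sub_bg <- intersect(ids, background)
  n <- length(sub_bg)
  labels <- unique(ann$identifier[ann$transcript_id %in% sub_bg])
  if (length(labels) == 0) {
    return(empty_enrichment())
  }
  rows <- lapply(labels, function(lab) {
    carriers <- unique(ann$transcript_id[ann$identifier == lab])
    carriers <- intersect(carriers, background)
    K <- length(carriers)
    k <- length(intersect(carriers, sub_bg))
    data.frame(identifier = lab, k = k, n = n, K = K, N = N,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$k > 0, , drop = FALSE]
  if (nrow(res) == 0) return(empty_enrichment())
  res$fold <- (res$k / res$n) / (res$K / res$N)
  res$p_value <- mapply(hypergeom_upper_tail, res$k, res$n, res$K, res$N)
  res$q_value <- bh_adjust(res$p_value)
  desc <- ann$description
  if (is.null(desc)) desc <- rep("", nrow(ann))
  res$description <- desc[match(res$identifier, ann$identifier)]
  res$namespace <- namespace
  res <- res[res$q_value <= q_cutoff, , drop = FALSE]
  res <- res[order(res$q_value, -res$fold, res$identifier), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("namespace", "identifier", "description", "k", "n", "K", "N",
          "fold", "p_value", "q_value")]
}

empty_enrichment <- function() {
  data.frame(namespace = character(0), identifier = character(0),
             description = character(0), k = integer(0), n = integer(0),
             K = integer(0), N = integer(0), fold = numeric(0),
             p_value = numeric(0), q_value = numeric(0),
             stringsAsFactors = FALSE)
}

# add one row per (transcript, ancestor) reachable through the parent table
propagate_go_labels <- function(ann, go_parents) {
  parent_of <- split(go_parents$parent, go_parents$child)
  closure <- function(term) {
    seen <- character(0)
    frontier <- term
    while (length(frontier) > 0) {
      nxt <- unique(unlist(parent_of[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, c(seen, term))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  extra <- lapply(seq_len(nrow(ann)), function(i) {
    anc <- closure(ann$identifier[[i]])
    if (length(anc) == 0) return(NULL)
    data.frame(transcript_id = ann$transcript_id[[i]],
               namespace = ann$namespace[[i]], identifier = anc,
               description = "", stringsAsFactors = FALSE)
  })
  extra <- do.call(rbind, extra[!vapply(extra, is.null, TRUE)])
  cols <- c("transcript_id", "namespace", "identifier", "description")
  if (!"description" %in% names(ann)) ann$description <- ""
  unique(rbind(ann[, cols], if (!is.null(extra)) extra[, cols]))
}

#' Compare label frequencies between two subsets
#'
#' For every label of the namespace seen in either subset, reports the
#' within-subset carrier frequencies and their ratio; labels private to
#' one subset are flagged `a-only` / `b-only`, shared ones `shared`.
#'
#' @param a,b `transcript_subset`s.
#' @param annotations Label data frame (as in [enrich_subset()]).
#' @param namespace Namespace to compare.
#' @return Data frame `identifier, freq_a, freq_b, ratio, status`.
#' @export
compare_subsets <- function(a, b, annotations, namespace) {
  ann <- annotations[annotations$namespace == namespace, , drop = FALSE]
  freq_in <- function(ids, lab) {
    carriers <- unique(ann$transcript_id[ann$identifier == lab])
    length(intersect(carriers, ids)) / length(ids)
  }
  labs <- unique(ann$identifier[ann$transcript_id %in%
                                  c(a$transcript_ids, b$transcript_ids)])
  fa <- vapply(labs, freq_in, 0, ids = a$transcript_ids)
  fb <- vapply(labs, freq_in, 0, ids = b$transcript_ids)
  status <- ifelse(fa > 0 & fb > 0, "shared",
                   ifelse(fa > 0, "a-only", "b-only"))
  out <- data.frame(identifier = labs, freq_a = fa, freq_b = fb,
                    ratio = ifelse(fb > 0, fa / fb, Inf),
                    status = status, stringsAsFactors = FALSE)
  out$ratio[out$status == "b-only"] <- 0
  out <- out[order(out$identifier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Taxonomy-aware label frequency ratio
#'
#' The frequency of transcripts both carrying a label and classified to a
#' given genus within a subset, divided by the same frequency within a
#' background subset — highlighting clade-specific functional signal in
#' community samples.
#'
#' @param subset,background `transcript_subset`s with
#'   `background` containing `subset`.
#' @param label Label identifier.
#' @param genus_taxid Genus to condition on.
#' @param annotations Label data frame.
#' @param classifications Classification data frame.
#' @param taxonomy A `taxonomy` object.
#' @return The ratio, or `NA` when the background frequency is zero.
#' @export
taxonomic_ratio <- function(subset, label, genus_taxid, annotations,
                            classifications, background, taxonomy) {
  if (!all(subset$transcript_ids %in% background$transcript_ids)) {
    stop("background must contain the subset")
  }
  carriers <- unique(annotations$transcript_id[
    annotations$identifier == label])
  cls <- classifications[classifications$status == "classified", ,
                         drop = FALSE]
  lifted <- vapply(cls$taxid, ancestor_at_rank, 0L,
                   rank = "genus", taxonomy = taxonomy)
  in_genus <- cls$query_id[!is.na(lifted) & lifted == genus_taxid]
  both <- intersect(carriers, in_genus)
  f_sub <- length(intersect(both, subset$transcript_ids)) /
    length(subset$transcript_ids)
  f_bg <- length(intersect(both, background$transcript_ids)) /
    length(background$transcript_ids)
  if (f_bg == 0) return(NA_real_)
  f_sub / f_bg
}

#' Write an enrichment table as TSV
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
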