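#' Weight of a core gene family
#'
#' Rewards broad species coverage and low average copy number:
#' `w = (s_f / S) * (s_f / n_f)` where `s_f` is the number of clade
#' species with at least one member, `S` the number of clade species, and
#' `n_f` the member count within clade species. A single-copy family
#' present in every species weighs 1.
#'
#' @param s_f Species represented in the family (within the clade).
#' @param S Total species in the clade.
#' @param n_f Family members from clade species.
#' @return A positive weight.
#' @export
gf_weight <- function(s_f, S, n_f) {
  stopifnot(s_f >= 1, s_f <= S, n_f >= s_f)
  (s_f / S) * (s_f / n_f)
}

# exact rational comparison s_f / S >= t for thresholds with <= 6 decimals
core_threshold_met <- function(s_f, S, t) {
  s_f * 1e6 >= round(t * 1e6) * S
}

#' Define the core gene-family set of a clade
#'
#' A family is core for a clade when it is represented in at least a
#' threshold fraction (default 90%) of the clade's species — tolerating
#' annotation errors or family loss in a few species without requiring
#' complete conservation. The threshold comparison is exact (integer
#' cross-multiplication), so `9/10` species at `t = 0.9` is core and
#' `8/10` is not. Each core family receives a weight from [gf_weight()].
#'
#' @param clade_taxid Clade to evaluate; its species are the reference
#'   species descending from this taxon.
#' @param bundle A `reference_bundle`.
#' @param t Representation threshold in (0, 1] (default 0.9).
#' @return List of class `core_gf_set`: `clade_taxid`, `threshold`,
#'   `species` (clade species taxids), `entries` (data frame gf_id / s_f /
#'   n_f / weight).
#' @export
define_core_gfs <- function(clade_taxid, bundle, t = 0.9) {
  stopifnot(t > 0, t <= 1)
  clade <- tax_descendants(bundle$taxonomy, clade_taxid)
  species <- intersect(unique(bundle$genes$species_taxid), clade)
  S <- length(species)
  if (S == 0) stop("clade ", clade_taxid, " has no species in the bundle")
  rows <- lapply(names(bundle$families), function(gf_id) {
    members <- bundle$families[[gf_id]]
    sp <- bundle$genes$species_taxid[match(members, bundle$genes$gene_id)]
    in_clade <- sp %in% species
    s_f <- length(unique(sp[in_clade]))
    n_f <- sum(in_clade)
    if (s_f == 0 || !core_threshold_met(s_f, S, t)) return(NULL)
    data.frame(gf_id = gf_id, s_f = s_f, n_f = n_f,
               weight = gf_weight(s_f, S, n_f), stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(entries)) {
    entries <- data.frame(gf_id = character(0), s_f = integer(0),
                          n_f = integer(0), weight = numeric(0),
                          stringsAsFactors = FALSE)
  }
  entries <- entries[order(entries$gf_id), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(clade_taxid = as.integer(clade_taxid), threshold = t,
                 species = species, entries = entries),
            class = "core_gf_set")
}

#' @export
print.core_gf_set <- function(x, ...) {
  cat("core gene-family set: clade", x$clade_taxid, "-",
      nrow(x$entries), "core families over", length(x$species),
      "species (t =", x$threshold, ")\n")
  invisible(x)
}

#' Core families represented in a transcriptome
#'
#' With `k = 1`, the gene family of each transcript's top protein hit is
#' considered represented. With `k > 1`, each transcript's `k` best hits
#' are grouped by family, each candidate family is scored by its best
#' bitscore (ties: lower E-value, then family id), and only the
#' best-scoring family counts. The union over transcripts is intersected
#' with the core set.
#'
#' @param hits Cutoff-filtered hit data frame (all queries).
#' @param core A `core_gf_set`.
#' @param bundle A `reference_bundle`.
#' @param k Number of top hits considered per transcript (default 1).
#' @return Character vector of represented core `gf_id`s.
#' @export
represented_core_gfs <- function(hits, core, bundle, k = 1L) {
  stopifnot(k >= 1)
  represented <- character(0)
  for (h in hits_by_query(hits)) {
    o <- order_hits(h)
    top_k <- h[o[seq_len(min(k, nrow(h)))], , drop = FALSE]
    gfs <- gene_gf(bundle, top_k$sseqid)
    ok <- !is.na(gfs)
    if (!any(ok)) next
    top_k <- top_k[ok, , drop = FALSE]
    gfs <- gfs[ok]
    if (k == 1L) {
      represented <- c(represented, gfs[[1]])
    } else {
      score <- tapply(seq_along(gfs), gfs, function(i)
        c(max(top_k$bitscore[i]), -min(top_k$evalue[i])))
      cand <- names(score)
      sc <- do.call(rbind, score)
      best <- cand[order(-sc[, 1], -sc[, 2], cand)][[1]]
      represented <- c(represented, best)
    }
  }
  sort(intersect(unique(represented), core$entries$gf_id))
}

#' Score gene-space completeness
#'
#' The completeness score is the summed weight of represented core
#' families divided by the summed weight of all core families, together
#' with the represented and missing family lists.
#'
#' @param core A `core_gf_set`.
#' @param represented Character vector of represented core `gf_id`s (must
#'   be a subset of the core set).
#' @return List of class `completeness_result`: `score`, `represented`,
#'   `missing`.
#' @export
score_completeness <- function(core, represented) {
  extra <- setdiff(represented, core$entries$gf_id)
  if (length(extra) > 0) {
    stop("represented families not in the core set: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  w <- stats::setNames(core$entries$weight, core$entries$gf_id)
  total <- sum(w)
  score <- if (total == 0) NA_real_ else sum(w[represented]) / total
  structure(list(score = score,
                 represented = sort(unique(represented)),
                 missing = sort(setdiff(names(w), represented))),
            class = "completeness_result")
}

#' @export
print.completeness_result <- function(x, ...) {
  cat(sprintf("completeness score: %.4f (%d represented, %d missing)\n",
              x$score, length(x$represented), length(x$missing)))
  invisible(x)
}

#' Full completeness analysis report
#'
#' Runs core-set definition, representation and scoring, and returns a
#' JSON-ready report; optionally writes the report and a missing-family
#' TSV (with each missing family's majority-vote labels, for functional
#' bias review).
#'
#' @inheritParams define_core_gfs
#' @inheritParams represented_core_gfs
#' @param json_path,missing_tsv_path Optional output paths.
#' @export
completeness_report <- function(clade_taxid, bundle, hits, t = 0.9, k = 1L,
                                json_path = NULL, missing_tsv_path = NULL) {
  core <- define_core_gfs(clade_taxid, bundle, t)
  rep_gfs <- represented_core_gfs(hits, core, bundle, k)
  res <- score_completeness(core, rep_gfs)
  entries <- core$entries
  entries$represented <- entries$gf_id %in% rep_gfs
  report <- list(clade = core$clade_taxid, threshold = t,
                 n_species = length(core$species),
                 score = res$score, families = entries)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(missing_tsv_path)) {
    rows <- lapply(res$missing, function(gf_id) {
      lab <- gf_majority_labels(gf_id, bundle)
      if (nrow(lab) == 0) {
        return(paste(gf_id, "", "", sep = "\t"))
      }
      paste(gf_id, lab$namespace, lab$identifier, sep = "\t")
    })
    writeLines(as.character(unlist(rows)), missing_tsv_path)
  }
  report
}
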