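# Gene-family candidate calling from similarity hits.

#' Best hit per query
#'
#' For each query, the hit with maximal bitscore; ties broken by lower
#' e-value, then lexicographically smaller subject id.
#'
#' @param hits data.frame as returned by [read_hits_tabular()].
#' @return data.frame with one row per query (queries without hits absent).
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Assign gene-family candidacy from similarity hits
#'
#' A peptide is a family candidate iff its length is at least
#' `min_peptide_len` amino acids AND the percent identity of its best
#' (bitscore-maximal) hit to the reference set is at least
#' `min_best_identity`.  Both boundaries are inclusive: peptides *shorter
#' than* the length cutoff or with *less than* the identity cutoff are
#' rejected.  Peptides with no hit are never candidates.
#'
#' @param peptides Named character vector of peptide sequences, or named
#'   integer vector of peptide lengths (aa).
#' @param hits data.frame of similarity hits (query = peptide id).
#' @param family_label Family name recorded in the output (e.g. `"TPS"`).
#' @param min_peptide_len Minimum peptide length in aa.
#' @param min_best_identity Minimum percent identity of the best hit.
#' @return data.frame with one row per peptide: `gene_id`, `family`,
#'   `best_subject`, `best_identity`, `peptide_len`, `qualifies`.
#' @export
assign_family <- function(peptides, hits, family_label = "family",
                          min_peptide_len = 350L, min_best_identity = 30) {
  stopifnot(!is.null(names(peptides)))
  plen <- if (is.numeric(peptides)) as.integer(peptides) else nchar(peptides)
  names(plen) <- names(peptides)
  missing_pep <- setdiff(unique(hits$query_id), names(plen))
  if (length(missing_pep)) {
    stop("hit query not in peptide set: ", missing_pep[1L])
  }
  best <- best_hit_per_query(hits)
  idx <- match(names(plen), best$query_id)
  out <- data.frame(
    gene_id = names(plen),
    family = family_label,
    best_subject = best$subject_id[idx],
    best_identity = best$percent_identity[idx],
    peptide_len = unname(plen),
    stringsAsFactors = FALSE
  )
  out$qualifies <- !is.na(out$best_identity) &
    out$peptide_len >= min_peptide_len &
    out$best_identity >= min_best_identity
  rownames(out) <- NULL
  out
}

#' Family candidates from a domain-hit table
#'
#' Alternate candidate route for families defined by a diagnostic domain
#' (e.g. cytochrome P450s via Pfam PF00067): a peptide qualifies iff it
#' carries the domain and meets the length cutoff.
#'
#' @param peptides Named peptide sequences or lengths (aa).
#' @param domain_gene_ids Gene ids with a match to the diagnostic domain.
#' @param family_label Family name recorded in the output.
#' @param min_peptide_len Minimum peptide length in aa (no length filter by
#'   default for this route).
#' @return data.frame as in [assign_family()] (identity columns `NA`).
#' @export
assign_family_by_domain <- function(peptides, domain_gene_ids,
                                    family_label = "family",
                                    min_peptide_len = 1L) {
  stopifnot(!is.null(names(peptides)))
  plen <- if (is.numeric(peptides)) as.integer(peptides) else nchar(peptides)
  data.frame(
    gene_id = names(peptides),
    family = family_label,
    best_subject = NA_character_,
    best_identity = NA_real_,
    peptide_len = unname(plen),
    qualifies = names(peptides) %in% domain_gene_ids &
      plen >= min_peptide_len,
    stringsAsFactors = FALSE
  )
}
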