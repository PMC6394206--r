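# Paralog pairing, protein-guided codon alignment, and the pair->Ks chain
# feeding the WGD mixture/SiZer analyses.

#' Pair paralogs from an all-vs-all protein self-comparison
#'
#' Keeps unordered gene pairs with reciprocal hits (both directions present)
#' passing the e-value and alignment-length thresholds; self-hits are
#' excluded and each pair is reported once (`gene_a < gene_b`).
#'
#' @param hits data.frame of similarity hits from a proteome self-search.
#' @param max_evalue Maximum e-value for a hit to count.
#' @param min_aln_len Minimum alignment length (aa).
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
pair_paralogs <- function(hits, max_evalue = 1e-10, min_aln_len = 100L) {
  h <- hits[hits$query_id != hits$subject_id &
              hits$evalue <= max_evalue &
              hits$alignment_length >= min_aln_len, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(h$query_id, h$subject_id, sep = "\r")
  rev_key <- paste(h$subject_id, h$query_id, sep = "\r")
  reciprocal <- key %in% rev_key
  h <- h[reciprocal, , drop = FALSE]
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Select the longest isoform per locus
#'
#' @param seqs Named character vector of CDS (or peptide) sequences keyed by
#'   transcript id.
#' @param gene_of_tx Named character vector mapping transcript id to locus
#'   id.
#' @return Named character vector with one sequence per locus (named by
#'   locus id); length ties broken by lexicographically smaller transcript
#'   id.
#' @export
select_longest_isoforms <- function(seqs, gene_of_tx) {
  stopifnot(all(names(seqs) %in% names(gene_of_tx)))
  df <- data.frame(tx = names(seqs), gene = unname(gene_of_tx[names(seqs)]),
                   len = nchar(seqs), stringsAsFactors = FALSE)
  df <- df[order(df$gene, -df$len, df$tx), , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  setNames(unname(seqs[df$tx]), df$gene)
}

#' Global protein alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (opening 10, extension 1), via `Biostrings::pairwiseAlignment()`.
#'
#' @param pep_a,pep_b Peptide sequences (nonempty, standard amino acids).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return list with aligned strings `a` and `b` (gaps as `-`).
#' @export
align_proteins_global <- function(pep_a, pep_b, gap_open = 10,
                                  gap_extend = 1) {
  pep_a <- toupper(pep_a)
  pep_b <- toupper(pep_b)
  if (!nzchar(pep_a) || !nzchar(pep_b)) stop("empty peptide sequence")
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
  if (!grepl(ok, pep_a) || !grepl(ok, pep_b)) {
    stop("non-amino-acid characters in peptide")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pep_a), Biostrings::AAString(pep_b),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Thread CDS onto a protein alignment
#'
#' Each aligned residue is replaced by its codon and each protein gap by a
#' 3-nt gap, producing a codon-structured CDS alignment.  A terminal stop
#' codon on either CDS is stripped.
#'
#' @param protein_alignment list with aligned strings `a`, `b` (from
#'   [align_proteins_global()]).
#' @param cds_a,cds_b Unaligned coding sequences; length must be 3x the
#'   ungapped peptide length (after stop stripping).
#' @param name_a,name_b Gene names used in error messages.
#' @return list with aligned CDS strings `a` and `b`.
#' @export
thread_codons <- function(protein_alignment, cds_a, cds_b,
                          name_a = "a", name_b = "b") {
  thread_one <- function(aln, cds, nm) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3L != 0L) {
      stop("CDS length of ", nm, " not divisible by 3")
    }
    cods <- codon_split(cds)
    if (length(cods) > 0L &&
        cods[length(cods)] %in% c("TAA", "TAG", "TGA")) {
      cods <- cods[-length(cods)]
    }
    res <- strsplit(aln, "", fixed = TRUE)[[1L]]
    npep <- sum(res != "-")
    if (length(cods) != npep) {
      stop("CDS of ", nm, " does not match peptide length (",
           length(cods), " codons vs ", npep, " residues)")
    }
    out <- character(length(res))
    out[res == "-"] <- "---"
    out[res != "-"] <- cods
    paste(out, collapse = "")
  }
  list(a = thread_one(protein_alignment$a, cds_a, name_a),
       b = thread_one(protein_alignment$b, cds_b, name_b))
}

#' Ks estimates for a table of paralog pairs
#'
#' For each pair: translate-free protein-guided codon alignment (the peptide
#' is derived by translating the CDS), then [ng86_ks()].
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (see [pair_paralogs()]).
#' @param cds Named character vector of coding sequences (one per locus,
#'   longest isoform; see [select_longest_isoforms()]).
#' @return data.frame with the pair columns plus `ks`, `ka`, `ps`, `pn`,
#'   `saturated`, `codons_compared`.
#' @export
ks_for_pairs <- function(pairs, cds) {
  missing_cds <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing_cds)) stop("no CDS for gene ", missing_cds[1L])
  pep <- vapply(cds, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }, character(1))
  pep <- sub("\\*$", "", pep)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]
    b <- pairs$gene_b[i]
    aln <- align_proteins_global(pep[[a]], pep[[b]])
    cod <- thread_codons(aln, cds[[a]], cds[[b]], a, b)
    est <- ng86_ks(cod$a, cod$b)
    data.frame(gene_a = a, gene_b = b, ks = est$ks, ka = est$ka,
               ps = est$ps, pn = est$pn, saturated = est$saturated,
               codons_compared = est$codons_compared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
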