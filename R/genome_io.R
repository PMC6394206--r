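#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and returned in file order, named by the first
#' whitespace-delimited token of each header.  Works for nucleotide and
#' peptide FASTA alike.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate id ", ids[duplicated(ids)][1L], " in ", path)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id ", ids[!nzchar(seqs)][1L])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Construct a genome annotation of gene loci
#'
#' The canonical in-memory annotation: one row per locus with 1-based
#' inclusive coordinates, sorted within each sequence by start (ties by end,
#' then gene id), and a dense 0-based `rank` giving each locus its positional
#' index along its pseudomolecule.  Clustering operates on these ranks.
#'
#' @param genes data.frame with columns `gene_id`, `seq_id`, `start`, `end`
#'   and optionally `strand` (defaults to `"+"`).
#' @return A `genome_annotation` (a sorted data.frame with a `rank` column).
#' @export
genome_annotation <- function(genes) {
  req <- c("gene_id", "seq_id", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(genes$strand)) genes$strand <- "+"
  genes <- genes[, c(req, "strand")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$seq_id <- as.character(genes$seq_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  if (any(genes$start < 1L)) stop("start coordinates must be >= 1")
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start][1L]
    stop("end < start for gene ", bad)
  }
  o <- order(genes$seq_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- as.integer(
    unlist(lapply(split(seq_len(nrow(genes)), genes$seq_id),
                  function(i) seq_along(i) - 1L), use.names = FALSE)
  )
  # split() orders groups alphabetically; rows are already sorted that way
  rownames(genes) <- NULL
  class(genes) <- c("genome_annotation", "data.frame")
  genes
}

#' Read gene loci from a GFF3 file
#'
#' Only rows of the configured locus feature type become loci; mRNA and exon
#' rows are ignored so clustering counts loci, not isoforms.  Coordinates are
#' kept 1-based inclusive (GFF3 convention).
#'
#' @param path Path to a GFF3 file.
#' @param locus_feature Feature type treated as a gene locus.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path, locus_feature = "gene") {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[as.character(g$type) == locus_feature]
  if (length(g) == 0L) stop("no '", locus_feature, "' features in ", path)
  ids <- as.character(g$ID)
  if (any(is.na(ids) | !nzchar(ids))) {
    stop("feature without ID attribute in ", path)
  }
  strand <- as.character(BiocGenerics::strand(g))
  strand[strand == "*"] <- "+"
  genome_annotation(data.frame(
    gene_id = ids,
    seq_id = as.character(GenomeInfoDb::seqnames(g)),
    start = BiocGenerics::start(g),
    end = BiocGenerics::end(g),
    strand = strand,
    stringsAsFactors = FALSE
  ))
}

#' Write gene loci as GFF3
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(annotation, path, source = "dupscan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  with(annotation, writeLines(sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    seq_id, source, start, end, strand, gene_id), con))
  invisible(path)
}

#' Read a 12-column tabular similarity-hit file
#'
#' Standard `outfmt 6`-style columns: query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bitscore.  No filtering is applied here.
#'
#' @param path Path to the tab-separated hits file.
#' @return data.frame of hits (possibly zero rows).
#' @export
read_hits_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bitscore")
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) {
    return(as.data.frame(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10L)), cols)))
  }
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop(sprintf("line %d: expected 12 columns, got %d", bad[1L], nf[bad[1L]]))
  }
  h <- read.table(path, sep = "\t", quote = "", comment.char = "",
                  col.names = cols, stringsAsFactors = FALSE)
  if (any(h$percent_identity < 0 | h$percent_identity > 100)) {
    stop("percent_identity outside [0, 100]")
  }
  if (any(h$alignment_length < 1)) stop("alignment_length < 1")
  h
}

#' Write intervals as BED6
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention at this boundary (`start - 1`, `end`).
#'
#' @param intervals data.frame with `seq_id`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (any(intervals$start > intervals$end)) stop("start > end in intervals")
  if (any(intervals$start < 1L)) stop("1-based start must be >= 1")
  name <- intervals$name %||% rep(".", nrow(intervals))
  score <- intervals$score %||% rep(0L, nrow(intervals))
  strand <- intervals$strand %||% rep(".", nrow(intervals))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     intervals$seq_id, as.integer(intervals$start) - 1L,
                     as.integer(intervals$end), name, score, strand),
             path)
  invisible(path)
}

#' Read BED intervals back to 1-based inclusive coordinates
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return data.frame with `seq_id`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  b <- read.table(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  data.frame(
    seq_id = b[[1L]],
    start = as.integer(b[[2L]]) + 1L,
    end = as.integer(b[[3L]]),
    name = if (ncol(b) >= 4L) b[[4L]] else ".",
    strand = if (ncol(b) >= 6L) b[[6L]] else ".",
    stringsAsFactors = FALSE
  )
}

#' Read an FPKM expression matrix
#'
#' Expects a TSV with a header row of sample ids and a first column of gene
#' ids.  Values must be non-negative; gene and sample ids must be unique.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(x[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id ", ids[duplicated(ids)][1L])
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative FPKM values")
  rownames(m) <- ids
  m
}

#' Write an FPKM expression matrix as TSV
#'
#' @param m Numeric matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @param id_column Header for the gene-id column.
#' @export
write_expression_table <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
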