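# Tandem-repeat detection: telomere-motif tracts and monomer arrays.

# chain sorted match intervals into runs where neighbours are separated by
# <= max_gap bp; returns data.frame(start, end, copies) per run
chain_matches <- function(starts, ends, max_gap) {
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      copies = integer(0)))
  }
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  n <- length(starts)
  brk <- if (n > 1L) (starts[-1L] - ends[-n] - 1L) > max_gap else logical(0)
  grp <- cumsum(c(TRUE, brk))
  data.frame(
    start = tapply(starts, grp, min),
    end = tapply(ends, grp, max),
    copies = as.integer(tapply(starts, grp, length)),
    row.names = NULL
  )
}

#' Find telomere-repeat tracts
#'
#' Scans a sequence for maximal tandem runs of an exact telomere motif
#' (forward strand) or of its reverse complement (minus strand), merging
#' consecutive motif copies separated by at most `max_gap_bp`.  Runs with at
#' least `min_copies` copies are reported.  The default motif is the plant
#' (Arabidopsis-type) telomere repeat.
#'
#' @param seq A single sequence: character scalar, optionally named by its
#'   sequence id.
#' @param motif Telomere repeat unit (given for the forward/plus strand).
#' @param min_copies Minimum motif copies in a reported tract.
#' @param max_gap_bp Maximum gap between consecutive motif copies within a
#'   tract, in bp.
#' @param end_window_bp A tract within this many bp of either sequence end is
#'   flagged `at_end`.
#' @param seq_id Sequence id used in the output; defaults to `names(seq)`.
#' @return data.frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `copies`, `strand`, `at_end`.
#' @export
find_telomere_tracts <- function(seq, motif = "TTTAGGG", min_copies = 10L,
                                 max_gap_bp = 21L, end_window_bp = 100000L,
                                 seq_id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(motif))
  seq_id <- seq_id %||% names(seq) %||% "seq"
  subject <- Biostrings::DNAString(seq[[1L]])
  len <- length(subject)
  one_strand <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject)
    runs <- chain_matches(BiocGenerics::start(m), BiocGenerics::end(m),
                          max_gap_bp)
    runs <- runs[runs$copies >= min_copies, , drop = FALSE]
    if (nrow(runs) == 0L) return(NULL)
    data.frame(seq_id = seq_id, start = as.integer(runs$start),
               end = as.integer(runs$end), copies = runs$copies,
               strand = strand,
               at_end = runs$start <= end_window_bp |
                 runs$end >= len - end_window_bp + 1L,
               stringsAsFactors = FALSE)
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  out <- rbind(one_strand(motif, "+"), one_strand(rc, "-"))
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), copies = integer(0),
                      strand = character(0), at_end = logical(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start), , drop = FALSE]
}

# anchor candidate monomer copy starts by exact k-mer seeds taken every k bp
# along the monomer; returns sorted unique candidate starts (1-based)
seed_anchors <- function(subject, monomer, k) {
  offsets <- seq(1L, nchar(monomer) - k + 1L, by = k)
  seeds <- substring(monomer, offsets, offsets + k - 1L)
  keep <- !grepl("[^ACGT]", seeds)
  offsets <- offsets[keep]
  seeds <- seeds[keep]
  if (length(seeds) == 0L) return(integer(0))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  hits <- Biostrings::matchPDict(pd, subject)
  anchors <- unlist(lapply(seq_along(seeds), function(i) {
    BiocGenerics::start(hits[[i]]) - (offsets[i] - 1L)
  }), use.names = FALSE)
  anchors <- sort(unique(anchors[anchors >= 1L]))
  # collapse anchors closer than half a monomer (same copy seen via slightly
  # shifted seeds); keep the first of each clump
  if (length(anchors) > 1L) {
    res <- anchors[1L]
    for (a in anchors[-1L]) {
      if (a - res[length(res)] > nchar(monomer) %/% 2L) res <- c(res, a)
    }
    anchors <- res
  }
  anchors
}

ungapped_identity <- function(subject_chars, start, monomer_chars) {
  L <- length(monomer_chars)
  end <- start + L - 1L
  if (start < 1L || end > length(subject_chars)) return(NA_real_)
  100 * sum(subject_chars[start:end] == monomer_chars) / L
}

#' Find tandem arrays of a monomer sequence
#'
#' Locates copies of a query monomer (e.g. a 5S rDNA unit) by exact k-mer
#' seeding plus ungapped extension, then chains co-oriented copies whose
#' start-to-start spacing is at most `max_spacing_factor` times the monomer
#' length into arrays.  Both strands are searched.
#'
#' @param seq A single sequence (character scalar, optionally named).
#' @param monomer Monomer sequence, length >= `seed_k`.
#' @param min_copies Minimum chained copies in a reported array.
#' @param max_spacing_factor Maximum start-to-start spacing between
#'   consecutive copies, as a multiple of the monomer length.
#' @param min_match_identity Minimum percent identity of an ungapped copy
#'   match.
#' @param seed_k Exact-seed length in bp.
#' @param seq_id Sequence id for the output; defaults to `names(seq)`.
#' @return data.frame with `seq_id`, `start`, `end`, `strand`,
#'   `copy_number`, `monomer_len` (median start-to-start spacing) and
#'   `mean_identity`.
#' @export
find_monomer_arrays <- function(seq, monomer, min_copies = 5L,
                                max_spacing_factor = 1.5,
                                min_match_identity = 80,
                                seed_k = 15L, seq_id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  monomer <- toupper(unname(monomer[[1L]]))
  if (nchar(monomer) < seed_k) {
    stop("monomer shorter than seed length (", seed_k, " bp)")
  }
  if (nchar(monomer) < 10L) stop("monomer must be >= 10 bp")
  seq_id <- seq_id %||% names(seq) %||% "seq"
  subject <- Biostrings::DNAString(seq[[1L]])
  subject_chars <- strsplit(as.character(subject), "", fixed = TRUE)[[1L]]
  L <- nchar(monomer)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(monomer)))

  one_strand <- function(mono, strand) {
    mono_chars <- strsplit(mono, "", fixed = TRUE)[[1L]]
    anchors <- seed_anchors(subject, mono, seed_k)
    if (length(anchors) == 0L) return(NULL)
    idn <- vapply(anchors, function(a) {
      ungapped_identity(subject_chars, a, mono_chars)
    }, numeric(1))
    keep <- !is.na(idn) & idn >= min_match_identity
    anchors <- anchors[keep]
    idn <- idn[keep]
    if (length(anchors) < min_copies) return(NULL)
    brk <- diff(anchors) > max_spacing_factor * L
    grp <- cumsum(c(TRUE, brk))
    out <- lapply(split(seq_along(anchors), grp), function(i) {
      if (length(i) < min_copies) return(NULL)
      a <- anchors[i]
      data.frame(seq_id = seq_id,
                 start = a[1L],
                 end = a[length(a)] + L - 1L,
                 strand = strand,
                 copy_number = length(a),
                 monomer_len = as.integer(round(median(diff(a)))),
                 mean_identity = mean(idn[i]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  out <- rbind(one_strand(monomer, "+"), one_strand(rc, "-"))
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      copy_number = integer(0), monomer_len = integer(0),
                      mean_identity = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}
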