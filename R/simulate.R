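# Synthetic-genome, paralog-pair and expression-table generators with
# planted ground truth.  Defaults define the package's reference study
# conditions: a desk-scale annotated genome with planted family clusters
# (including one two-family co-cluster), telomere tracts at pseudomolecule
# ends, a 5S-like monomer array, paralog pairs drawn from a three-component
# Ks mixture, and replicated FPKM tables with planted diverged/conserved
# duplicate pairs.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Default genome simulation configuration
#'
#' Three 1-Mbp pseudomolecules carrying 240 gene loci; planted clusters: a
#' five-copy TPS cluster, a two-copy TPS cluster, a three-copy CYP cluster
#' and a mixed TPS/CYP co-cluster; telomere tracts at three pseudomolecule
#' ends; one 5S-like tandem array of 135 copies of a 496-bp monomer.
#'
#' @param seed Mandatory RNG seed.
#' @return Config list accepted by [simulate_genome()].
#' @export
genome_sim_config <- function(seed) {
  list(
    seed = seed,
    genome = list(
      n_pseudomolecules = 3L,
      lengths = c(1000000L, 1000000L, 1000000L),
      gene_count = 240L,
      gene_length = c(500L, 3000L)
    ),
    clusters = list(
      list(family = "TPS", size = 5L, gap_bp = 20000L, intervening_genes = 2L),
      list(family = "TPS", size = 2L, gap_bp = 50000L, intervening_genes = 5L),
      list(family = "CYP", size = 3L, gap_bp = 30000L, intervening_genes = 3L),
      list(family = c("TPS", "CYP"), size = 4L, gap_bp = 15000L,
           intervening_genes = 1L)
    ),
    telomeres = list(
      list(seq_id = "pm01", end = "left", copies = 50L),
      list(seq_id = "pm01", end = "right", copies = 50L),
      list(seq_id = "pm02", end = "right", copies = 30L)
    ),
    arrays = list(
      list(seq_id = "pm03", monomer_len = 496L, copies = 135L,
           mutation_rate = 0.01)
    ),
    telomere_motif = "TTTAGGG"
  )
}

# place an interval of width w uniformly on [1, L] avoiding `occupied`
# (2-col matrix of start,end), with `margin` bp padding; NA if no fit found
place_interval <- function(L, w, occupied, margin = 0L, tries = 200L) {
  for (i in seq_len(tries)) {
    s <- sample.int(L - w + 1L, 1L)
    e <- s + w - 1L
    if (nrow(occupied) == 0L ||
        all(e + margin < occupied[, 1L] | s - margin > occupied[, 2L])) {
      return(c(s, e))
    }
  }
  NA_integer_
}

#' Simulate an annotated genome with planted ground truth
#'
#' Generates uniform-random background sequence per pseudomolecule, places
#' non-overlapping gene loci, plants family clusters that satisfy their
#' configured inter-member gaps and intervening-gene counts, writes telomere
#' tracts at configured ends (plus-strand motif on right ends, reverse
#' complement on left ends) and inserts monomer tandem arrays.  Everything
#' is deterministic given the config seed.
#'
#' @param config Config list (see [genome_sim_config()]): fields `seed`,
#'   `genome`, `clusters`, `telomeres`, `arrays`, `telomere_motif`.
#' @param out_dir Optional directory; when given, FASTA, GFF3 and truth TSVs
#'   are written there.
#' @return list with `sequences` (named character), `annotation`
#'   (a [genome_annotation()]) and `truth` (member-level data.frame
#'   `clusters`, plus `telomeres`, `arrays` and the `monomers` sequences).
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  stopifnot(!is.null(config$seed))
  with_seed(config$seed, {
    g <- config$genome
    n_pm <- g$n_pseudomolecules
    lens <- as.integer(g$lengths)
    stopifnot(length(lens) == n_pm)
    pm_ids <- sprintf("pm%02d", seq_len(n_pm))
    names(lens) <- pm_ids
    motif <- config$telomere_motif %||% "TTTAGGG"
    motif_rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    glen_rng <- g$gene_length %||% c(500L, 3000L)
    draw_glen <- function(k) sample(glen_rng[1L]:glen_rng[2L], k,
                                    replace = TRUE)

    occupied <- setNames(lapply(pm_ids, function(i) {
      matrix(integer(0), 0L, 2L)
    }), pm_ids)
    add_occ <- function(sid, s, e) {
      occupied[[sid]] <<- rbind(occupied[[sid]], c(s, e))
    }

    # telomere tracts at configured ends
    telo_truth <- NULL
    for (tl in config$telomeres %||% list()) {
      w <- tl$copies * nchar(motif)
      L <- lens[[tl$seq_id]]
      if (w > L) stop("telomere tract exceeds sequence length")
      if (identical(tl$end, "left")) {
        s <- 1L
        strand <- "-"
      } else {
        s <- L - w + 1L
        strand <- "+"
      }
      e <- s + w - 1L
      add_occ(tl$seq_id, s, e)
      telo_truth <- rbind(telo_truth, data.frame(
        seq_id = tl$seq_id, start = s, end = e, copies = tl$copies,
        strand = strand, stringsAsFactors = FALSE))
    }

    # monomer tandem arrays
    array_truth <- NULL
    monomers <- character(0)
    for (ai in seq_along(config$arrays %||% list())) {
      ar <- config$arrays[[ai]]
      monomer <- random_dna(ar$monomer_len)
      arr_units <- vapply(seq_len(ar$copies), function(i) {
        u <- strsplit(monomer, "", fixed = TRUE)[[1L]]
        nmut <- stats::rbinom(1L, ar$monomer_len, ar$mutation_rate %||% 0)
        if (nmut > 0L) {
          pos <- sample.int(ar$monomer_len, nmut)
          for (p in pos) {
            u[p] <- sample(setdiff(c("A", "C", "G", "T"), u[p]), 1L)
          }
        }
        paste(u, collapse = "")
      }, character(1))
      w <- ar$monomer_len * ar$copies
      L <- lens[[ar$seq_id]]
      pos <- place_interval(L, w, occupied[[ar$seq_id]], margin = 1000L)
      if (anyNA(pos)) stop("could not place array ", ai)
      add_occ(ar$seq_id, pos[1L], pos[2L])
      aid <- sprintf("array%02d", ai)
      monomers[[aid]] <- monomer
      array_truth <- rbind(array_truth, data.frame(
        array_id = aid, seq_id = ar$seq_id, start = pos[1L], end = pos[2L],
        copies = ar$copies, monomer_len = ar$monomer_len,
        mutation_rate = ar$mutation_rate %||% 0,
        sequence = paste(arr_units, collapse = ""),
        stringsAsFactors = FALSE))
    }

    # planted clusters: members separated by exactly gap_bp with
    # `intervening_genes` background loci inside each gap
    genes <- NULL
    cluster_truth <- NULL
    bg_counter <- 0L
    for (ci in seq_along(config$clusters %||% list())) {
      cl <- config$clusters[[ci]]
      fam <- rep(cl$family, length.out = cl$size)
      mlen <- draw_glen(cl$size)
      need_gap <- cl$intervening_genes * (glen_rng[1L] + 20L) + 40L
      if (cl$gap_bp < need_gap && cl$intervening_genes > 0L) {
        stop("cluster ", ci, ": gap_bp too small for intervening genes")
      }
      # relative layout
      starts <- integer(cl$size)
      starts[1L] <- 1L
      if (cl$size > 1L) {
        for (i in 2:cl$size) {
          starts[i] <- starts[i - 1L] + mlen[i - 1L] + cl$gap_bp
        }
      }
      span <- starts[cl$size] + mlen[cl$size] - 1L
      sid <- cl$seq_id %||% pm_ids[(ci - 1L) %% n_pm + 1L]
      # 150 kbp buffer keeps separate planted clusters from chaining under
      # the default distance rule
      pos <- place_interval(lens[[sid]], span, occupied[[sid]],
                            margin = 150000L)
      if (anyNA(pos)) stop("could not place cluster ", ci)
      add_occ(sid, pos[1L], pos[2L])
      cid <- sprintf("cluster%02d", ci)
      mem_ids <- sprintf("%s_%s_m%d", cid, fam, seq_len(cl$size))
      mem_start <- pos[1L] + starts - 1L
      genes <- rbind(genes, data.frame(
        gene_id = mem_ids, seq_id = sid, start = mem_start,
        end = mem_start + mlen - 1L,
        strand = sample(c("+", "-"), cl$size, replace = TRUE),
        stringsAsFactors = FALSE))
      cluster_truth <- rbind(cluster_truth, data.frame(
        cluster_id = cid, gene_id = mem_ids, family = fam, seq_id = sid,
        start = mem_start, end = mem_start + mlen - 1L,
        gap_bp = cl$gap_bp, intervening_genes = cl$intervening_genes,
        stringsAsFactors = FALSE))
      # intervening background genes, centered in each gap
      if (cl$size > 1L && cl$intervening_genes > 0L) {
        for (i in 1:(cl$size - 1L)) {
          gap_s <- mem_start[i] + mlen[i]        # first bp after member i
          slot <- cl$gap_bp %/% (cl$intervening_genes + 1L)
          for (j in seq_len(cl$intervening_genes)) {
            bg_counter <- bg_counter + 1L
            blen <- min(draw_glen(1L), slot - 20L)
            bs <- gap_s + (j - 1L) * slot + 10L
            genes <- rbind(genes, data.frame(
              gene_id = sprintf("bg%04d", bg_counter), seq_id = sid,
              start = bs, end = bs + blen - 1L,
              strand = sample(c("+", "-"), 1L),
              stringsAsFactors = FALSE))
          }
        }
      }
    }

    # remaining background genes, uniform over pseudomolecules by length
    n_left <- g$gene_count - (if (is.null(genes)) 0L else nrow(genes))
    attempts <- 0L
    max_attempts <- 50L * max(n_left, 1L)
    while (n_left > 0L) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("requested gene content exceeds available genome space")
      }
      bg_counter <- bg_counter + 1L
      sid <- sample(pm_ids, 1L, prob = lens)
      blen <- draw_glen(1L)
      pos <- place_interval(lens[[sid]], blen, occupied[[sid]],
                            margin = 10L)
      if (anyNA(pos)) next
      add_occ(sid, pos[1L], pos[2L])
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("bg%04d", bg_counter), seq_id = sid,
        start = pos[1L], end = pos[2L],
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE))
      n_left <- n_left - 1L
    }

    annotation <- genome_annotation(genes)

    # sequence: random background, then overwrite planted repeat content
    sequences <- setNames(vapply(pm_ids, function(sid) {
      random_dna(lens[[sid]])
    }, character(1)), pm_ids)
    if (!is.null(telo_truth)) {
      for (i in seq_len(nrow(telo_truth))) {
        tt <- telo_truth[i, ]
        unit <- if (tt$strand == "+") motif else motif_rc
        tract <- strrep(unit, tt$copies)
        substr(sequences[[tt$seq_id]], tt$start, tt$end) <- tract
      }
    }
    if (!is.null(array_truth)) {
      for (i in seq_len(nrow(array_truth))) {
        at <- array_truth[i, ]
        substr(sequences[[at$seq_id]], at$start, at$end) <- at$sequence
      }
    }
    array_truth$sequence <- NULL

    truth <- list(
      clusters = cluster_truth %||% data.frame(),
      telomeres = telo_truth %||% data.frame(),
      arrays = array_truth %||% data.frame(),
      monomers = monomers
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(sequences, file.path(out_dir, "genome.fasta"), width = 80L)
      write_gff3(annotation, file.path(out_dir, "genes.gff3"))
      if (length(monomers)) {
        write_fasta(monomers, file.path(out_dir, "monomers.fasta"))
      }
      for (nm in c("clusters", "telomeres", "arrays")) {
        if (nrow(truth[[nm]])) {
          write.table(truth[[nm]], file.path(out_dir,
                                             paste0("truth_", nm, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
    list(sequences = sequences, annotation = annotation, truth = truth)
  })
}

#' Default Ks-mixture pair simulation configuration
#'
#' Three components emulating a paralog age distribution with a WGD-scale
#' middle peak: weights (0.3, 0.5, 0.2), means (0.22, 0.60, 1.36), standard
#' deviations (0.06, 0.15, 0.30); 3000 pairs of 240-codon CDS evolved at
#' ka/ks = 0.2 to within 0.02 of their target Ks.
#'
#' @param seed Mandatory RNG seed.
#' @param n_pairs Number of pairs.
#' @return Config list accepted by [simulate_ks_pairs()].
#' @export
ks_sim_config <- function(seed, n_pairs = 3000L) {
  list(seed = seed,
       ks_mixture = list(weights = c(0.3, 0.5, 0.2),
                         means = c(0.22, 0.60, 1.36),
                         sds = c(0.06, 0.15, 0.30),
                         n_pairs = n_pairs),
       n_codons = 240L, omega = 0.2, tol = 0.02)
}

#' Simulate paralog CDS pairs from a Ks mixture
#'
#' Per pair: the target Ks is drawn from the configured Gaussian mixture
#' (truncated at 0), a random stop-free ancestor CDS is generated, and the
#' two copies accumulate substitutions (synonymous always accepted,
#' nonsynonymous with probability `omega`, stops rejected) until the NG86 Ks
#' of the pair is within `tol` of the target or the pair saturates.
#' Saturated/unreachable pairs are flagged and excluded from the truth
#' component labels.
#'
#' @param config Config list (see [ks_sim_config()]).
#' @return list with `cds_a`, `cds_b` (named character vectors) and `truth`
#'   data.frame (`pair_id`, `component`, `target_ks`, `realized_ks`,
#'   `saturated`).
#' @export
simulate_ks_pairs <- function(config) {
  stopifnot(!is.null(config$seed))
  mx <- config$ks_mixture
  stopifnot(abs(sum(mx$weights) - 1) < 1e-8)
  n_pairs <- mx$n_pairs
  if (n_pairs == 0L) {
    return(list(cds_a = character(0), cds_b = character(0),
                truth = data.frame(pair_id = character(0),
                                   component = integer(0),
                                   target_ks = numeric(0),
                                   realized_ks = numeric(0),
                                   saturated = logical(0))))
  }
  tab <- ng86_tables()
  non_stop <- which(!is.na(tab$syn))
  n_codons <- config$n_codons %||% 240L
  omega <- config$omega %||% 0.2
  tol <- config$tol %||% 0.02
  with_seed(config$seed, {
    comp <- sample.int(length(mx$weights), n_pairs, replace = TRUE,
                       prob = mx$weights)
    target <- rnorm(n_pairs, mx$means[comp], mx$sds[comp])
    target <- pmax(target, 0)
    cds_a <- cds_b <- character(n_pairs)
    realized <- numeric(n_pairs)
    saturated <- logical(n_pairs)
    for (i in seq_len(n_pairs)) {
      anc <- sample(non_stop, n_codons, replace = TRUE)
      ev <- evolve_pair_cpp(anc, target[i], tol, omega, tab$syn, tab$Sd,
                            tab$Nd, tab$mut_new, tab$mut_syn, tab$mut_stop,
                            max_steps = 400L * n_codons)
      cds_a[i] <- paste(tab$codons[ev$a], collapse = "")
      cds_b[i] <- paste(tab$codons[ev$b], collapse = "")
      realized[i] <- ev$ks
      saturated[i] <- ev$saturated
    }
    ids <- sprintf("pair%05d", seq_len(n_pairs))
    names(cds_a) <- paste0(ids, "_a")
    names(cds_b) <- paste0(ids, "_b")
    truth <- data.frame(pair_id = ids,
                        component = ifelse(saturated, NA_integer_, comp),
                        target_ks = target, realized_ks = realized,
                        saturated = saturated, stringsAsFactors = FALSE)
    list(cds_a = cds_a, cds_b = cds_b, truth = truth)
  })
}

#' Default expression simulation configuration
#'
#' Six tissues with two replicates each (log-scale replicate correlation
#' target 0.98), 200 background genes, 20 planted diverged duplicate pairs
#' (complementary tissue profiles) and 20 planted conserved pairs, lognormal
#' noise sigma 0.3 on the log2 scale.
#'
#' @param seed Mandatory RNG seed.
#' @return Config list accepted by [simulate_expression()].
#' @export
expression_sim_config <- function(seed) {
  list(seed = seed,
       expression = list(
         tissues = c("leaf", "root", "flower", "seedling", "stem12yr",
                     "branch12yr"),
         replicates = 2L,
         replicate_r_target = 0.98,
         n_genes = 200L,
         diverged_pairs = 20L,
         conserved_pairs = 20L,
         noise_sd = 0.3))
}

#' Simulate an FPKM expression table with planted duplicate-pair structure
#'
#' Base expression profiles are lognormal (gene and tissue effects on the
#' log2 scale); biological replicates are generated with a configurable
#' log-scale correlation; planted diverged pairs receive complementary
#' on/off tissue profiles while planted conserved pairs share one profile.
#'
#' @param config Config list (see [expression_sim_config()]).
#' @return list with `table` (FPKM matrix, columns `<tissue>_rep<i>`),
#'   `tissue_table` (replicate-1 columns only, named by tissue),
#'   `replicate_pairs` data.frame, and `truth` (data.frames `diverged`,
#'   `conserved`).
#' @export
simulate_expression <- function(config) {
  stopifnot(!is.null(config$seed))
  ex <- config$expression
  tissues <- ex$tissues
  if (length(tissues) < 2L) stop("need at least 2 tissues")
  reps <- ex$replicates %||% 2L
  rho <- ex$replicate_r_target %||% 0.98
  noise_sd <- ex$noise_sd %||% 0.3
  with_seed(config$seed, {
    n_bg <- ex$n_genes %||% 200L
    ids_bg <- sprintf("gene%04d", seq_len(n_bg))
    nt <- length(tissues)
    # background: gene effect + tissue effect, log2 scale
    base <- matrix(rnorm(n_bg * nt, 0, 1), n_bg, nt) +
      rnorm(n_bg, 3, 1.5)
    rownames(base) <- ids_bg
    on_level <- 5
    off_level <- -2
    div_truth <- cons_truth <- NULL
    half <- seq_len(nt %/% 2L)
    for (i in seq_len(ex$diverged_pairs %||% 0L)) {
      a <- sprintf("div%03d_a", i)
      b <- sprintf("div%03d_b", i)
      pa <- rep(off_level, nt)
      pa[half] <- on_level + rnorm(1)
      pb <- rep(off_level, nt)
      pb[-half] <- on_level + rnorm(1)
      base <- rbind(base, rbind(pa, pb))
      rownames(base)[nrow(base) - 1:0] <- c(a, b)
      div_truth <- rbind(div_truth, data.frame(gene_a = a, gene_b = b,
                                               stringsAsFactors = FALSE))
    }
    for (i in seq_len(ex$conserved_pairs %||% 0L)) {
      a <- sprintf("cons%03d_a", i)
      b <- sprintf("cons%03d_b", i)
      p <- on_level / 2 + rnorm(nt, 0, 2) + rnorm(1)
      base <- rbind(base, rbind(p, p))
      rownames(base)[nrow(base) - 1:0] <- c(a, b)
      cons_truth <- rbind(cons_truth, data.frame(gene_a = a, gene_b = b,
                                                 stringsAsFactors = FALSE))
    }
    n_genes <- nrow(base)
    # per-gene biological (lognormal) noise is part of the profile shared by
    # replicates; replicate-specific noise alone sets the replicate
    # correlation.  The target correlation applies to raw FPKM, so the
    # required log-scale correlation is backed out through the lognormal
    # moment relation r_raw = (exp(rho_log*s2) - 1) / (exp(s2) - 1).
    base <- base + matrix(rnorm(n_genes * nt, 0, noise_sd), n_genes, nt)
    sigma_p <- sd(as.vector(base))
    s2 <- (sigma_p * log(2))^2
    rho_log <- min(log(1 + rho * (exp(s2) - 1)) / s2, 1 - 1e-9)
    sigma_e <- sigma_p * sqrt((1 - rho_log) / rho_log)
    cols <- as.vector(outer(tissues, seq_len(reps),
                            function(t, r) paste0(t, "_rep", r)))
    tab <- matrix(0, n_genes, length(cols),
                  dimnames = list(rownames(base), cols))
    for (r in seq_len(reps)) {
      noise <- matrix(rnorm(n_genes * nt, 0, sigma_e), n_genes, nt)
      tab[, paste0(tissues, "_rep", r)] <- pmax(2^(base + noise) - 0.25, 0)
    }
    replicate_pairs <- if (reps >= 2L) {
      data.frame(sample_a = paste0(tissues, "_rep1"),
                 sample_b = paste0(tissues, "_rep2"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_a = character(0), sample_b = character(0))
    }
    tissue_table <- tab[, paste0(tissues, "_rep1"), drop = FALSE]
    colnames(tissue_table) <- tissues
    list(table = tab, tissue_table = tissue_table,
         replicate_pairs = replicate_pairs,
         truth = list(diverged = div_truth %||%
                        data.frame(gene_a = character(0),
                                   gene_b = character(0)),
                      conserved = cons_truth %||%
                        data.frame(gene_a = character(0),
                                   gene_b = character(0))))
  })
}
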