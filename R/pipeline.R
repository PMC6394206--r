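# End-to-end orchestration: one config drives I/O, assembly metrics, repeat
# arrays, family assignment, cluster detection, Ks/WGD inference and
# expression analysis, writing per-stage TSV/BED artifacts plus a JSON
# summary.

#' Default pipeline parameter preset
#'
#' The printed-parameter defaults used throughout the package: cluster rule
#' (10 intervening genes, 100 kbp), family filter (350 aa, 30% identity),
#' replicate-correlation threshold (r > 0.94), Ks window [0.01, 2], and the
#' repeat-array defaults.
#'
#' @return Named list of stage parameter blocks.
#' @export
pipeline_defaults <- function() {
  list(
    clusters = list(max_intervening_genes = 10L,
                    max_pair_distance_bp = 100000L),
    family = list(min_peptide_len = 350L, min_best_identity = 30),
    telomeres = list(motif = "TTTAGGG", min_copies = 10L, max_gap_bp = 21L,
                     end_window_bp = 100000L),
    arrays = list(min_copies = 5L, max_spacing_factor = 1.5,
                  min_match_identity = 80),
    ks = list(max_evalue = 1e-10, min_aln_len = 100L,
              window = c(0.01, 2.0), k_range = 1:5, n_restarts = 10L),
    expression = list(min_replicate_r = 0.94, expressed_fpkm = 1.0,
                      r_threshold = 0.5)
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  config
}

merge_params <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  defaults[names(override)] <- override
  defaults
}

#' Run the full analysis pipeline
#'
#' Runs the enabled stages in dependency order (inputs -> assembly metrics /
#' repeat arrays -> family assignment -> clusters -> Ks/WGD -> expression),
#' writes per-stage TSV/BED artifacts and a `summary.json` into the output
#' directory, and returns the summary invisibly.  A failing stage aborts
#' with an error naming the stage.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   `inputs` (paths: `fasta`, `gff3`, `peptides`, `cds`, `hits`,
#'   `self_hits`, `expression`, `monomers`), `stages` (named logical flags:
#'   `metrics`, `telomeres`, `arrays`, `family`, `clusters`, `ks`,
#'   `expression`), `params` (overrides of [pipeline_defaults()]),
#'   `out_dir`, `seed`.
#' @return Summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||% list()
  params <- lapply(names(pipeline_defaults()), function(nm) {
    merge_params(pipeline_defaults()[[nm]], cfg$params[[nm]])
  })
  names(params) <- names(pipeline_defaults())
  seed <- cfg$seed %||% 1L
  summary <- list(seed = seed, parameters = params)
  message("pipeline: seed=", seed, ", out_dir=", out_dir)

  run_stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) return(NULL)
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  need_input <- function(field) {
    path <- cfg$inputs[[field]]
    if (is.null(path)) stop("input '", field, "' not configured")
    if (!file.exists(path)) stop("input file not found: ", path)
    path
  }

  sequences <- NULL
  get_sequences <- function() {
    if (is.null(sequences)) sequences <<- read_fasta(need_input("fasta"))
    sequences
  }

  run_stage("metrics", stages$metrics, function() {
    lens <- nchar(get_sequences())
    s <- assembly_summary(lens)
    summary$metrics <<- unclass(s)
    sct <- size_class_table(lens)
    write.table(sct, file.path(out_dir, "size_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  run_stage("telomeres", stages$telomeres, function() {
    p <- params$telomeres
    tr <- do.call(rbind, lapply(names(get_sequences()), function(sid) {
      find_telomere_tracts(get_sequences()[sid], motif = p$motif,
                           min_copies = p$min_copies,
                           max_gap_bp = p$max_gap_bp,
                           end_window_bp = p$end_window_bp)
    }))
    if (is.null(tr)) {
      tr <- data.frame(seq_id = character(0), start = integer(0),
                       end = integer(0), copies = integer(0),
                       strand = character(0), at_end = logical(0))
    }
    write.table(tr, file.path(out_dir, "telomere_tracts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(tr)) tr$name <- sprintf("telomere_%d", seq_len(nrow(tr)))
    write_bed(tr, file.path(out_dir, "telomere_tracts.bed"))
    lens <- nchar(get_sequences())
    both <- vapply(split(seq_len(nrow(tr)), tr$seq_id), function(i) {
      L <- lens[[tr$seq_id[i[1L]]]]
      any(tr$start[i] <= p$end_window_bp) &&
        any(tr$end[i] >= L - p$end_window_bp + 1L)
    }, logical(1))
    summary$telomeres <<- list(
      n_tracts = nrow(tr),
      n_sequences_with_tract = length(unique(tr$seq_id)),
      n_sequences_with_both_ends = sum(both))
  })

  run_stage("arrays", stages$arrays, function() {
    p <- params$arrays
    monomers <- read_fasta(need_input("monomers"))
    ar <- do.call(rbind, lapply(names(get_sequences()), function(sid) {
      do.call(rbind, lapply(names(monomers), function(mid) {
        res <- find_monomer_arrays(get_sequences()[sid], monomers[mid],
                                   min_copies = p$min_copies,
                                   max_spacing_factor = p$max_spacing_factor,
                                   min_match_identity = p$min_match_identity)
        if (nrow(res)) res$monomer_id <- mid
        res
      }))
    }))
    if (is.null(ar)) {
      ar <- data.frame(seq_id = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       copy_number = integer(0), monomer_len = integer(0),
                       mean_identity = numeric(0), monomer_id = character(0))
    }
    write.table(ar, file.path(out_dir, "monomer_arrays.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$arrays <<- list(n_arrays = nrow(ar),
                            total_copies = sum(ar$copy_number))
  })

  family_calls <- NULL
  run_stage("family", stages$family, function() {
    p <- params$family
    peptides <- read_fasta(need_input("peptides"))
    hits <- read_hits_tabular(need_input("hits"))
    fa <- assign_family(peptides, hits,
                        family_label = cfg$family_label %||% "family",
                        min_peptide_len = p$min_peptide_len,
                        min_best_identity = p$min_best_identity)
    family_calls <<- fa
    write.table(fa, file.path(out_dir, "family_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$family <<- list(n_peptides = nrow(fa),
                            n_candidates = sum(fa$qualifies))
  })

  clusters <- NULL
  run_stage("clusters", stages$clusters, function() {
    p <- params$clusters
    ann <- read_gff3(need_input("gff3"))
    members <- if (!is.null(family_calls)) {
      family_calls$gene_id[family_calls$qualifies]
    } else if (!is.null(cfg$inputs$members)) {
      readLines(need_input("members"))
    } else {
      stop("no family members available (enable 'family' or give a members file)")
    }
    cl <- detect_clusters(ann, members,
                          max_intervening_genes = p$max_intervening_genes,
                          max_pair_distance_bp = p$max_pair_distance_bp)
    clusters <<- cl
    write.table(cl, file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sp <- cluster_spans(cl)
    sp$name <- sp$cluster_id
    write_bed(sp, file.path(out_dir, "cluster_spans.bed"))
    summary$clusters <<- summarize_family_clustering(cl, members)
  })

  run_stage("ks", stages$ks, function() {
    p <- params$ks
    cds <- read_fasta(need_input("cds"))
    self_hits <- read_hits_tabular(need_input("self_hits"))
    pairs <- pair_paralogs(self_hits, max_evalue = p$max_evalue,
                           min_aln_len = p$min_aln_len)
    ks <- ks_for_pairs(pairs, cds)
    write.table(ks, file.path(out_dir, "ks_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    vals <- ks$ks[!ks$saturated]
    fit <- fit_gmm(vals, k_range = p$k_range, n_restarts = p$n_restarts,
                   seed = seed, window = p$window)
    map <- sizer(vals[vals >= p$window[1] & vals <= p$window[2]])
    write_sizer_tsv(map, file.path(out_dir, "sizer_map.tsv"))
    modes <- significant_modes(map)
    summary$ks <<- list(n_pairs = nrow(ks),
                        mixture = list(K = fit$K, weights = fit$weights,
                                       means = fit$means, sds = fit$sds,
                                       bic = fit$bic),
                        sizer_modes = modes)
  })

  run_stage("expression", stages$expression, function() {
    p <- params$expression
    tab <- read_expression_table(need_input("expression"))
    res <- list()
    if (!is.null(cfg$replicate_pairs)) {
      rp <- as.data.frame(cfg$replicate_pairs)
      qc <- replicate_correlation(tab, rp,
                                  min_replicate_r = p$min_replicate_r)
      write.table(qc, file.path(out_dir, "replicate_qc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res$replicate_qc <- list(n_pairs = nrow(qc), n_pass = sum(qc$pass))
    }
    if (!is.null(clusters) && nrow(clusters) > 0L) {
      calls <- lapply(split(clusters$gene_id, clusters$cluster_id),
                      function(mm) {
        if (!all(mm %in% rownames(tab))) return(NULL)
        classify_cluster_expression(mm, tab,
                                    expressed_fpkm = p$expressed_fpkm,
                                    r_threshold = p$r_threshold)
      })
      calls <- calls[!vapply(calls, is.null, logical(1))]
      pairs <- do.call(rbind, lapply(names(calls), function(cid) {
        cbind(cluster_id = cid, calls[[cid]]$pairs)
      }))
      if (!is.null(pairs)) {
        write.table(pairs, file.path(out_dir, "expression_divergence.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res$divergence <- list(
          n_pairs = nrow(pairs),
          n_diverged = sum(pairs$call == "diverged"))
      }
    }
    summary$expression <<- res
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
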