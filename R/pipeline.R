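#' Default configuration of the circRNA coding-potential screen
#'
#' Returns the full, defaulted configuration tree. The `simulate` block
#' describes the built-in demo study: a paired tumour/normal cohort in which
#' one planted positive circle (253 nt, 92-aa junction-spanning ORF,
#' upregulated, anti-correlated with an NK activation marker set) hides
#' among a large field of decoy circles. See the methods vignette for the
#' rationale behind each default.
#'
#' @param ... Named overrides, e.g. `screen_config(seed = 3)` or
#'   `screen_config(detect = list(min_unique = 5))`.
#' @return A validated `screen_config` list.
#' @export
screen_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulate = list(
      n_pairs = 12L,            # tumour/normal pairs (24 libraries)
      n_chrom = 2L,
      chrom_length = 80000L,
      gc = 0.45,
      n_genes = 72L,            # annotated multi-exon genes
      n_decoys = 205L,          # decoy circles planted beside the positive
      n_decoy_up = 5L,          # decoys that are genuinely upregulated
      decoy_lfc = 1.5,
      positive_lfc = 2.5,       # planted positive tumour/normal log2 FC
      decoy_base = 4,           # expected normal-tissue read scale
      decoy_up_base = 10,
      positive_base = 24,
      linear_base = 8,
      pair_sd = 1.0,            # shared per-pair log2 effect (circles)
      resid_sd = 0.3,           # per-library residual log2 noise (circles)
      read_len = 150L,
      depth = 4000L,            # reads per library
      err = 0.001,              # per-base substitution rate
      n_expr_genes = 2000L,     # background coding genes
      target_r = -0.8,          # planted NK-set correlation (see vignette)
      corr_noise_sd = 0.3,
      gene_sets = ""            # optional GMT path; "" = built-in NK set
    ),
    detect = list(k = 20L, max_mismatch = 2L, span_cap = 1e5,
                  min_unique = 2L),
    de = list(pseudocount = 0.5, lfc_cut = 1, p_cut = 0.05, adjust = FALSE),
    orf = list(max_aa = 100L, require_junction = TRUE),
    gsea = list(weight = 1, n_perm = 2000L, p_cut = 0.01, mode = "sample")
  )
  validate_config(list(...), defaults = defaults)
}

#' Validate a raw configuration
#'
#' Accepts a YAML file path, YAML text, or a nested list; merges it into the
#' defaults, rejecting unknown keys (with their key path) and out-of-range
#' values. An empty input yields all defaults.
#'
#' @param raw Path to a YAML file, a YAML string, or a named list.
#' @param defaults Defaults tree to merge into (from [screen_config()]).
#' @return A `screen_config` list.
#' @export
validate_config <- function(raw = list(), defaults = NULL) {
  if (is.null(defaults)) return(screen_config_merge_raw(raw))
  raw <- config_as_list(raw)
  cfg <- merge_config(defaults, raw, path = character())
  check_config_ranges(cfg)
  structure(cfg, class = "screen_config")
}

screen_config_merge_raw <- function(raw) {
  do.call(screen_config, config_as_list(raw))
}

config_as_list <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- if (file.exists(raw)) yaml::read_yaml(raw) else
      yaml::yaml.load(raw)
    if (is.null(raw)) raw <- list()
  }
  if (!is.list(raw)) abort("Configuration must be a list or YAML.")
  raw
}

merge_config <- function(defaults, raw, path) {
  if (length(raw) == 0L) return(defaults)
  if (is.null(names(raw)) || any(!nzchar(names(raw)))) {
    abort(sprintf("Unnamed configuration entries under '%s'.",
                  paste(path, collapse = ".")))
  }
  for (nm in names(raw)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      abort(sprintf("Unknown configuration key: %s", here))
    }
    if (is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]],
                                     config_as_list(raw[[nm]]), c(path, nm))
    } else {
      val <- raw[[nm]]
      if (length(val) != 1L || !(is.numeric(val) || is.character(val) ||
                                   is.logical(val))) {
        abort(sprintf("Configuration key %s must be a scalar.", here))
      }
      defaults[[nm]] <- val
    }
  }
  defaults
}

check_config_ranges <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) abort(sprintf("Configuration key %s %s.", key, msg))
  }
  chk(cfg$detect$k >= 10L, "detect.k", "must be >= 10")
  chk(cfg$detect$max_mismatch >= 0L, "detect.max_mismatch", "must be >= 0")
  chk(cfg$detect$min_unique >= 1L, "detect.min_unique", "must be >= 1")
  chk(cfg$detect$span_cap > 0, "detect.span_cap", "must be > 0")
  chk(cfg$simulate$gc > 0 && cfg$simulate$gc < 1, "simulate.gc",
      "must be in (0, 1)")
  chk(cfg$simulate$err >= 0 && cfg$simulate$err < 1, "simulate.err",
      "must be in [0, 1)")
  chk(cfg$simulate$read_len >= 2L * cfg$detect$k, "simulate.read_len",
      "must be >= 2 * detect.k")
  chk(cfg$simulate$n_pairs >= 2L, "simulate.n_pairs", "must be >= 2")
  chk(abs(cfg$simulate$target_r) <= 1, "simulate.target_r",
      "must be in [-1, 1]")
  chk(cfg$gsea$n_perm >= 100L, "gsea.n_perm", "must be >= 100")
  chk(cfg$gsea$p_cut > 0 && cfg$gsea$p_cut <= 1, "gsea.p_cut",
      "must be in (0, 1]")
  chk(cfg$gsea$weight >= 0, "gsea.weight", "must be >= 0")
  chk(cfg$gsea$mode %in% c("sample", "gene_set"), "gsea.mode",
      "must be 'sample' or 'gene_set'")
  chk(cfg$de$pseudocount > 0, "de.pseudocount", "must be > 0")
  chk(cfg$de$p_cut > 0 && cfg$de$p_cut <= 1, "de.p_cut", "must be in (0, 1]")
  chk(cfg$orf$max_aa >= 1L, "orf.max_aa", "must be >= 1")
  invisible(cfg)
}

# deterministic stage-seed fan-out from the global seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 7919L + stage * 104729L
}

#' NK cell activation marker gene set (27 genes)
#'
#' The functional natural-killer-cell activation marker set used by the demo
#' screen: effector molecules, activating receptors and activation-induced
#' transcription factors.
#'
#' @return Character vector of 27 gene symbols.
#' @export
nk_marker_set <- function() {
  c("EGR2", "EGR3", "IFNG", "TNF", "GZMB", "PRF1", "KLRK1", "NCR1", "NCR2",
    "NCR3", "KLRD1", "NKG7", "GNLY", "FASLG", "TNFSF10", "IL2RB", "CD69",
    "CD226", "SLAMF7", "FCGR3A", "KIR2DL4", "CD160", "CD244", "TBX21",
    "EOMES", "IL12RB2", "STAT4")
}

#' Simulate the demo screen dataset
#'
#' Builds the full synthetic study described by the `simulate` block of a
#' [screen_config()]: genome with splice-flanked genes, one planted positive
#' circle carrying the designed 253-nt / 92-aa worked-example sequence,
#' decoy circles, per-library reads, and a gene expression matrix whose NK
#' marker set is anti-correlated with the condition-centred abundance of the
#' positive circle (so the planted association is specific to that circle
#' rather than a generic tumour effect).
#'
#' @param config A `screen_config`.
#' @return List: `genome`, `genes`, `truth` ([sim_truth()]), `reads`,
#'   `expression` (from [sim_expression()]), `groups`, `pairs`,
#'   `positive_id`, `nk_set`.
#' @export
simulate_screen_data <- function(config) {
  sc <- config$simulate
  seed0 <- stage_seed(config$seed, 1L)
  set.seed(seed0)

  n_pairs <- sc$n_pairs
  samples <- c(sprintf("T%02d", seq_len(n_pairs)),
               sprintf("N%02d", seq_len(n_pairs)))
  groups <- setNames(rep(c("tumour", "normal"), each = n_pairs), samples)
  pairs <- setNames(rep(seq_len(n_pairs), 2L), samples)
  is_tum <- groups == "tumour"

  genome <- sim_genome(sc$n_chrom, sc$chrom_length, sc$gc)
  gg <- sim_genes(genome, sc$n_genes, exons_per_gene = c(3L, 5L),
                  exon_len = c(160L, 300L), intron_len = c(60L, 160L),
                  gap = c(60L, 250L))
  genome <- gg$genome
  genes <- gg$genes

  # force gene 1 to host the designed positive circle: plus strand, exons
  # 2 and 3 resized to 100 + 153 nt and overwritten with the demo sequence
  g1 <- genes$gene_id[1]
  # renumber gene 1's exons in genomic order so plus-strand transcript
  # order and genomic order agree after forcing the strand
  ex1 <- genes[genes$gene_id == g1, ]
  ex1 <- ex1[order(ex1$start), ]
  ex1$exon <- seq_len(nrow(ex1))
  ex1$strand <- "+"
  genes <- dplyr::bind_rows(genes[genes$gene_id != g1, ], ex1)
  demo <- circ_demo_sequence()
  e2 <- ex1[2, ]; e3 <- ex1[3, ]
  e2new_end <- e2$start + 100L
  e3new_end <- e3$start + 153L
  genes$end[genes$gene_id == g1 & genes$exon == 2L] <- e2new_end
  genes$end[genes$gene_id == g1 & genes$exon == 3L] <- e3new_end
  ch <- genome[[e2$chrom]]
  ch <- splice_into(ch, e2$start, substring(demo, 1L, 100L))
  ch <- splice_into(ch, e3$start, substring(demo, 101L, 253L))
  # restore template-strand splice flanks around gene 1's (plus-strand) exons
  ex1b <- genes[genes$gene_id == g1, ]
  for (i in seq_len(nrow(ex1b))) {
    ch <- splice_into(ch, ex1b$start[i] - 2L, "AG")
    ch <- splice_into(ch, ex1b$end[i], "GT")
  }
  genome[[e2$chrom]] <- ch

  circ_abund <- function(base, lfc) {
    pe <- rnorm(n_pairs, 0, sc$pair_sd)[pairs]
    setNames(2^(log2(base) + pe + lfc * is_tum +
                  rnorm(length(samples), 0, sc$resid_sd)), samples)
  }

  pos_lg_pair <- rnorm(n_pairs, 0, sc$pair_sd)[pairs]
  pos_resid <- rnorm(length(samples), 0, sc$resid_sd)
  pos_ab <- setNames(2^(log2(sc$positive_base) + pos_lg_pair +
                          sc$positive_lfc * is_tum + pos_resid), samples)
  pos_centred <- setNames(2^(log2(sc$positive_base) + pos_lg_pair +
                               pos_resid), samples)

  circs <- list(plant_circ(genes, genome, g1, 2L, 3L, pos_ab,
                           circ_id = "circPOS"))
  # decoys: single-exon blocks drawn from the remaining genes, long enough
  # that every read crosses the junction at most once
  host <- genes |>
    dplyr::filter(.data$gene_id != g1, .data$end - .data$start >= 160L)
  host <- host[sample.int(nrow(host)), ]
  n_dec <- sc$n_decoys
  if (nrow(host) < 1L) abort("No decoy host exons available.")
  up_idx <- seq_len(sc$n_decoy_up)
  for (i in seq_len(n_dec)) {
    hrow <- host[(i - 1L) %% nrow(host) + 1L, ]
    lfc <- if (i %in% up_idx) sc$decoy_lfc else 0
    base <- if (i %in% up_idx) sc$decoy_up_base else sc$decoy_base
    circs[[i + 1L]] <- plant_circ(
      genes, genome, hrow$gene_id, hrow$exon, hrow$exon,
      circ_abund(base, lfc), circ_id = sprintf("circDEC%03d", i))
  }
  circs <- dplyr::bind_rows(circs)
  circs$true_lfc <- c(sc$positive_lfc,
                      ifelse(seq_len(n_dec) %in% up_idx, sc$decoy_lfc, 0))

  linear <- tibble::tibble(
    gene_id = unique(genes$gene_id),
    seq = vapply(unique(genes$gene_id), function(g)
      splice_transcript(genes, genome, g), character(1)),
    abundance = lapply(unique(genes$gene_id), function(g)
      setNames(rep(sc$linear_base, length(samples)) *
                 2^rnorm(length(samples), 0, 0.2), samples)))

  truth <- sim_truth(circs, linear, samples, seed = config$seed)
  reads <- sim_reads(truth, read_len = sc$read_len, depth = sc$depth,
                     err = sc$err, anchor_k = config$detect$k,
                     seed = stage_seed(config$seed, 2L))

  nk <- if (nzchar(sc$gene_sets)) read_gmt(sc$gene_sets)[[1]] else
    nk_marker_set()
  # the NK correlation is planted against the log2 condition-centred
  # profile, the scale on which the pipeline measures correlations
  expression <- sim_expression(
    n_genes = sc$n_expr_genes, n_samples = length(samples),
    circ_profile = log2(pos_centred), corr_set = nk,
    target_r = sc$target_r, noise_sd = sc$corr_noise_sd,
    seed = stage_seed(config$seed, 3L))
  # align sample labels with the read simulation
  names(expression$genes) <- c("feature_id", samples)
  expression$circ <- setNames(as.numeric(pos_centred), samples)

  list(genome = genome, genes = genes, truth = truth, reads = reads,
       expression = expression, groups = groups, pairs = pairs,
       positive_id = circs$circ_id[1],
       positive_junction_id = sprintf("%s:%d-%d:%s", circs$chrom[1],
                                      circs$acceptor_pos[1],
                                      circs$donor_pos[1], circs$strand[1]),
       nk_set = nk)
}

#' Reconstruct a circle's spliced sequence from the annotation
#'
#' Given a called junction, takes the exons of the overlapping gene that lie
#' inside the junction span and splices them in transcript order (junction
#' at offset 0, acceptor side first). Falls back to the raw genomic span
#' when no annotated exon block matches the breakpoints exactly.
#'
#' @param junction One-row tibble (`chrom`, `strand`, `acceptor_pos`,
#'   `donor_pos`).
#' @param genes Gene-model tibble.
#' @param genome Named character genome vector.
#' @return Character scalar: the circular sequence, junction at offset 0.
#' @export
circ_seq_from_annotation <- function(junction, genes, genome) {
  ex <- genes[genes$chrom == junction$chrom &
                genes$strand == junction$strand &
                genes$start >= junction$acceptor_pos &
                genes$end <= junction$donor_pos, ]
  span_seq <- sub0(genome[[junction$chrom]], junction$acceptor_pos,
                   junction$donor_pos)
  if (junction$strand == "-") span_seq <- revcomp(span_seq)
  if (nrow(ex) == 0L) return(span_seq)
  ex <- ex[ex$gene_id == ex$gene_id[1], ]
  ex <- ex[order(ex$exon), ]
  if (min(ex$start) != junction$acceptor_pos ||
      max(ex$end) != junction$donor_pos) {
    return(span_seq)
  }
  pieces <- sub0(genome[[junction$chrom]], ex$start, ex$end)
  if (junction$strand == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

#' Run the full discovery screen
#'
#' Executes the stages in order: simulate (or load reads), detect
#' backsplice junctions, quantify (RPM) and test differential expression,
#' annotate rolling ORFs, run correlation-ranked GSEA for the surviving
#' candidates, and prioritize hits. All intermediates are written to
#' `out_dir` when given.
#'
#' @param config A `screen_config` (or anything [validate_config()] accepts).
#' @param out_dir Optional output directory; must not already contain a
#'   report unless `overwrite = TRUE` (re-running refuses rather than mixing
#'   runs).
#' @param overwrite Allow writing into a previously used `out_dir`.
#' @return A `screen_report`: list with `candidates` (full candidate table),
#'   `hits`, per-stage `summary`, and `provenance` (config hash, seed,
#'   package version).
#' @export
run_screen <- function(config = screen_config(), out_dir = NULL,
                       overwrite = FALSE) {
  if (!inherits(config, "screen_config")) config <- validate_config(config)
  if (!is.null(out_dir)) {
    if (file.exists(file.path(out_dir, "report.json")) && !overwrite) {
      abort(sprintf(
        "Output directory '%s' already holds a run; use overwrite = TRUE.",
        out_dir))
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  sim <- simulate_screen_data(config)
  summary <- list(simulate = list(
    n_circles_planted = nrow(sim$truth$circs),
    n_genes = length(unique(sim$genes$gene_id)),
    n_reads = nrow(sim$reads), n_samples = length(sim$truth$sample_names)))

  transcripts <- setNames(sim$truth$linear$seq,
                          paste0("tx_", sim$truth$linear$gene_id))
  det <- detect_junctions(
    sim$reads, sim$genome, transcripts = transcripts,
    k = config$detect$k, max_mismatch = config$detect$max_mismatch,
    span_cap = config$detect$span_cap, min_unique = config$detect$min_unique)
  summary$detect <- list(n_junction_reads = nrow(det$evidence),
                         n_candidates = nrow(det$candidates),
                         min_unique = config$detect$min_unique)

  if (nrow(det$candidates) == 0L) {
    report <- screen_report(config, summary, candidates = tibble::tibble(),
                            hits = tibble::tibble(), sim = sim)
    if (!is.null(out_dir)) write_screen_outputs(out_dir, sim, det, NULL,
                                                NULL, NULL, report)
    return(report)
  }

  support_counts <- dplyr::rename(det$support, feature_id = "circ_id")
  rpm <- rpm_normalize(support_counts, det$mapped_totals)
  de <- de_test(rpm, sim$groups, paired = TRUE, pairs = sim$pairs,
                pseudocount = config$de$pseudocount,
                lfc_cut = config$de$lfc_cut, p_cut = config$de$p_cut,
                adjust = config$de$adjust)
  summary$de <- c(config$de,
                  list(n_up = sum(de$table$call == "up"),
                       n_down = sum(de$table$call == "down"),
                       method = de$method))

  orf_records <- purrr::map_dfr(seq_len(nrow(det$candidates)), function(i) {
    jx <- det$candidates[i, ]
    sq <- circ_seq_from_annotation(jx, sim$genes, sim$genome)
    orfs <- circ_orfs(sq, circ_id = jx$circ_id)
    best <- best_circ_orf(orfs,
                          require_junction = config$orf$require_junction)
    if (nrow(best) == 0L) {
      tibble::tibble(circ_id = jx$circ_id, circ_length = nchar(sq),
                     start_offset = NA_integer_, nt_length = NA_integer_,
                     aa_length = NA_integer_, passes = NA_integer_,
                     spans_junction = FALSE, exceeds_360 = NA,
                     peptide = NA_character_, unique_cterm = NA_character_)
    } else {
      dplyr::mutate(best[, c("circ_id", "start_offset", "nt_length",
                             "aa_length", "passes", "spans_junction",
                             "exceeds_360", "peptide", "unique_cterm")],
                    circ_length = nchar(sq), .after = "circ_id")
    }
  })
  summary$orf <- c(config$orf,
                   list(n_junction_spanning = sum(orf_records$spans_junction),
                        n_pass_filter = sum(orf_records$spans_junction &
                                              orf_records$aa_length <
                                                config$orf$max_aa,
                                            na.rm = TRUE)))

  up_ids <- de$table$feature_id[de$table$call == "up"]
  cand_ids <- orf_records |>
    dplyr::filter(.data$circ_id %in% up_ids, .data$spans_junction,
                  .data$aa_length < config$orf$max_aa) |>
    dplyr::pull("circ_id")
  # correlations on the log2 scale: junction-read RPM profiles are long
  # tailed, and Pearson r on the raw scale is dominated by single samples
  rpm_m <- em_values(rpm)
  log_genes <- sim$expression$genes
  for (s in colnames(rpm_m)) log_genes[[s]] <- log2(log_genes[[s]] + 1)
  gsea_results <- setNames(lapply(seq_along(cand_ids), function(i) {
    prof <- log2(rpm_m[cand_ids[i], ] + config$de$pseudocount)
    if (config$gsea$mode == "sample") {
      gsea_sample_test(prof, log_genes, sim$nk_set,
                       n_perm = config$gsea$n_perm,
                       weight = config$gsea$weight,
                       seed = stage_seed(config$seed, 10L + i),
                       set_name = "NK_activation")
    } else {
      ranked <- rank_by_correlation(prof, log_genes)
      gsea_test(ranked, sim$nk_set, n_perm = config$gsea$n_perm,
                weight = config$gsea$weight,
                seed = stage_seed(config$seed, 10L + i),
                set_name = "NK_activation")
    }
  }), cand_ids)
  summary$gsea <- c(config$gsea, list(n_tested = length(cand_ids)))

  candidates <- prioritize_hits(de, orf_records, gsea_results,
                                max_aa = config$orf$max_aa,
                                p_cut = config$gsea$p_cut)
  hits <- candidates[candidates$is_hit, , drop = FALSE]
  summary$prioritize <- list(n_candidates = nrow(candidates),
                             n_hits = nrow(hits))

  report <- screen_report(config, summary, candidates, hits, sim)
  if (!is.null(out_dir)) {
    write_screen_outputs(out_dir, sim, det, rpm, de, candidates, report)
  }
  report
}

screen_report <- function(config, summary, candidates, hits, sim) {
  structure(list(
    candidates = candidates, hits = hits, summary = summary,
    positive_id = sim$positive_id,
    positive_junction_id = sim$positive_junction_id,
    provenance = list(config_hash = rlang::hash(unclass(config)),
                      seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("circscreen")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> seed %s: %d candidates, %d hit(s)\n",
              format(x$provenance$seed), nrow(x$candidates), nrow(x$hits)))
  if (nrow(x$hits) > 0L) {
    cat("hits:", paste(x$hits$circ_id, collapse = ", "), "\n")
  }
  invisible(x)
}

write_screen_outputs <- function(out_dir, sim, det, rpm, de, candidates,
                                 report) {
  write_genome_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
  write_genes_gff3(sim$genes, file.path(out_dir, "genes.gff3"))
  write_reads_fastq(sim$reads, file.path(out_dir, "reads"))
  write_junctions_bed(sim$truth$circs, file.path(out_dir,
                                                 "planted_junctions.bed"))
  jsonlite::write_json(
    list(seed = report$provenance$seed,
         circs = sim$truth$circs[, c("circ_id", "gene_id", "chrom", "strand",
                                     "acceptor_pos", "donor_pos", "length",
                                     "true_lfc")],
         nk_set = sim$nk_set),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (nrow(det$candidates) > 0L) {
    write_junctions_bed(det$candidates, file.path(out_dir, "candidates.bed"))
    readr::write_tsv(det$support, file.path(out_dir, "support.tsv"))
  }
  if (!is.null(rpm)) readr::write_tsv(rpm, file.path(out_dir, "rpm.tsv"))
  if (!is.null(de)) readr::write_tsv(de$table, file.path(out_dir, "de.tsv"))
  if (!is.null(candidates) && nrow(candidates) > 0L) {
    readr::write_tsv(candidates, file.path(out_dir, "candidate_table.tsv"))
  }
  jsonlite::write_json(
    list(summary = report$summary, provenance = report$provenance,
         hits = if (nrow(report$hits) > 0L) report$hits$circ_id else
           character()),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
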