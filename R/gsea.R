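#' Rank genes by Pearson correlation with a circRNA profile
#'
#' Computes the per-gene sample Pearson correlation with the circRNA's
#' abundance profile (the molecular phenotype) and orders genes by
#' descending correlation, ties broken lexicographically by gene id.
#' Constant genes get `r = 0` and are flagged.
#'
#' @param circ Named numeric vector of per-sample circRNA abundance
#'   (>= 4 samples, non-constant).
#' @param genes An [expr_mat()] (or tibble) of gene abundances over the same
#'   samples.
#' @return Tibble (`gene_id`, `r`, `constant`) in ranking order.
#' @export
rank_by_correlation <- function(circ, genes) {
  m <- em_values(expr_mat_passthrough(tibble::as_tibble(genes)))
  if (!is.null(names(circ))) {
    if (!all(colnames(m) %in% names(circ))) {
      abort("Sample mismatch between `circ` and `genes`.")
    }
    circ <- circ[colnames(m)]
  } else if (length(circ) != ncol(m)) {
    abort("Sample mismatch between `circ` and `genes`.")
  }
  if (length(circ) < 4L) abort("Need >= 4 samples.")
  if (sd(circ) == 0) abort("`circ` profile is constant; r undefined.")
  sds <- apply(m, 1L, sd)
  r <- rep(0, nrow(m))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.numeric(cor(circ, t(m[ok, , drop = FALSE])))
  out <- tibble::tibble(gene_id = rownames(m), r = r, constant = !ok)
  out[order(-out$r, out$gene_id), ]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum over a ranked gene list: at each set member
#' (hit) the sum increases by that gene's `|metric|^weight` normalized over
#' all hits; at each non-member it decreases by `1/(N - n)`. The enrichment
#' score is the extremum of largest absolute value; the leading edge
#' contains the members at or before (positive ES) / at or after (negative
#' ES) the extremum.
#'
#' @param ranked Ranked tibble from [rank_by_correlation()] (columns
#'   `gene_id`, `r`), or any tibble with those columns in rank order.
#' @param set Character vector of member gene ids.
#' @param weight Metric exponent (1 = classic weighted GSEA; 0 = unweighted
#'   Kolmogorov-Smirnov).
#' @return List: `es`, `running` (tibble `rank`, `gene_id`, `score`, `hit`),
#'   `leading_edge`, `degenerate` (set covers the whole list or has no
#'   overlap; `es` is `NA` in that case).
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  ids <- ranked$gene_id
  N <- length(ids)
  hit <- ids %in% set
  n <- sum(hit)
  if (n == 0L || n == N) {
    return(list(es = NA_real_, running = NULL, leading_edge = character(),
                degenerate = TRUE))
  }
  w <- abs(ranked$r)^weight
  wh <- w * hit
  denom <- sum(wh)
  inc <- if (denom > 0) wh / denom else hit / n
  dec <- (!hit) / (N - n)
  running <- cumsum(inc - dec)
  imax <- which.max(running)
  imin <- which.min(running)
  es <- if (abs(running[imax]) >= abs(running[imin])) running[imax] else
    running[imin]
  leading <- if (es >= 0) ids[seq_len(imax)][hit[seq_len(imax)]] else
    ids[seq(imin, N)][hit[seq(imin, N)]]
  list(es = es,
       running = tibble::tibble(rank = seq_len(N), gene_id = ids,
                                score = running, hit = hit),
       leading_edge = leading, degenerate = FALSE)
}

# ES from sorted hit ranks only (O(n) per permutation). `absw` are the
# |metric|^weight values in rank order. Agrees exactly with gsea_es().
es_from_hits <- function(absw, N, hits) {
  hits <- sort(hits)
  n <- length(hits)
  wh <- absw[hits]
  denom <- sum(wh)
  cumhit <- if (denom > 0) cumsum(wh) / denom else seq_len(n) / n
  miss_before <- (hits - seq_len(n)) / (N - n)
  at_hit <- cumhit - miss_before                 # value right after each hit
  before_hit <- c(0, cumhit[-n]) - miss_before   # value just before each hit
  hi <- max(at_hit)
  lo <- min(c(before_hit, cumhit[n] - (N - n) / (N - n)))
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Permutation test for gene-set enrichment
#'
#' Builds the null by drawing random gene sets of the same size from the
#' ranked list (gene-set permutation). The p value uses the add-one
#' correction `p = (1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`, so `p = 0` is
#' never reported. `NES = ES / mean(|ES_null|)` over null scores of the same
#' sign.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return A `circ_gsea` object with fields `set_name`, `es`, `nes`, `p`,
#'   `n_perm`, `direction`, `leading_edge`, `running`.
#' @param set_name Label stored in the result.
#' @export
gsea_test <- function(ranked, set, n_perm = 1000L, weight = 1, seed = NULL,
                      set_name = "set") {
  if (n_perm < 100L) abort("`n_perm` must be >= 100.")
  if (!is.null(seed)) set.seed(seed)
  obs <- gsea_es(ranked, set, weight)
  if (obs$degenerate) {
    return(structure(list(set_name = set_name, es = NA_real_, nes = NA_real_,
                          p = NA_real_, n_perm = n_perm,
                          direction = NA_character_,
                          leading_edge = character(), running = NULL,
                          degenerate = TRUE, mode = "gene_set"),
                     class = "circ_gsea"))
  }
  N <- nrow(ranked)
  n <- sum(ranked$gene_id %in% set)
  absw <- abs(ranked$r)^weight
  null_es <- vapply(seq_len(n_perm), function(i) {
    es_from_hits(absw, N, sample.int(N, n))
  }, numeric(1))
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same_sign) > 0) obs$es / mean(abs(same_sign)) else
    NA_real_
  structure(list(set_name = set_name, es = obs$es, nes = nes, p = p,
                 n_perm = n_perm,
                 direction = if (obs$es >= 0) "positive" else "negative",
                 leading_edge = obs$leading_edge, running = obs$running,
                 degenerate = FALSE, mode = "gene_set"),
            class = "circ_gsea")
}

#' Phenotype-permutation test for correlation GSEA
#'
#' Like [gsea_test()], but the null is built by permuting the circRNA
#' profile across samples and recomputing the whole correlation ranking for
#' every permutation. Unlike gene-set permutation, this null preserves the
#' gene-gene correlation structure of the expression matrix, so a gene set
#' whose members co-vary as a block (as co-regulated marker panels do) is
#' not spuriously called enriched when the block drifts by chance.
#'
#' @param profile Named per-sample circRNA abundance vector (the phenotype).
#' @param genes Expression matrix ([expr_mat()] or tibble) over the same
#'   samples.
#' @param set Character vector of member gene ids.
#' @param n_perm Number of profile permutations (>= 100).
#' @param weight Metric exponent.
#' @param seed Optional integer seed.
#' @param set_name Label stored in the result.
#' @return A `circ_gsea` object (field `mode = "sample"`).
#' @export
gsea_sample_test <- function(profile, genes, set, n_perm = 1000L,
                             weight = 1, seed = NULL, set_name = "set") {
  if (n_perm < 100L) abort("`n_perm` must be >= 100.")
  if (!is.null(seed)) set.seed(seed)
  ranked <- rank_by_correlation(profile, genes)
  obs <- gsea_es(ranked, set, weight)
  if (obs$degenerate) {
    return(structure(list(set_name = set_name, es = NA_real_, nes = NA_real_,
                          p = NA_real_, n_perm = n_perm,
                          direction = NA_character_,
                          leading_edge = character(), running = NULL,
                          degenerate = TRUE, mode = "sample"),
                     class = "circ_gsea"))
  }
  m <- em_values(expr_mat_passthrough(tibble::as_tibble(genes)))
  if (!is.null(names(profile))) profile <- profile[colnames(m)]
  ids <- rownames(m)
  N <- length(ids)
  hit_of_gene <- ids %in% set
  sds <- apply(m, 1L, sd)
  ok <- sds > 0
  tm <- t(m[ok, , drop = FALSE])
  null_es <- vapply(seq_len(n_perm), function(i) {
    pp <- sample(as.numeric(profile))
    r <- numeric(N)
    r[ok] <- as.numeric(cor(pp, tm))
    ord <- order(-r, ids)
    es_from_hits(abs(r[ord])^weight, N, which(hit_of_gene[ord]))
  }, numeric(1))
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same_sign) > 0) obs$es / mean(abs(same_sign)) else
    NA_real_
  structure(list(set_name = set_name, es = obs$es, nes = nes, p = p,
                 n_perm = n_perm,
                 direction = if (obs$es >= 0) "positive" else "negative",
                 leading_edge = obs$leading_edge, running = obs$running,
                 degenerate = FALSE, mode = "sample"),
            class = "circ_gsea")
}

#' @export
print.circ_gsea <- function(x, ...) {
  cat(sprintf("<circ_gsea> %s: ES=%.3f NES=%.3f p=%.4g (%s, %d permutations)\n",
              x$set_name, x$es, x$nes, x$p, x$direction, x$n_perm))
  invisible(x)
}

#' Prioritize screen candidates
#'
#' Combines the three stage outputs keyed by circRNA id: candidates are the
#' tumour-upregulated circles whose best ORF spans the junction and encodes
#' `< max_aa` amino acids; they are ranked by expression fold change and a
#' *hit* additionally shows negative pathway enrichment with permutation
#' `p < p_cut`.
#'
#' @param de A `circ_de` object (or its [tidy()] table) for the circRNAs.
#' @param orfs Tibble of best-ORF records per circle (`circ_id`,
#'   `aa_length`, `spans_junction`, ...).
#' @param gsea Named list of `circ_gsea` results (one per circ id), or a
#'   tibble with columns `circ_id`, `es`, `p`.
#' @param max_aa ORF length filter (strict, default 100).
#' @param p_cut Enrichment p cut for calling a hit.
#' @return Tibble of candidates ranked by fold change with `es`, `gsea_p`
#'   and `is_hit`.
#' @export
prioritize_hits <- function(de, orfs, gsea, max_aa = 100L, p_cut = 0.05) {
  if (missing(de) || is.null(de)) abort("Missing stage output: de")
  if (missing(orfs) || is.null(orfs)) abort("Missing stage output: orfs")
  if (missing(gsea) || is.null(gsea)) abort("Missing stage output: gsea")
  det <- if (inherits(de, "circ_de")) de$table else tibble::as_tibble(de)
  gt <- if (is.list(gsea) && !is.data.frame(gsea)) {
    tibble::tibble(circ_id = names(gsea),
                   es = vapply(gsea, function(g) g$es, numeric(1)),
                   gsea_p = vapply(gsea, function(g) g$p, numeric(1)))
  } else {
    g <- tibble::as_tibble(gsea)
    if ("p" %in% names(g) && !"gsea_p" %in% names(g)) {
      g <- dplyr::rename(g, gsea_p = "p")
    }
    g
  }
  up <- det[det$call == "up", c("feature_id", "log2fc", "p", "padj")]
  names(up)[1] <- "circ_id"
  cand <- dplyr::inner_join(up, tibble::as_tibble(orfs), by = "circ_id") |>
    dplyr::filter(.data$spans_junction, .data$aa_length < max_aa) |>
    dplyr::left_join(gt, by = "circ_id") |>
    dplyr::arrange(dplyr::desc(.data$log2fc)) |>
    dplyr::mutate(is_hit = !is.na(.data$es) & .data$es < 0 &
                    !is.na(.data$gsea_p) & .data$gsea_p < p_cut)
  cand
}
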