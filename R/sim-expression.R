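#' Simulate a paired tumour/normal gene expression matrix
#'
#' Generates a features-by-samples abundance matrix with three planted
#' structures recorded in the returned truth:
#'
#' * **Correlated genes** (`corr_set`): generated on the abundance scale as
#'   `a * z(circ_profile) + noise`, where `z()` standardizes the circRNA
#'   profile, `sign(a) = sign(target_r)` and `|a|` is chosen so the population
#'   Pearson correlation equals `target_r` for any `noise_sd > 0`
#'   (`a = |r| * noise_sd / sqrt(1 - r^2)`). With `noise_sd = 0` the
#'   correlation is exactly `sign(target_r)`.
#' * **Differential features** (`de_spec`): a named `feature -> log2FC` map;
#'   these genes are generated on the log2 scale with the condition effect
#'   added to tumour samples.
#' * **Paired design**: samples come in tumour/normal pairs sharing a
#'   per-pair, per-gene log-normal effect (`pair_sd` on the log2 scale).
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (>= 4, even; pair `i` is samples
#'   `T_i`/`N_i`).
#' @param circ_profile Named or positional numeric vector (length
#'   `n_samples`) of the phenotype circRNA's abundance. Must be non-constant
#'   when `corr_set` is non-empty.
#' @param corr_set Character vector of gene ids to plant as correlated
#'   (subset of the generated gene ids, or new ids appended).
#' @param target_r Target Pearson correlation in `[-1, 1]`.
#' @param noise_sd Noise SD (abundance scale, in units of the correlated
#'   genes' spread) for `corr_set` genes.
#' @param de_spec Named numeric vector `feature -> log2 fold change`.
#' @param gene_noise_sd Residual SD on the log2 scale for background/DE genes.
#' @param pair_sd SD of the shared per-pair log2 effect.
#' @param baseline_log2 Mean log2 abundance of background genes.
#' @param seed Optional integer seed.
#' @return List with `genes` (an [expr_mat()] of abundances), `circ` (the
#'   phenotype profile, named by sample), `groups` (named sample -> group
#'   map), `pairs` (named sample -> pair id), and `truth` (planted structure).
#' @export
sim_expression <- function(n_genes, n_samples, circ_profile = NULL,
                           corr_set = character(), target_r = 0,
                           noise_sd = 0.3, de_spec = NULL,
                           gene_noise_sd = 0.25, pair_sd = 1,
                           baseline_log2 = 5, seed = NULL) {
  check_scalar_number(n_samples, "n_samples", lower = 4)
  if (n_samples %% 2L != 0L) abort("`n_samples` must be even (paired design).")
  if (abs(target_r) > 1) abort("`target_r` must be in [-1, 1].")
  if (!is.null(seed)) set.seed(seed)

  n_pairs <- n_samples %/% 2L
  samples <- c(sprintf("T%02d", seq_len(n_pairs)),
               sprintf("N%02d", seq_len(n_pairs)))
  groups <- setNames(rep(c("tumour", "normal"), each = n_pairs), samples)
  pairs <- setNames(rep(seq_len(n_pairs), 2L), samples)

  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  gene_ids <- union(gene_ids, c(corr_set, names(de_spec)))

  if (length(corr_set) > 0L) {
    if (is.null(circ_profile)) {
      abort("`circ_profile` is required when `corr_set` is non-empty.")
    }
    if (length(circ_profile) != n_samples) {
      abort("`circ_profile` must have one value per sample.")
    }
    if (sd(circ_profile) == 0) {
      abort("`circ_profile` is constant; correlation is undefined.")
    }
  }

  m <- matrix(0, nrow = length(gene_ids), ncol = n_samples,
              dimnames = list(gene_ids, samples))
  is_tum <- groups == "tumour"
  lfc <- setNames(rep(0, length(gene_ids)), gene_ids)
  if (!is.null(de_spec)) lfc[names(de_spec)] <- de_spec

  for (gi in seq_along(gene_ids)) {
    pair_eff <- rnorm(n_pairs, 0, pair_sd)[pairs]
    lg <- baseline_log2 + pair_eff + lfc[gi] * is_tum +
      rnorm(n_samples, 0, gene_noise_sd)
    m[gi, ] <- 2^lg
  }

  if (length(corr_set) > 0L) {
    z <- as.numeric(scale(circ_profile))
    r <- target_r
    a <- if (noise_sd > 0 && abs(r) < 1) {
      sign(r) * abs(r) * noise_sd / sqrt(1 - r^2)
    } else {
      sign(r)
    }
    for (g in corr_set) {
      x <- a * z + noise_sd * rnorm(n_samples)
      v <- 100 + 15 * x
      if (any(v < 0)) {
        warn("Correlated gene values clipped at zero.")
        v <- pmax(v, 0)
      }
      m[g, ] <- v
    }
  }

  if (!is.null(circ_profile) && is.null(names(circ_profile))) {
    names(circ_profile) <- samples
  }
  list(
    genes = expr_mat(tibble::as_tibble(m, rownames = "feature_id"),
                     unit = "expression"),
    circ = circ_profile,
    groups = groups,
    pairs = pairs,
    truth = list(corr_set = corr_set, target_r = target_r,
                 noise_sd = noise_sd, de_spec = de_spec, seed = seed))
}
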