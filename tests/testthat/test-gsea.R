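make_ranked <- function(n = 200, seed = 1) {
  set.seed(seed)
  genes <- tibble::tibble(feature_id = sprintf("G%04d", 1:n))
  m <- matrix(rnorm(n * 12), nrow = n,
              dimnames = list(genes$feature_id, sprintf("s%02d", 1:12)))
  m <- m - min(m) + 1
  circ <- rlnorm(12)
  rank_by_correlation(circ, tibble::as_tibble(m, rownames = "feature_id"))
}

test_that("correlation ranking reproduces exact correlations and tie rules", {
  circ <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  genes <- tibble::tibble(
    feature_id = c("same", "anti", "scaled", "flat"),
    s1 = c(1, 4, 2, 5), s2 = c(2, 3, 4, 5), s3 = c(3, 2, 6, 5),
    s4 = c(4, 1, 8, 5))
  rk <- rank_by_correlation(circ, genes)
  expect_equal(rk$r[rk$gene_id == "same"], 1)
  expect_equal(rk$r[rk$gene_id == "anti"], -1)
  expect_equal(rk$r[rk$gene_id == "scaled"], 1)  # linearity
  expect_equal(rk$r[rk$gene_id == "flat"], 0)
  expect_true(rk$constant[rk$gene_id == "flat"])
  # ties broken lexicographically: r = 1 for both "same" and "scaled"
  expect_identical(rk$gene_id[1:2], c("same", "scaled"))
  expect_error(rank_by_correlation(circ[1:3], genes), "mismatch|samples")
  expect_error(rank_by_correlation(rep(1, 4), genes), "constant")
})

test_that("enrichment scores match the direct running-sum oracle", {
  ranked <- make_ranked(150, seed = 2)
  set.seed(3)
  for (w in c(0, 1)) {
    for (i in 1:25) {
      set <- sample(ranked$gene_id, sample(5:40, 1))
      got <- gsea_es(ranked, set, weight = w)
      want <- oracle_es(ranked$r, ranked$gene_id %in% set, w)
      expect_equal(got$es, want, tolerance = 1e-10)
      # internal fast path used by the permutation null agrees too
      fast <- circscreen:::es_from_hits(abs(ranked$r)^w, nrow(ranked),
                                        which(ranked$gene_id %in% set))
      expect_equal(fast, want, tolerance = 1e-10)
    }
  }
})

test_that("extreme placements give the expected score signs and values", {
  ranked <- make_ranked(100, seed = 4)
  top <- ranked$gene_id[1:10]
  got <- gsea_es(ranked, top, weight = 0)
  expect_equal(got$es, 1)               # all hits before any miss
  expect_setequal(got$leading_edge, top)
  bottom <- ranked$gene_id[91:100]
  expect_lt(gsea_es(ranked, bottom, weight = 1)$es, 0)
  everything <- gsea_es(ranked, ranked$gene_id)
  expect_true(everything$degenerate)
  nothing <- gsea_es(ranked, c("absent1", "absent2"))
  expect_true(nothing$degenerate)
})

test_that("weighted scores agree with the fgsea reference implementation", {
  ranked <- make_ranked(300, seed = 5)
  stats <- setNames(ranked$r, ranked$gene_id)
  set.seed(6)
  for (i in 1:10) {
    idx <- sort(sample.int(300, 25))
    ours <- gsea_es(ranked, ranked$gene_id[idx], weight = 1)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("reversing the ranked list negates the unweighted score", {
  ranked <- make_ranked(120, seed = 7)
  rev_ranked <- ranked[rev(seq_len(nrow(ranked))), ]
  set.seed(8)
  for (i in 1:10) {
    set <- sample(ranked$gene_id, 15)
    ga <- gsea_es(ranked, set, weight = 0)
    b <- gsea_es(rev_ranked, set, weight = 0)$es
    run <- ga$running$score
    # when the positive and negative excursions tie exactly, the sign of
    # the reported extremum is a convention; the magnitude must still match
    tie <- abs(abs(max(run)) - abs(min(run))) < 1e-12
    if (tie) {
      expect_equal(abs(ga$es), abs(b), tolerance = 1e-10)
    } else {
      expect_equal(ga$es, -b, tolerance = 1e-10)
    }
  }
})

test_that("permutation p values are reproducible and never zero", {
  ranked <- make_ranked(200, seed = 9)
  set <- ranked$gene_id[1:15]
  r1 <- gsea_test(ranked, set, n_perm = 200, seed = 42)
  r2 <- gsea_test(ranked, set, n_perm = 200, seed = 42)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
  expect_error(gsea_test(ranked, set, n_perm = 50), "n_perm")
  gl <- glance(r1)
  expect_identical(gl$direction, "positive")
  td <- tidy(r1)
  expect_true(all(td$gene_id %in% set))
})

test_that("a planted anti-correlated set is detected with a negative score", {
  hits <- 0
  for (rep_i in 1:10) {
    sim <- sim_expression(400, 12, circ_profile = rlnorm(12, 4, 1),
                          corr_set = sprintf("GENE%04d", 1:27),
                          target_r = -0.6, noise_sd = 0.3,
                          seed = 100 + rep_i)
    ranked <- rank_by_correlation(sim$circ, sim$genes)
    res <- gsea_test(ranked, sprintf("GENE%04d", 1:27), n_perm = 200,
                     seed = rep_i)
    if (res$es < 0 && res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("prioritization intersects the stage outputs and flags hits", {
  de <- structure(list(table = tibble::tibble(
    feature_id = c("c1", "c2", "c3", "c4"),
    log2fc = c(2.5, 1.5, 3.0, -2), p = c(1e-4, 1e-3, 1e-5, 1e-4),
    padj = c(1e-3, 1e-2, 1e-4, 1e-3),
    call = c("up", "up", "up", "down"))), class = "circ_de")
  orfs <- tibble::tibble(circ_id = c("c1", "c2", "c3", "c4"),
                         aa_length = c(92L, 150L, 40L, 30L),
                         spans_junction = c(TRUE, TRUE, TRUE, TRUE))
  gsea <- tibble::tibble(circ_id = c("c1", "c3"),
                         es = c(-0.8, 0.5), gsea_p = c(0.002, 0.01))
  out <- prioritize_hits(de, orfs, gsea, p_cut = 0.01)
  # c2 fails the length filter, c4 is downregulated
  expect_setequal(out$circ_id, c("c1", "c3"))
  expect_identical(out$circ_id[1], "c3")       # ranked by fold change
  expect_identical(out$circ_id[out$is_hit], "c1")
  expect_error(prioritize_hits(NULL, orfs, gsea), "de")
})
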