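test_that("RPM and FPKM follow their definitions", {
  cm <- tibble::tibble(feature_id = c("j1", "j2", "j3"),
                       s1 = c(5, 0, 7))
  rpm <- rpm_normalize(cm, c(s1 = 1e6))
  expect_equal(rpm$s1, c(5, 0, 7))
  rpm2 <- rpm_normalize(cm, c(s1 = 3.5e6))
  expect_equal(rpm2$s1[3], 2)           # 7 / 3.5e6 * 1e6
  expect_identical(em_unit(rpm), "RPM")
  expect_error(rpm_normalize(cm, c(s1 = 0)), "s1")
  expect_error(rpm_normalize(cm, c(other = 1)), "s1")

  gm <- tibble::tibble(feature_id = c("g1", "g2"), s1 = c(100, 250))
  fp <- fpkm_normalize(gm, c(g1 = 1000, g2 = 2500),
                       c(s1 = 1e6))
  expect_equal(fp$s1[1], 100)
  fp2 <- fpkm_normalize(gm, c(g1 = 2000, g2 = 2500), c(s1 = 1e6))
  expect_equal(fp2$s1[1], 50)           # doubling length halves FPKM
  fp3 <- fpkm_normalize(gm, c(g1 = 1000, g2 = 2500), c(s1 = 5e6))
  expect_equal(fp3$s1[2], 20)           # 250 / 2.5kb / 5M reads
  expect_error(fpkm_normalize(gm, c(g1 = 0, g2 = 1), c(s1 = 1)), "> 0")
})

test_that("normalization is invariant to a common depth rescaling", {
  set.seed(21)
  cm <- tibble::tibble(feature_id = sprintf("f%d", 1:20),
                       a = rpois(20, 50), b = rpois(20, 80))
  totals <- c(a = 2e6, b = 3e6)
  r1 <- rpm_normalize(cm, totals)
  r2 <- rpm_normalize(dplyr::mutate(cm, a = a * 7, b = b * 7), totals * 7)
  expect_equal(em_values(r1), em_values(r2))
  lens <- setNames(rep(1500, 20), cm$feature_id)
  f1 <- fpkm_normalize(cm, lens, totals)
  f2 <- fpkm_normalize(dplyr::mutate(cm, a = a * 3, b = b * 3), lens,
                       totals * 3)
  expect_equal(em_values(f1), em_values(f2))
})

make_de_matrix <- function(n_feat, n_pairs, lfc = 0, noise_sd = 0.25,
                           pair_sd = 1, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("T%02d", 1:n_pairs), sprintf("N%02d", 1:n_pairs))
  groups <- setNames(rep(c("tumour", "normal"), each = n_pairs), samples)
  pairs <- setNames(rep(1:n_pairs, 2), samples)
  m <- t(vapply(seq_len(n_feat), function(i) {
    pe <- rnorm(n_pairs, 0, pair_sd)[pairs]
    2^(6 + pe + lfc * (groups == "tumour") + rnorm(2 * n_pairs, 0, noise_sd))
  }, numeric(2 * n_pairs)))
  colnames(m) <- samples
  tbl <- tibble::as_tibble(m)
  tbl <- dplyr::bind_cols(tibble::tibble(feature_id =
                                           sprintf("f%04d", 1:n_feat)), tbl)
  list(mat = tbl, groups = groups, pairs = pairs)
}

test_that("differential calls follow the thresholds exactly", {
  d <- make_de_matrix(30, 6, lfc = 0, noise_sd = 1e-6, pair_sd = 0, seed = 2)
  same <- de_test(d$mat, d$groups, pairs = d$pairs)
  expect_true(all(abs(same$table$log2fc) < 1e-4))
  expect_true(all(same$table$call == "ns"))
  expect_true(all(same$table$padj >= same$table$p))

  up <- make_de_matrix(20, 6, lfc = 2, noise_sd = 0.05, seed = 3)
  res <- de_test(up$mat, up$groups, pairs = up$pairs)
  expect_true(all(res$table$call == "up"))
  expect_equal(mean(res$table$log2fc), 2, tolerance = 0.15)

  # strong significance but sub-threshold fold change stays ns
  sub <- make_de_matrix(20, 6, lfc = 0.8, noise_sd = 0.02, seed = 4)
  res2 <- de_test(sub$mat, sub$groups, pairs = sub$pairs)
  expect_true(all(res2$table$p < 0.01))
  expect_true(all(res2$table$call == "ns"))

  # down direction is symmetric
  dn <- make_de_matrix(10, 6, lfc = -2, noise_sd = 0.05, seed = 5)
  expect_true(all(de_test(dn$mat, dn$groups,
                          pairs = dn$pairs)$table$call == "down"))
})

test_that("degenerate variance yields p = 1 with a warning, not a crash", {
  tbl <- tibble::tibble(feature_id = "f1", T01 = 4, T02 = 4, N01 = 4,
                        N02 = 4)
  groups <- setNames(c("tumour", "tumour", "normal", "normal"),
                     names(tbl)[-1])
  pairs <- setNames(c(1, 2, 1, 2), names(tbl)[-1])
  expect_warning(res <- de_test(tbl, groups, pairs = pairs), "Degenerate")
  expect_equal(res$table$p, 1)
  expect_equal(res$table$log2fc, 0)
})

test_that("unpaired mode and the FDR switch behave", {
  d <- make_de_matrix(50, 6, lfc = 2, noise_sd = 0.2, pair_sd = 0, seed = 6)
  welch <- de_test(d$mat, d$groups, paired = FALSE)
  expect_match(welch$method, "Welch")
  expect_gt(mean(welch$table$call == "up"), 0.9)
  fdr <- de_test(d$mat, d$groups, pairs = d$pairs, adjust = TRUE)
  expect_true(all(fdr$table$padj >= fdr$table$p))
  expect_error(de_test(d$mat, d$groups, paired = TRUE), "pairs")

  td <- tidy(welch)
  expect_identical(names(td), c("feature_id", "log2fc", "p", "padj", "call"))
  gl <- glance(welch)
  expect_identical(gl$n_features, 50L)
})
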