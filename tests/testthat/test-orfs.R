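test_that("rolling translation handles the canonical small circles", {
  # stop reached before the junction: a plain 2-aa ORF, no crossing
  o <- circ_orfs("ATGAAATAG")
  expect_identical(o$peptide[o$start_offset == 0], "MK")
  expect_identical(o$aa_length[o$start_offset == 0], 2L)
  expect_identical(o$passes[o$start_offset == 0], 0L)
  expect_false(o$spans_junction[o$start_offset == 0])

  # L = 11, no in-frame stop within three passes -> infinite, capped at 3L
  o2 <- circ_orfs("ATGGAAGAAGA")
  row <- o2[o2$start_offset == 0, ]
  expect_false(row$has_stop)
  expect_true(row$truncated)
  expect_identical(row$nt_length, 33L)
  expect_identical(row$aa_length, 11L)
  want <- oracle_rolling_orfs("ATGGAAGAAGA")
  w0 <- want[want$start_offset == 0, ]
  expect_identical(row$peptide, w0$peptide)
  expect_identical(row$nt_length, as.integer(w0$nt_length))

  # L %% 3 == 0 and no stop: frame never shifts, unique C-terminus empty
  o3 <- circ_orfs("ATGGGCGGCGGC")
  r3 <- o3[o3$start_offset == 0, ]
  expect_false(r3$has_stop)
  expect_identical(r3$unique_cterm, "")

  expect_error(circ_orfs("ATG"), ">= 6")
})

test_that("rolling ORFs match brute-force translation of the repeated sequence", {
  set.seed(13)
  n_cases <- 0
  for (i in 1:250) {
    L <- sample(30:600, 1)
    s <- random_circle(L)
    got <- circ_orfs(s)
    want <- oracle_rolling_orfs(s)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want) == 0) next
    got <- got[order(got$start_offset), ]
    want <- want[order(want$start_offset), ]
    expect_identical(got$start_offset, as.integer(want$start_offset))
    expect_identical(got$nt_length, as.integer(want$nt_length))
    expect_identical(got$peptide, want$peptide)
    expect_identical(got$has_stop, want$has_stop)
    expect_identical(got$passes, want$passes)
    n_cases <- n_cases + nrow(want)
  }
  expect_gt(n_cases, 500)
})

test_that("rotation shifts start offsets and nothing else", {
  set.seed(14)
  for (i in 1:20) {
    L <- sample(40:200, 1)
    s <- random_circle(L)
    r <- sample(L - 1, 1)
    rot <- paste0(substr(s, r + 1, L), substr(s, 1, r))
    a <- circ_orfs(s)
    b <- circ_orfs(rot)
    expect_identical(nrow(a), nrow(b))
    if (nrow(a) == 0) next
    a$mapped <- (a$start_offset - r) %% L
    a <- a[order(a$mapped), ]
    b <- b[order(b$start_offset), ]
    expect_identical(b$start_offset, as.integer(a$mapped))
    expect_identical(b$peptide, a$peptide)
    expect_identical(b$nt_length, a$nt_length)
    expect_identical(b$has_stop, a$has_stop)
  }
})

test_that("three passes visit every position-frame combination once", {
  set.seed(15)
  for (L in c(31L, 44L, 100L, 253L)) {
    expect_true(L %% 3 != 0)
    starts <- (3L * (seq_len(L) - 1L)) %% L
    expect_identical(sort(starts), 0:(L - 1))
  }
})

test_that("the frameshift C-terminus follows the re-entry definition", {
  # single-pass ORF: empty with a reason
  o <- circ_orfs("ATGAAATAG")
  uc <- orf_unique_cterm(o[1, ], "ATGAAATAG")
  expect_identical(as.character(uc), "")
  expect_match(attr(uc, "reason"), "single-pass")

  # the designed worked-example circle: 253 nt, 92-aa ORF crossing the
  # junction; the re-entrant suffix equals the brute-force oracle
  d <- circ_demo_sequence()
  expect_identical(nchar(d), 253L)
  orfs <- circ_orfs(d)
  best <- best_circ_orf(orfs)
  expect_identical(best$aa_length, 92L)
  expect_true(best$spans_junction)
  expect_true(best$exceeds_360)
  want <- oracle_unique_cterm(d, best$start_offset, best$aa_length)
  expect_identical(best$unique_cterm, want)
  expect_identical(nchar(want), 92L - as.integer(ceiling(253 / 3)))
  expect_identical(as.character(orf_unique_cterm(best, d)),
                   best$unique_cterm)
})

test_that("the screen filter uses a strict 100-aa boundary", {
  rec <- tibble::tibble(circ_id = sprintf("c%d", 1:4),
                        aa_length = c(100L, 99L, 12L, 150L),
                        spans_junction = c(TRUE, TRUE, FALSE, TRUE))
  kept <- filter_circorfs(rec)
  expect_identical(kept$circ_id, "c2")
  expect_identical(attr(kept, "n_in"), 4L)
  expect_equal(attr(kept, "retained_fraction"), 0.25)
  pure_len <- filter_circorfs(rec, require_junction = FALSE)
  expect_setequal(pure_len$circ_id, c("c2", "c3"))
})

test_that("best ORF selection prefers length then smallest start", {
  orfs <- tibble::tibble(start_offset = c(10L, 4L, 30L),
                         aa_length = c(50L, 50L, 20L),
                         spans_junction = c(TRUE, TRUE, TRUE))
  expect_identical(best_circ_orf(orfs)$start_offset, 4L)
  none <- dplyr::mutate(orfs, spans_junction = FALSE)
  expect_identical(nrow(best_circ_orf(none)), 0L)
  expect_identical(nrow(best_circ_orf(none, require_junction = FALSE)), 1L)
})

test_that("linear mORF calling matches the three-frame oracle", {
  expect_identical(linear_morfs("ATGTAA")$aa_length, 1L)
  expect_identical(nrow(linear_morfs("CCCCCCCCCCC")), 0L)
  set.seed(16)
  for (i in 1:10) {
    s <- random_circle(3000)
    got <- linear_morfs(s)
    want <- oracle_morfs(s)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$start_offset, as.integer(want$start_offset))
    expect_identical(got$aa_length, as.integer(want$aa_length))
  }
})
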