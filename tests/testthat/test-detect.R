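test_that("k-mer index agrees with a brute-force scan on both strands", {
  set.seed(7)
  refs <- c(chrA = random_circle(600), chrB = random_circle(400))
  # plant a k-mer and its reverse complement at known spots
  q <- "ACGTACGTGGATCCAAGCTT"
  refs["chrA"] <- paste0(substr(refs["chrA"], 1, 100), q,
                         substr(refs["chrA"], 121, 600))
  refs["chrB"] <- paste0(substr(refs["chrB"], 1, 50), revcomp(q),
                         substr(refs["chrB"], 71, 400))
  idx <- build_kmer_index(refs, k = 20)
  queries <- c(q, substr(refs["chrB"], 201, 220), strrep("A", 20))
  for (qq in queries) {
    got <- kmer_lookup(idx, qq)
    want <- oracle_kmer_scan(refs, qq)
    got <- got[order(got$chrom, got$pos, got$strand), ]
    want <- want[order(want$chrom, want$pos, want$strand), ]
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$chrom, want$chrom)
      expect_equal(got$pos, want$pos)
      expect_equal(got$strand, want$strand)
    }
  }
  expect_identical(nrow(kmer_lookup(idx, strrep("N", 20))), 0L)
  expect_error(build_kmer_index(c(a = "ACGT"), k = 20), "exceeds")
})

test_that("linear partition separates reference reads from junction reads", {
  st <- make_tiny_study(n_genes = 6, n_circ = 2, depth = 0, seed = 51)
  refs <- c(st$genome, st$transcripts)
  tx <- st$transcripts[[1]]

  exact <- substr(tx, 101, 250)
  circ <- st$circs[1, ]
  unrolled <- strrep(circ$seq, 2)
  jump <- substr(unrolled, circ$length - 70 + 1, circ$length - 70 + 150)

  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  reads <- tibble::tibble(
    sample = "s1",
    read_id = c("verbatim", "two_subs", "three_subs", "junction", "rc"),
    seq = c(exact, mutate_at(exact, c(30, 90)),
            mutate_at(exact, c(30, 90, 140)), jump, revcomp(exact)))
  part <- partition_linear(reads, refs)
  expect_setequal(part$mapped$read_id, c("verbatim", "two_subs", "rc"))
  expect_setequal(part$unmapped$read_id, c("three_subs", "junction"))
  expect_identical(unname(part$mapped_totals["s1"]), 3)

  empty <- partition_linear(reads[0, ], refs)
  expect_identical(nrow(empty$mapped), 0L)
  expect_identical(nrow(empty$unmapped), 0L)
})

test_that("anchors partition the read and head-to-tail geometry is enforced", {
  a <- extract_anchors(strrep("ACGT", 10), k = 20)
  expect_identical(paste0(a$left, a$right), strrep("ACGT", 10))
  expect_error(extract_anchors("ACGTACGT", k = 20), "shorter")

  colinear <- list(seq = strrep("A", 40), chrom = "chr1", pL = 100, pR = 500)
  expect_null(detect_headtotail(colinear))
  reversed <- list(seq = strrep("A", 40), chrom = "chr1", pL = 1500, pR = 500)
  expect_identical(detect_headtotail(reversed), reversed)
  far <- list(seq = strrep("A", 40), chrom = "chr1", pL = 1.2e6, pR = 100)
  expect_null(detect_headtotail(far, span_cap = 1e5))
  expect_identical(detect_headtotail(far, span_cap = 2e6), far)
  expect_null(detect_headtotail(NULL))
})

test_that("breakpoint extension recovers planted junctions exactly", {
  st <- make_tiny_study(n_genes = 6, n_circ = 3, depth = 4000, seed = 61)
  det <- detect_junctions(st$reads, st$genome, transcripts = st$transcripts)

  expect_setequal(det$candidates$circ_id, st$circs$circ_id)
  got <- det$candidates[match(st$circs$circ_id, det$candidates$circ_id), ]
  expect_equal(got$acceptor_pos, st$circs$acceptor_pos)
  expect_equal(got$donor_pos, st$circs$donor_pos)
  expect_equal(got$strand, st$circs$strand)

  # no linear leakage: every junction read originated from a circle
  expect_true(all(grepl("\\|circ:", det$evidence$read_id)))

  # mutating the donor flank away from GT kills the junction
  circ <- st$circs[1, ]
  chrom <- st$genome[[circ$chrom]]
  unrolled <- strrep(circ$seq, 2)
  jump <- substr(unrolled, circ$length - 70 + 1, circ$length - 70 + 150)
  idx <- build_kmer_index(st$genome, 20)
  pair <- circscreen:::place_anchor_pair(jump, idx, 20)
  prov <- detect_headtotail(pair)
  expect_false(is.null(prov))
  bp <- extend_to_breakpoint(prov, st$genome)
  expect_equal(bp$acceptor_pos, circ$acceptor_pos)
  expect_equal(bp$donor_pos, circ$donor_pos)

  broken <- st$genome
  flank_at <- if (circ$strand == "+") circ$donor_pos else circ$acceptor_pos - 2
  broken[[circ$chrom]] <- paste0(substr(chrom, 1, flank_at), "CC",
                                 substr(chrom, flank_at + 3, nchar(chrom)))
  expect_null(extend_to_breakpoint(prov, broken))
})

test_that("flank signature disambiguates alignment-equivalent breakpoints", {
  # engineered locus: the base after the donor equals the first circle base,
  # so the alignment alone admits two breakpoints; only the true one is
  # GT/AG flanked
  set.seed(71)
  left <- random_circle(300)
  circ <- paste0("G", random_circle(79))       # first circle base 'G'
  right <- random_circle(300)
  genome <- c(chrZ = paste0(left, "AG", circ, "GT", random_circle(200)))
  acc <- 302L
  don <- acc + 80L
  unrolled <- strrep(circ, 2)
  jump <- substr(unrolled, 80 - 30 + 1, 80 - 30 + 60)  # 30 nt each side
  idx <- build_kmer_index(genome, 20)
  pair <- circscreen:::place_anchor_pair(jump, idx, 20)
  expect_false(is.null(pair))
  bp <- extend_to_breakpoint(detect_headtotail(pair), genome, k = 20)
  expect_equal(bp$acceptor_pos, acc)
  expect_equal(bp$donor_pos, don)
  expect_equal(bp$strand, "+")
})

test_that("candidate calling applies the unique-read and per-sample rules", {
  base <- tibble::tibble(chrom = "chr1", strand = "+", acceptor_pos = 100L,
                         donor_pos = 400L, tie = FALSE)
  two_distinct <- dplyr::bind_rows(base, base) |>
    dplyr::mutate(sample = "s1", read_id = c("r1", "r2"),
                  seq = c("AAAA", "CCCC"))
  called <- call_candidates(two_distinct, min_unique = 2)
  expect_identical(nrow(called$candidates), 1L)
  expect_identical(called$candidates$best_sample_support, 2L)

  five_copies <- dplyr::bind_rows(rep(list(base), 5)) |>
    dplyr::mutate(sample = "s1", read_id = sprintf("r%d", 1:5),
                  seq = "AAAA")
  expect_identical(nrow(call_candidates(five_copies)$candidates), 0L)

  spread <- dplyr::bind_rows(rep(list(base), 3)) |>
    dplyr::mutate(sample = c("s1", "s2", "s3"),
                  read_id = sprintf("r%d", 1:3),
                  seq = c("AAAA", "CCCC", "GGGG"))
  expect_identical(nrow(call_candidates(spread)$candidates), 0L)

  catalogue <- tibble::tibble(chrom = "chr1", acceptor_pos = 100L,
                              donor_pos = 400L, strand = "+")
  expect_true(call_candidates(two_distinct,
                              catalogue = catalogue)$candidates$known)
  expect_false(call_candidates(
    two_distinct,
    catalogue = dplyr::mutate(catalogue, acceptor_pos = 101L)
  )$candidates$known)
})

test_that("detection is strand symmetric under genome reversal", {
  st <- make_tiny_study(n_genes = 5, n_circ = 3, depth = 3000, seed = 81)
  det <- detect_junctions(st$reads, st$genome, transcripts = st$transcripts)

  M <- nchar(st$genome[[1]])
  flipped_genome <- setNames(revcomp(st$genome), names(st$genome))
  flipped_reads <- dplyr::mutate(st$reads, seq = revcomp(seq))
  flipped_tx <- setNames(revcomp(st$transcripts), names(st$transcripts))
  det2 <- detect_junctions(flipped_reads, flipped_genome,
                           transcripts = flipped_tx)

  expected <- det$candidates |>
    dplyr::mutate(acc2 = M - donor_pos, don2 = M - acceptor_pos,
                  strand2 = ifelse(strand == "+", "-", "+"))
  expect_setequal(
    sprintf("%s:%d-%d:%s", expected$chrom, expected$acc2, expected$don2,
            expected$strand2),
    det2$candidates$circ_id)
})
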