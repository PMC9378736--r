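# Independent brute-force oracles used to freeze expected values.
# These deliberately use naive per-position loops, not the package's
# arithmetic, so they cannot share bugs with the implementation.

# naive codon-by-codon rolling translation on the 4x-repeated sequence,
# starts restricted to the first copy
oracle_rolling_orfs <- function(seq) {
  L <- nchar(seq)
  rep4 <- strrep(seq, 4L)
  code <- Biostrings::GENETIC_CODE
  starts <- integer()
  for (s in 0:(L - 1L)) {
    if (substr(rep4, s + 1L, s + 3L) == "ATG") starts <- c(starts, s)
  }
  rows <- lapply(starts, function(s) {
    pep <- character()
    pos <- s
    has_stop <- FALSE
    while (pos + 3L <= s + 3L * L) {
      codon <- substr(rep4, pos + 1L, pos + 3L)
      aa <- unname(code[codon])
      pos <- pos + 3L
      if (aa == "*") {
        has_stop <- TRUE
        break
      }
      pep <- c(pep, aa)
    }
    nt_len <- if (has_stop) pos - 3L - s else pos - s
    lastpos <- pos - 1L
    passes <- sum(seq(L, 4L * L, by = L) <= lastpos)
    list(start_offset = s, nt_length = nt_len,
         aa_length = length(pep), has_stop = has_stop,
         passes = as.integer(passes),
         peptide = paste(pep, collapse = ""))
  })
  if (length(rows) == 0L) {
    return(data.frame(start_offset = integer(), nt_length = integer(),
                      aa_length = integer(), has_stop = logical(),
                      passes = integer(), peptide = character()))
  }
  do.call(rbind.data.frame, rows)
}

# residues translated from re-entrant codons (start >= one circumference
# past the ORF start), computed directly from the sequence
oracle_unique_cterm <- function(seq, start_offset, aa_length) {
  L <- nchar(seq)
  rep4 <- strrep(seq, 4L)
  code <- Biostrings::GENETIC_CODE
  out <- character()
  for (i in seq_len(aa_length) - 1L) {
    u <- start_offset + 3L * i
    if (u - start_offset >= L) {
      out <- c(out, unname(code[substr(rep4, u + 1L, u + 3L)]))
    }
  }
  paste(out, collapse = "")
}

# brute-force scan for all placements of a k-mer (both strands)
oracle_kmer_scan <- function(refs, q) {
  k <- nchar(q)
  rcq <- circscreen::revcomp(q)
  out <- list()
  for (nm in names(refs)) {
    s <- refs[[nm]]
    for (p in 0:(nchar(s) - k)) {
      w <- substr(s, p + 1L, p + k)
      if (w == q) out[[length(out) + 1L]] <-
          data.frame(chrom = nm, pos = p, strand = "+")
      if (w == rcq) out[[length(out) + 1L]] <-
          data.frame(chrom = nm, pos = p, strand = "-")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  }
  do.call(rbind, out)
}

# naive three-frame ATG->stop scan, longest ORF per stop
oracle_morfs <- function(seq) {
  n <- nchar(seq)
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (f in 0:2) {
    open_start <- NA_integer_
    pos <- f
    while (pos + 3L <= n) {
      codon <- substr(seq, pos + 1L, pos + 3L)
      if (is.na(open_start) && codon == "ATG") open_start <- pos
      if (!is.na(open_start) && unname(code[codon]) == "*" &&
            pos > open_start) {
        out[[length(out) + 1L]] <- data.frame(
          start_offset = open_start, nt_length = pos - open_start,
          aa_length = (pos - open_start) %/% 3L)
        open_start <- NA_integer_
      }
      pos <- pos + 3L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start_offset = integer(), nt_length = integer(),
                      aa_length = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start_offset), , drop = FALSE]
}

# direct running-sum ES computed with an explicit per-rank loop
oracle_es <- function(r, hit, weight) {
  N <- length(r)
  n <- sum(hit)
  wh <- abs(r)^weight * hit
  denom <- sum(wh)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + (if (denom > 0) wh[i] / denom else 1 / n)
    } else {
      cur - 1 / (N - n)
    }
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# random circle generator for property tests
random_circle <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# small simulated study shared by detection tests: genome, flanked genes,
# planted single-exon circles, error-free reads
make_tiny_study <- function(n_genes = 8, n_circ = 4, depth = 2500,
                            samples = c("s1", "s2"), circ_ab = 30,
                            linear_ab = 10, err = 0, seed = 42,
                            read_len = 150) {
  genome <- sim_genome(1, 40000, 0.5, seed = seed)
  gg <- sim_genes(genome, n_genes, exons_per_gene = c(2, 4),
                  exon_len = c(160, 300), seed = seed + 1)
  genes <- gg$genes
  genome <- gg$genome
  circs <- dplyr::bind_rows(lapply(seq_len(n_circ), function(i) {
    gid <- sprintf("gene%04d", i)
    plant_circ(genes, genome, gid, 1, 1,
               setNames(rep(circ_ab, length(samples)), samples))
  }))
  ids <- unique(genes$gene_id)
  linear <- tibble::tibble(
    gene_id = ids,
    seq = vapply(ids, function(g) splice_transcript(genes, genome, g),
                 character(1)),
    abundance = lapply(ids, function(g)
      setNames(rep(linear_ab, length(samples)), samples)))
  truth <- sim_truth(circs, linear, samples, seed = seed)
  reads <- sim_reads(truth, read_len = read_len, depth = depth, err = err,
                     seed = seed + 2)
  list(genome = genome, genes = genes, circs = circs, linear = linear,
       truth = truth, reads = reads,
       transcripts = setNames(linear$seq, paste0("tx_", ids)))
}
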