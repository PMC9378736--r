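#' Simulate a toy reference genome
#'
#' Draws independent bases at a target GC fraction for each chromosome.
#' The genome is returned as a named character vector (chromosome name to
#' sequence); all package functions accept this representation.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in nt (>= 10000).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Optional integer seed; fixing it makes the genome reproducible.
#' @return Named character vector of chromosome sequences.
#' @examples
#' g <- sim_genome(1, 10000, gc = 0.5, seed = 7)
#' nchar(g)
#' @export
sim_genome <- function(n_chrom = 1L, chrom_length = 1e5, gc = 0.5,
                       seed = NULL) {
  check_scalar_number(n_chrom, "n_chrom", lower = 1)
  check_scalar_number(chrom_length, "chrom_length", lower = 10000)
  if (!is.numeric(gc) || length(gc) != 1L || gc <= 0 || gc >= 1) {
    abort("`gc` must be strictly between 0 and 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(seq_len(n_chrom), function(i) random_dna(chrom_length, gc),
              character(1))
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

#' Simulate multi-exon gene models with canonical splice flanks
#'
#' Places non-overlapping genes on the genome and rewrites the bases flanking
#' every exon boundary so that, on the template strand, each intron reads
#' GT...AG (the DNA image of the GU/AG rule used by the backsplice detector).
#' Because flanks are written around *every* exon (including terminal ones),
#' any contiguous exon block chosen for circularization is guaranteed to carry
#' a GT donor and an AG acceptor at its backsplice junction.
#'
#' Coordinates are 0-based half-open. For minus-strand genes the plus strand
#' of the genome shows the complement signature (AC before the exon's genomic
#' start, CT after its genomic end), exactly what the detector expects for
#' minus-strand junctions.
#'
#' @param genome Named character vector from [sim_genome()].
#' @param n_genes Number of genes to place.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_len Range of exon lengths (nt).
#' @param intron_len Range of intron lengths (nt, >= 10 so flank rewrites
#'   of adjacent exons never collide).
#' @param gap Range of intergenic gap lengths (nt, >= 10).
#' @param seed Optional integer seed.
#' @return A list with elements `genome` (the flank-rewritten genome) and
#'   `genes`, a tibble with one row per exon: `gene_id`, `chrom`, `strand`,
#'   `exon` (1-based index in transcript order), `start`, `end`.
#' @export
sim_genes <- function(genome, n_genes, exons_per_gene = c(2L, 6L),
                      exon_len = c(120L, 300L), intron_len = c(60L, 200L),
                      gap = c(50L, 400L), seed = NULL) {
  stopifnot(is.character(genome), length(genome) >= 1, !is.null(names(genome)))
  check_scalar_number(n_genes, "n_genes", lower = 0)
  if (min(intron_len) < 10 || min(gap) < 10) {
    abort("`intron_len` and `gap` minima must be >= 10 nt.")
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_genes == 0L) {
    return(list(genome = genome, genes = tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      exon = integer(), start = integer(), end = integer())))
  }

  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1L)

  rows <- list()
  cursor <- setNames(rep(10L, length(genome)), names(genome))
  ci <- 1L
  for (gi in seq_len(n_genes)) {
    n_ex <- rint(exons_per_gene)
    ex_l <- vapply(seq_len(n_ex), function(i) rint(exon_len), integer(1))
    in_l <- if (n_ex > 1)
      vapply(seq_len(n_ex - 1L), function(i) rint(intron_len), integer(1))
    else integer(0)
    span <- sum(ex_l) + sum(in_l)
    placed <- FALSE
    for (try in seq_along(genome)) {
      chrom <- names(genome)[ci]
      start <- cursor[chrom] + rint(gap)
      if (start + span + 10L <= nchar(genome[chrom])) {
        placed <- TRUE
        break
      }
      ci <- ci %% length(genome) + 1L
    }
    if (!placed) {
      abort(sprintf(
        "Insufficient genome space: placed %d of %d genes.", gi - 1L, n_genes))
    }
    strand <- sample(c("+", "-"), 1L)
    starts <- start + c(0L, cumsum(ex_l[-n_ex] + in_l))
    ends <- starts + ex_l
    # transcript order: genomic for "+", reverse genomic for "-"
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    rows[[gi]] <- tibble::tibble(
      gene_id = sprintf("gene%04d", gi), chrom = chrom, strand = strand,
      exon = seq_len(n_ex), start = starts[ord], end = ends[ord])
    cursor[chrom] <- start + span
    ci <- ci %% length(genome) + 1L
  }
  genes <- dplyr::bind_rows(rows)

  # rewrite splice flanks around every exon on the template strand
  for (ch in unique(genes$chrom)) {
    s <- genome[[ch]]
    sub <- genes[genes$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      if (sub$strand[i] == "+") {
        s <- splice_into(s, sub$start[i] - 2L, "AG")
        s <- splice_into(s, sub$end[i], "GT")
      } else {
        s <- splice_into(s, sub$start[i] - 2L, "AC")
        s <- splice_into(s, sub$end[i], "CT")
      }
    }
    genome[[ch]] <- s
  }
  list(genome = genome, genes = genes)
}

#' Spliced linear transcript sequence of a gene
#'
#' Concatenates exon sequences in transcript (5'->3') order, reverse
#' complementing for minus-strand genes.
#'
#' @param genes Gene-model tibble from [sim_genes()].
#' @param genome Named character genome vector.
#' @param gene_id Gene identifier.
#' @return A single character string.
#' @export
splice_transcript <- function(genes, genome, gene_id) {
  ex <- genes[genes$gene_id == gene_id, ]
  if (nrow(ex) == 0L) abort(sprintf("Unknown gene_id '%s'.", gene_id))
  ex <- ex[order(ex$exon), ]
  pieces <- sub0(genome[[ex$chrom[1]]], ex$start, ex$end)
  if (ex$strand[1] == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

#' Plant a circular RNA from a contiguous exon block
#'
#' The circle's spliced sequence is the concatenation of the chosen exons in
#' transcript order; its backsplice junction joins the end of `exon_to` back
#' to the start of `exon_from`. The junction is recorded in genomic
#' coordinates as `(acceptor_pos, donor_pos)` with `acceptor_pos < donor_pos`
#' (start/end of the genomic span of the block), plus the strand.
#'
#' @param genes Gene-model tibble from [sim_genes()].
#' @param genome Named character genome vector.
#' @param gene_id Source gene.
#' @param exon_from,exon_to 1-based exon indices (transcript order) of the
#'   circularized block; `exon_from <= exon_to`.
#' @param abundance Named numeric vector of per-sample true abundances.
#' @param circ_id Optional identifier (default derived from the junction).
#' @return One-row tibble: `circ_id`, `gene_id`, `chrom`, `strand`,
#'   `acceptor_pos`, `donor_pos`, `length`, `seq`, and `abundance`
#'   (a list-column holding the named per-sample vector).
#' @export
plant_circ <- function(genes, genome, gene_id, exon_from, exon_to,
                       abundance, circ_id = NULL) {
  ex <- genes[genes$gene_id == gene_id, ]
  if (nrow(ex) == 0L) abort(sprintf("Unknown gene_id '%s'.", gene_id))
  ex <- ex[order(ex$exon), ]
  if (exon_from > exon_to || exon_from < 1L || exon_to > nrow(ex)) {
    abort("`exon_from`/`exon_to` out of range or reversed.")
  }
  blk <- ex[seq(exon_from, exon_to), ]
  pieces <- sub0(genome[[blk$chrom[1]]], blk$start, blk$end)
  if (blk$strand[1] == "-") pieces <- revcomp(pieces)
  seq <- paste(pieces, collapse = "")
  if (nchar(seq) < 40L) abort("Circularized block must be >= 40 nt.")
  acc <- min(blk$start)
  don <- max(blk$end)
  if (is.null(circ_id)) {
    circ_id <- sprintf("%s:%d-%d:%s", blk$chrom[1], acc, don, blk$strand[1])
  }
  tibble::tibble(
    circ_id = circ_id, gene_id = gene_id, chrom = blk$chrom[1],
    strand = blk$strand[1], exon_from = exon_from, exon_to = exon_to,
    acceptor_pos = acc, donor_pos = don, length = nchar(seq), seq = seq,
    abundance = list(abundance))
}

#' Assemble a simulation truth object
#'
#' Bundles planted circles, linear transcript abundances and the generating
#' seed into a single serializable object used by the read simulator and by
#' recovery tests.
#'
#' @param circs Tibble of planted circles ([plant_circ()] rows).
#' @param linear Tibble with columns `gene_id`, `seq` and `abundance`
#'   (list-column of named per-sample numeric vectors).
#' @param sample_names Character vector of sample names.
#' @param seed Generating seed (stored for provenance).
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(circs, linear, sample_names, seed = NA_integer_) {
  structure(list(circs = circs, linear = linear,
                 sample_names = sample_names, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d planted circles, %d linear transcripts, %d samples (seed %s)\n",
              nrow(x$circs), nrow(x$linear), length(x$sample_names),
              format(x$seed)))
  invisible(x)
}
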