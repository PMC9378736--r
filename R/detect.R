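#' Build an exact-match k-mer index over reference sequences
#'
#' Indexes every forward-strand k-mer of each reference sequence. Lookups
#' report perfect matches on both strands: a hit of the reverse complement of
#' the query at plus-strand position `p` is reported as a minus-strand
#' placement covering `[p, p + k)` in plus-strand coordinates.
#'
#' @param refs Named character vector of reference sequences (a genome from
#'   [sim_genome()], optionally plus spliced transcripts).
#' @param k K-mer length (default 20, the anchor length).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(refs, k = 20L) {
  stopifnot(is.character(refs), !is.null(names(refs)))
  if (any(nchar(refs) < k)) abort("`k` exceeds the length of a reference.")
  tabs <- lapply(names(refs), function(nm) {
    s <- refs[[nm]]
    n <- nchar(s) - k + 1L
    data.table::data.table(
      kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
      chrom = nm, pos = seq_len(n) - 1L)
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  structure(list(dt = dt, k = k), class = "kmer_index")
}

#' @rdname build_kmer_index
#' @param index A `kmer_index`.
#' @param queries Character vector of length-`k` sequences.
#' @return `kmer_lookup()` returns a tibble of placements: `query`, `chrom`,
#'   `pos` (0-based plus-strand start), `strand`.
#' @export
kmer_lookup <- function(index, queries) {
  stopifnot(inherits(index, "kmer_index"))
  if (length(queries) == 0L) {
    return(tibble::tibble(query = character(), chrom = character(),
                          pos = integer(), strand = character()))
  }
  fw <- index$dt[data.table::data.table(kmer = queries), nomatch = NULL,
                 on = "kmer"]
  fw[, strand := "+"]
  rcq <- revcomp(queries)
  rv <- index$dt[data.table::data.table(kmer = rcq, orig = queries),
                 nomatch = NULL, on = "kmer"]
  rv[, strand := "-"]
  rv[, kmer := rv$orig]
  rv[, "orig" := NULL]
  out <- data.table::rbindlist(list(fw, rv), use.names = TRUE)
  tibble::tibble(query = out$kmer, chrom = out$chrom, pos = out$pos,
                 strand = out$strand)
}

#' Partition reads into linearly mapped and unmapped
#'
#' A read is *mapped* when it matches a linear reference (genome chromosome
#' or spliced transcript) contiguously end-to-end, on either strand, with at
#' most `max_mismatch` substitutions. All other reads are unmapped and feed
#' the backsplice detector. Mapping uses non-overlapping k-mer seeds at read
#' offsets `0, k, 2k, ...` followed by full-length verification, so detection
#' of a true placement is guaranteed whenever the substitution count is
#' below the number of seeds.
#'
#' @param reads Tibble with columns `sample`, `read_id`, `seq`.
#' @param refs Named character vector of linear reference sequences.
#' @param k Seed length.
#' @param max_mismatch Per-read substitution budget (default 2).
#' @param index Optional pre-built [build_kmer_index()] over `refs`.
#' @return List with `mapped` and `unmapped` (row subsets of `reads`) and
#'   `mapped_totals`, a named per-sample count of mapped reads (the RPM
#'   denominators).
#' @export
partition_linear <- function(reads, refs, k = 20L, max_mismatch = 2L,
                             index = NULL) {
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0L) {
    return(list(mapped = reads, unmapped = reads,
                mapped_totals = setNames(numeric(), character())))
  }
  if (any(nchar(reads$seq) < 2L * k)) {
    abort("All reads must be at least 2k nt long.")
  }
  if (is.null(index)) index <- build_kmer_index(refs, k)
  n <- nchar(reads$seq[1])
  if (any(nchar(reads$seq) != n)) abort("Reads must have equal length.")
  n_seeds <- n %/% k
  seed_off <- (seq_len(n_seeds) - 1L) * k
  ref_len <- setNames(nchar(refs), names(refs))

  oriented <- list(fwd = reads$seq, rev = revcomp(reads$seq))
  mapped <- rep(FALSE, nrow(reads))
  for (orient in names(oriented)) {
    sq <- oriented[[orient]]
    todo <- which(!mapped)
    if (length(todo) == 0L) break
    cand <- list()
    for (so in seed_off) {
      seeds <- substring(sq[todo], so + 1L, so + k)
      hits <- kmer_lookup(index, unique(seeds))
      hits <- hits[hits$strand == "+", , drop = FALSE]
      if (nrow(hits) == 0L) next
      sp <- split(seq_len(nrow(hits)), hits$query)
      mi <- match(seeds, names(sp))
      cnt <- ifelse(is.na(mi), 0L, lengths(sp)[mi])
      rows <- rep(todo, times = cnt)
      hi <- unlist(sp[mi[!is.na(mi)]], use.names = FALSE)
      if (length(hi) == 0L) next
      cand[[length(cand) + 1L]] <- tibble::tibble(
        row = rows, chrom = hits$chrom[hi], start = hits$pos[hi] - so)
    }
    if (length(cand) == 0L) next
    cand <- dplyr::distinct(dplyr::bind_rows(cand))
    cand <- cand[cand$start >= 0L &
                   cand$start + n <= ref_len[cand$chrom], , drop = FALSE]
    if (nrow(cand) == 0L) next
    refsub <- substring(refs[cand$chrom], cand$start + 1L, cand$start + n)
    qry <- sq[cand$row]
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      hamming(qry[i], refsub[i]) <= max_mismatch
    }, logical(1))
    mapped[unique(cand$row[ok])] <- TRUE
  }
  totals <- tapply(mapped, reads$sample, sum)
  totals <- setNames(as.numeric(totals), names(totals))
  list(mapped = reads[mapped, , drop = FALSE],
       unmapped = reads[!mapped, , drop = FALSE],
       mapped_totals = totals)
}

#' Extract terminal anchors from a read
#'
#' The left anchor is the first `k` bases and the right anchor the last `k`
#' bases of the read, taken verbatim.
#'
#' @param seq Read sequence (length >= 2k).
#' @param k Anchor length.
#' @return List with `left` and `right` k-mers.
#' @export
extract_anchors <- function(seq, k = 20L) {
  n <- nchar(seq)
  if (n < 2L * k) abort("Read shorter than 2k; cannot extract anchors.")
  list(left = substring(seq, 1L, k), right = substring(seq, n - k + 1L, n))
}

# Place both anchors of a read; returns NULL unless both are uniquely
# placed on the same chromosome and strand. For minus-strand placements the
# read is reverse complemented so downstream logic always works in
# plus-strand coordinates.
place_anchor_pair <- function(seq, index, k) {
  a <- extract_anchors(seq, k)
  pl <- kmer_lookup(index, c(a$left, a$right))
  pL <- pl[pl$query == a$left, , drop = FALSE]
  pR <- pl[pl$query == a$right, , drop = FALSE]
  if (nrow(pL) != 1L || nrow(pR) != 1L) return(NULL)      # ambiguous/unplaced
  if (pL$chrom != pR$chrom || pL$strand != pR$strand) return(NULL)
  if (pL$strand == "+") {
    list(seq = seq, chrom = pL$chrom, pL = pL$pos, pR = pR$pos)
  } else {
    # the reverse complement of the read places forward; anchors swap roles
    list(seq = revcomp(seq), chrom = pL$chrom, pL = pR$pos, pR = pL$pos)
  }
}

#' Head-to-tail test on a placed anchor pair
#'
#' A provisional backsplice junction is emitted when the right anchor places
#' upstream of the left anchor (reversed genomic order relative to read
#' order) within `span_cap`.
#'
#' @param pair Placed anchor pair from `place_anchor_pair()` (fields `seq`,
#'   `chrom`, `pL`, `pR` in plus-strand coordinates).
#' @param span_cap Maximum genomic span between anchors (default 100 kb).
#' @return The pair (as a provisional junction) or `NULL`.
#' @export
detect_headtotail <- function(pair, span_cap = 1e5) {
  if (is.null(pair)) return(NULL)
  if (pair$pR >= pair$pL) return(NULL)          # colinear or overlapping
  if (pair$pL - pair$pR > span_cap) return(NULL)
  pair
}

#' Extend a provisional junction to a flank-validated breakpoint
#'
#' Slides the breakpoint across the read so that the whole read aligns as
#' (suffix of circle) + (prefix of circle) with at most `max_mismatch`
#' substitutions in total, and the genomic flanks match a splice signature:
#' `GT` after the donor and `AG` before the acceptor for a plus-strand
#' circle, or the complement signature (`CT` after the donor, `AC` before
#' the acceptor on the plus strand) for a minus-strand circle. When several
#' breakpoints validate, the one with the leftmost acceptor is returned
#' (ties to the plus-strand signature) and the tie is flagged.
#'
#' @param provisional Provisional junction from [detect_headtotail()].
#' @param genome Named character genome vector.
#' @param k Anchor length.
#' @param max_mismatch Per-read substitution budget.
#' @param min_span Minimum circle span in nt (default `2 * k`).
#' @return A one-row tibble (`chrom`, `strand`, `acceptor_pos`, `donor_pos`,
#'   `tie`) or `NULL` when no breakpoint validates.
#' @export
extend_to_breakpoint <- function(provisional, genome, k = 20L,
                                 max_mismatch = 2L, min_span = NULL) {
  if (is.null(provisional)) return(NULL)
  if (is.null(min_span)) min_span <- 2L * k
  sq <- provisional$seq
  n <- nchar(sq)
  chrom <- genome[[provisional$chrom]]
  clen <- nchar(chrom)
  pL <- provisional$pL
  pR <- provisional$pR

  # cumulative mismatches of read prefixes against the genome from pL
  left_end <- min(pL + n, clen)
  lref <- sub0(chrom, pL, left_end)
  lmis <- c(mismatch_vec(substring(sq, 1L, nchar(lref)), lref),
            rep(TRUE, n - nchar(lref)))
  cumL <- cumsum(lmis)

  # cumulative mismatches of read suffixes against the genome ending at pR+k
  rstart <- max(pR + k - n, 0L)
  rref <- sub0(chrom, rstart, pR + k)
  pad <- n - nchar(rref)
  rmis <- c(rep(TRUE, pad),
            mismatch_vec(substring(sq, pad + 1L, n), rref))
  sufR <- rev(cumsum(rev(rmis)))          # sufR[j] = mismatches in read[j..n]

  s <- seq(k, n - k)                       # candidate left-segment lengths
  acc <- pR + k - n + s
  don <- pL + s
  total <- cumL[s] + c(sufR, 0)[s + 1L]
  ok <- total <= max_mismatch & acc >= 2L & don + 2L <= clen &
    acc < don & (don - acc) >= min_span
  if (!any(ok)) return(NULL)
  s <- s[ok]; acc <- acc[ok]; don <- don[ok]; total <- total[ok]
  dflank <- substring(chrom, don + 1L, don + 2L)
  aflank <- substring(chrom, acc - 1L, acc)
  plus <- dflank == "GT" & aflank == "AG"
  minus <- dflank == "CT" & aflank == "AC"
  keep <- plus | minus
  if (!any(keep)) return(NULL)
  cand <- tibble::tibble(
    acceptor_pos = acc[keep], donor_pos = don[keep],
    mismatches = total[keep],
    strand = ifelse(plus[keep], "+", "-"))
  # best-scoring breakpoint first (fewest substitutions); among equal
  # scores the leftmost acceptor wins, then the plus-strand signature
  cand <- cand[order(cand$mismatches, cand$acceptor_pos, cand$strand), ,
               drop = FALSE]
  tibble::tibble(chrom = provisional$chrom, strand = cand$strand[1],
                 acceptor_pos = cand$acceptor_pos[1],
                 donor_pos = cand$donor_pos[1],
                 tie = sum(cand$mismatches == cand$mismatches[1]) > 1L)
}

#' Collect backsplice junction evidence from unmapped reads
#'
#' Runs anchor extraction, unique placement, the head-to-tail test and
#' breakpoint extension over every unmapped read.
#'
#' @param unmapped Tibble (`sample`, `read_id`, `seq`) of unmapped reads.
#' @param genome Named character genome vector.
#' @param k Anchor length.
#' @param max_mismatch Substitution budget.
#' @param span_cap Maximum genomic anchor span.
#' @param index Optional pre-built genome [build_kmer_index()].
#' @return Evidence tibble: one row per validated junction read with
#'   `sample`, `read_id`, `seq`, `chrom`, `strand`, `acceptor_pos`,
#'   `donor_pos`, `tie`.
#' @export
collect_junction_evidence <- function(unmapped, genome, k = 20L,
                                      max_mismatch = 2L, span_cap = 1e5,
                                      index = NULL) {
  unmapped <- tibble::as_tibble(unmapped)
  if (is.null(index)) index <- build_kmer_index(genome, k)
  if (nrow(unmapped) == 0L) {
    return(tibble::tibble(sample = character(), read_id = character(),
                          seq = character(), chrom = character(),
                          strand = character(), acceptor_pos = integer(),
                          donor_pos = integer(), tie = logical()))
  }
  # batch anchor placement: one lookup over all distinct terminal k-mers
  n <- nchar(unmapped$seq)
  left <- substring(unmapped$seq, 1L, k)
  right <- substring(unmapped$seq, n - k + 1L, n)
  pl <- kmer_lookup(index, unique(c(left, right)))
  sp <- split(seq_len(nrow(pl)), pl$query)
  first <- vapply(sp, `[`, integer(1), 1L)
  uq_n <- lengths(sp)
  li <- match(left, names(sp))
  ri <- match(right, names(sp))
  uniqL <- !is.na(li) & uq_n[li] == 1L
  uniqR <- !is.na(ri) & uq_n[ri] == 1L
  usable <- uniqL & uniqR
  usable[usable] <- pl$chrom[first[li[usable]]] ==
    pl$chrom[first[ri[usable]]] &
    pl$strand[first[li[usable]]] == pl$strand[first[ri[usable]]]

  out <- vector("list", sum(usable))
  j <- 0L
  for (i in which(usable)) {
    fl <- first[li[i]]
    fr <- first[ri[i]]
    pair <- if (pl$strand[fl] == "+") {
      list(seq = unmapped$seq[i], chrom = pl$chrom[fl],
           pL = pl$pos[fl], pR = pl$pos[fr])
    } else {
      list(seq = revcomp(unmapped$seq[i]), chrom = pl$chrom[fl],
           pL = pl$pos[fr], pR = pl$pos[fl])
    }
    prov <- detect_headtotail(pair, span_cap)
    if (is.null(prov)) next
    bp <- extend_to_breakpoint(prov, genome, k = k,
                               max_mismatch = max_mismatch)
    if (is.null(bp)) next
    j <- j + 1L
    out[[j]] <- list(sample = unmapped$sample[i],
                     read_id = unmapped$read_id[i], seq = unmapped$seq[i],
                     chrom = bp$chrom, strand = bp$strand,
                     acceptor_pos = bp$acceptor_pos,
                     donor_pos = bp$donor_pos, tie = bp$tie)
  }
  if (j == 0L) {
    return(tibble::tibble(sample = character(), read_id = character(),
                          seq = character(), chrom = character(),
                          strand = character(), acceptor_pos = integer(),
                          donor_pos = integer(), tie = logical()))
  }
  tibble::as_tibble(data.table::rbindlist(out[seq_len(j)]))
}

#' Call circRNA candidates from junction evidence
#'
#' Evidence is grouped by the exact junction `(chrom, strand, acceptor_pos,
#' donor_pos)`. *Unique* supporting reads are reads with distinct nucleotide
#' sequences (exact duplicates collapse to one). A candidate is kept when at
#' least one sample contributes `min_unique` unique reads. Candidates are
#' optionally annotated as known/novel against a junction catalogue.
#'
#' @param evidence Evidence tibble from [collect_junction_evidence()].
#' @param min_unique Minimum unique reads in at least one sample (default 2).
#' @param samples Optional full sample set (for zero-support columns).
#' @param catalogue Optional tibble of known junctions (`chrom`,
#'   `acceptor_pos`, `donor_pos`, `strand`), e.g. from [read_junctions_bed()].
#' @return List with `candidates` (one row per called junction: `circ_id`,
#'   coordinates, `total_support`, `best_sample_support`, `known`) and
#'   `support`, a candidates-by-samples tibble of unique-read counts.
#' @export
call_candidates <- function(evidence, min_unique = 2L, samples = NULL,
                            catalogue = NULL) {
  ev <- tibble::as_tibble(evidence)
  if (nrow(ev) == 0L) {
    return(list(candidates = tibble::tibble(
      circ_id = character(), chrom = character(), strand = character(),
      acceptor_pos = integer(), donor_pos = integer(),
      total_support = integer(), best_sample_support = integer(),
      known = logical()),
      support = tibble::tibble(circ_id = character())))
  }
  per <- ev |>
    dplyr::distinct(.data$chrom, .data$strand, .data$acceptor_pos,
                    .data$donor_pos, .data$sample, .data$seq) |>
    dplyr::count(.data$chrom, .data$strand, .data$acceptor_pos,
                 .data$donor_pos, .data$sample, name = "unique_reads")
  agg <- per |>
    dplyr::group_by(.data$chrom, .data$strand, .data$acceptor_pos,
                    .data$donor_pos) |>
    dplyr::summarise(total_support = sum(.data$unique_reads),
                     best_sample_support = max(.data$unique_reads),
                     .groups = "drop") |>
    dplyr::filter(.data$best_sample_support >= min_unique) |>
    dplyr::mutate(circ_id = sprintf("%s:%d-%d:%s", .data$chrom,
                                    .data$acceptor_pos, .data$donor_pos,
                                    .data$strand)) |>
    dplyr::relocate("circ_id")
  known <- if (!is.null(catalogue)) {
    paste(agg$chrom, agg$acceptor_pos, agg$donor_pos, agg$strand) %in%
      paste(catalogue$chrom, catalogue$acceptor_pos, catalogue$donor_pos,
            catalogue$strand)
  } else {
    rep(NA, nrow(agg))
  }
  agg$known <- known
  if (is.null(samples)) samples <- sort(unique(ev$sample))
  sup <- per |>
    dplyr::mutate(circ_id = sprintf("%s:%d-%d:%s", .data$chrom,
                                    .data$acceptor_pos, .data$donor_pos,
                                    .data$strand)) |>
    dplyr::filter(.data$circ_id %in% agg$circ_id) |>
    dplyr::select("circ_id", "sample", "unique_reads") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "unique_reads",
                       values_fill = 0L)
  for (s in setdiff(samples, names(sup))) sup[[s]] <- 0L
  sup <- sup[, c("circ_id", samples), drop = FALSE]
  list(candidates = agg, support = sup[match(agg$circ_id, sup$circ_id), ])
}

#' Detect circRNA candidates from reads (one-call wrapper)
#'
#' Chains [partition_linear()], [collect_junction_evidence()] and
#' [call_candidates()].
#'
#' @param reads Tibble (`sample`, `read_id`, `seq`).
#' @param genome Named character genome vector.
#' @param transcripts Optional named character vector of spliced linear
#'   transcripts (included in the linear mapping reference).
#' @param k,max_mismatch,span_cap,min_unique,catalogue See the stage
#'   functions.
#' @return List: `candidates`, `support`, `mapped_totals`, `evidence`.
#' @export
detect_junctions <- function(reads, genome, transcripts = NULL, k = 20L,
                             max_mismatch = 2L, span_cap = 1e5,
                             min_unique = 2L, catalogue = NULL) {
  refs <- c(genome, transcripts)
  part <- partition_linear(reads, refs, k = k, max_mismatch = max_mismatch)
  ev <- collect_junction_evidence(part$unmapped, genome, k = k,
                                  max_mismatch = max_mismatch,
                                  span_cap = span_cap)
  called <- call_candidates(ev, min_unique = min_unique,
                            samples = sort(unique(reads$sample)),
                            catalogue = catalogue)
  c(called, list(mapped_totals = part$mapped_totals, evidence = ev))
}
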