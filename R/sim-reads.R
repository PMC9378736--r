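#' Simulate single-end reads from linear and circular transcripts
#'
#' Reads are drawn per sample by a multinomial over all templates with
#' weights proportional to abundance times template length (fragment
#' sampling). Linear templates yield reads with uniform start positions;
#' circular templates are treated as rolling templates (start uniform on
#' `[0, L)`, sequence taken from the unrolled circle), so reads may cross the
#' backsplice junction. Sequencing error is i.i.d. per-base substitution;
#' no indels, matching the fixed-length exact-match anchor contract of the
#' detector.
#'
#' Read names encode the ground-truth origin as
#' `sample|kind:id|u:start|j:flag|i` where `flag` is 0 for a read that does
#' not cross the junction, 1 for any junction-crossing read, and 2 for a
#' junction-crossing read with at least `anchor_k` nt on each side of the
#' junction (the reads the anchor detector can in principle recover).
#'
#' @param truth A [sim_truth()] object.
#' @param read_len Read length in nt (>= `2 * anchor_k`).
#' @param depth Reads per sample.
#' @param err Per-base substitution rate in `[0, 1)`.
#' @param anchor_k Anchor length used for the `j:2` bookkeeping flag.
#' @param seed Optional integer seed.
#' @return Tibble with columns `sample`, `read_id`, `seq`. The attribute
#'   `junction_counts` holds a tibble of simulated junction-read counts
#'   (`circ_id`, `sample`, `n_crossing`, `n_anchor_safe`) recomputed nowhere:
#'   it is the simulator's own tally, checked against read names in tests.
#' @export
sim_reads <- function(truth, read_len = 150L, depth = 2000L, err = 0,
                      anchor_k = 20L, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (read_len < 2L * anchor_k) {
    abort(sprintf("`read_len` must be >= 2 * anchor_k = %d nt.", 2L * anchor_k))
  }
  check_scalar_number(err, "err", lower = 0, upper = 0.999)
  if (!is.null(seed)) set.seed(seed)

  templates <- dplyr::bind_rows(
    tibble::tibble(kind = "circ", id = truth$circs$circ_id,
                   seq = truth$circs$seq,
                   abundance = truth$circs$abundance),
    tibble::tibble(kind = "linear", id = truth$linear$gene_id,
                   seq = truth$linear$seq,
                   abundance = truth$linear$abundance))
  templates$len <- nchar(templates$seq)
  if (any(templates$kind == "linear" & templates$len < read_len)) {
    abort("All linear templates must be at least `read_len` nt long.")
  }

  out <- vector("list", length(truth$sample_names))
  jc <- list()
  for (si in seq_along(truth$sample_names)) {
    sm <- truth$sample_names[si]
    ab <- vapply(templates$abundance, function(a) {
      v <- if (!is.null(names(a))) unname(a[sm]) else a[si]
      if (is.na(v)) 0 else v
    }, numeric(1))
    w <- ab * templates$len
    if (depth == 0L || sum(w) == 0) {
      out[[si]] <- tibble::tibble(sample = character(), read_id = character(),
                                  seq = character())
      next
    }
    counts <- as.integer(rmultinom(1L, depth, w))
    rows <- which(counts > 0L)
    reads <- vector("list", length(rows))
    for (ri in seq_along(rows)) {
      tr <- rows[ri]
      n <- counts[tr]
      L <- templates$len[tr]
      if (templates$kind[tr] == "circ") {
        u <- sample.int(L, n, replace = TRUE) - 1L
        unrolled <- strrep(templates$seq[tr], ceiling((L + read_len) / L))
        sq <- substring(unrolled, u + 1L, u + read_len)
        ll <- L - u  # nt before the junction for crossing reads
        crossing <- u > 0L & (u + read_len) > L
        safe <- crossing & ll >= anchor_k & (read_len - ll) >= anchor_k
        jflag <- ifelse(safe, 2L, ifelse(crossing, 1L, 0L))
      } else {
        u <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
        sq <- substring(templates$seq[tr], u + 1L, u + read_len)
        jflag <- rep(0L, n)
      }
      reads[[ri]] <- tibble::tibble(
        sample = sm,
        read_id = sprintf("%s|%s:%s|u:%d|j:%d|%d", sm, templates$kind[tr],
                          templates$id[tr], u, jflag, seq_len(n)),
        seq = sq, kind = templates$kind[tr], tid = templates$id[tr],
        jflag = jflag)
    }
    reads <- dplyr::bind_rows(reads)
    if (err > 0 && nrow(reads) > 0L) {
      n_err <- rbinom(nrow(reads), read_len, err)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(read_len, n_err[i])
        ch <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        reads$seq[i] <- paste(ch, collapse = "")
      }
    }
    jc[[si]] <- reads |>
      dplyr::filter(.data$kind == "circ") |>
      dplyr::group_by(circ_id = .data$tid, sample = .data$sample) |>
      dplyr::summarise(n_crossing = sum(.data$jflag >= 1L),
                       n_anchor_safe = sum(.data$jflag == 2L),
                       .groups = "drop")
    out[[si]] <- reads[, c("sample", "read_id", "seq")]
  }
  res <- dplyr::bind_rows(out)
  attr(res, "junction_counts") <- dplyr::bind_rows(jc)
  res
}
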