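#' Enumerate rolling-circle open reading frames on a circular sequence
#'
#' The circular sequence is given with its backsplice junction at offset 0
#' (base 0 is the acceptor-side first base). For every ATG start offset
#' `s` in `[0, L)` (the start codon may itself wrap across the junction),
#' translation proceeds codon by codon around the circle until the first
#' in-frame stop or until `3L` nt (three full passes) are consumed. Three
#' passes are exhaustive: translation positions are periodic with period
#' `3L` nt, so an ORF with no stop within three passes never terminates and
#' is reported with `has_stop = FALSE` and its peptide truncated at `3L` nt
#' (`truncated = TRUE`).
#'
#' Junction bookkeeping follows a fixed convention: translation *crosses*
#' the junction each time a consumed codon (including the stop codon)
#' contains a position congruent to offset 0 beyond the start
#' (`passes` counts these crossings); `spans_junction = passes >= 1`;
#' `exceeds_360 = nt_length + 3 > L`, i.e. the ORF plus its stop codon is
#' longer than the circumference.
#'
#' The frameshift-derived unique C-terminus (`unique_cterm`) is the peptide
#' suffix translated after the ribosome re-enters sequence already traversed
#' in an earlier pass: residues from codon index `ceiling(L/3)` onward
#' (0-based, counted from the start codon). When `L %% 3 == 0` the reading
#' frame never shifts between passes and the segment is empty by definition.
#'
#' @param seq Circular sequence (ACGT, length >= 6), junction at offset 0.
#' @param circ_id Optional identifier copied into the output.
#' @param max_passes Number of full passes that bound translation (3 is
#'   exhaustive; kept as an argument for documentation purposes).
#' @return Tibble with one row per ATG: `circ_id`, `start_offset`,
#'   `nt_length` (sense codons only, stop excluded), `aa_length`,
#'   `has_stop`, `truncated`, `passes`, `spans_junction`, `exceeds_360`,
#'   `peptide`, `unique_cterm`.
#' @examples
#' circ_orfs("ATGAAATAG")
#' @export
circ_orfs <- function(seq, circ_id = NA_character_, max_passes = 3L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 6L) abort("Circular sequence must be >= 6 nt.")
  if (grepl("[^ACGTN]", seq)) abort("Sequence must be over ACGT (N allowed).")
  unrolled <- strrep(seq, max_passes + 1L)

  starts1 <- gregexpr("ATG", substring(unrolled, 1L, L + 2L),
                      fixed = TRUE)[[1]]
  starts <- if (starts1[1] == -1L) integer() else as.integer(starts1) - 1L
  stop1 <- gregexpr("TAA|TAG|TGA", unrolled)[[1]]
  stops <- if (stop1[1] == -1L) integer() else as.integer(stop1) - 1L

  empty <- tibble::tibble(
    circ_id = character(), start_offset = integer(), nt_length = integer(),
    aa_length = integer(), has_stop = logical(), truncated = logical(),
    passes = integer(), spans_junction = logical(), exceeds_360 = logical(),
    peptide = character(), unique_cterm = character())
  if (length(starts) == 0L) return(empty)

  rows <- lapply(starts, function(s) {
    frame_stops <- stops[stops %% 3L == s %% 3L & stops >= s + 3L &
                           stops <= s + 3L * L - 3L]
    if (length(frame_stops) > 0L) {
      p <- frame_stops[1]
      nt_len <- p - s
      has_stop <- TRUE
      truncated <- FALSE
      nt_total <- nt_len + 3L      # stop codon is consumed
    } else {
      nt_len <- 3L * L
      has_stop <- FALSE
      truncated <- TRUE
      nt_total <- nt_len
    }
    pep <- translate_nt(substring(unrolled, s + 1L, s + nt_len))
    # non-ACGT codon terminates the ORF at that codon
    xi <- regexpr("X", pep, fixed = TRUE)
    invalid <- xi > 0L
    if (invalid) {
      pep <- substring(pep, 1L, xi - 1L)
      nt_len <- 3L * (xi - 1L)
      nt_total <- nt_len
      has_stop <- FALSE
      truncated <- FALSE
    }
    lastpos <- s + nt_total - 1L
    passes <- lastpos %/% L
    aa_len <- nt_len %/% 3L
    i0 <- ceiling(L / 3)           # first re-entrant codon (0-based index)
    uc <- if (passes >= 1L && L %% 3L != 0L && aa_len > i0) {
      substring(pep, i0 + 1L, aa_len)
    } else {
      ""
    }
    list(circ_id = circ_id, start_offset = s, nt_length = nt_len,
         aa_length = aa_len, has_stop = has_stop, truncated = truncated,
         passes = as.integer(passes),
         spans_junction = passes >= 1L,
         exceeds_360 = nt_len + 3L > L, peptide = pep, unique_cterm = uc)
  })
  tibble::as_tibble(data.table::rbindlist(rows))
}

#' Frameshift-derived unique C-terminal segment of a rolling ORF
#'
#' Returns the residues translated from positions already covered in an
#' earlier pass but in a shifted reading frame (see [circ_orfs()] for the
#' convention). Requires a junction-spanning ORF (`passes >= 1`) on a circle
#' whose length is not a multiple of 3; otherwise the segment is empty and
#' the reason is attached as an attribute.
#'
#' @param orf One row of a [circ_orfs()] result.
#' @param seq The circular sequence the ORF was called on.
#' @return Character scalar (possibly `""` with attribute `reason`).
#' @export
orf_unique_cterm <- function(orf, seq) {
  L <- nchar(seq)
  if (orf$passes < 1L) {
    return(structure("", reason = "single-pass ORF"))
  }
  if (L %% 3L == 0L) {
    return(structure("", reason = "L %% 3 == 0: frame never shifts"))
  }
  i0 <- ceiling(L / 3)
  if (orf$aa_length <= i0) {
    return(structure("", reason = "ORF ends before re-entry"))
  }
  substring(orf$peptide, i0 + 1L, orf$aa_length)
}

#' Best (screen-representative) rolling ORF of a circle
#'
#' The longest ORF, restricted to junction-spanning ORFs when
#' `require_junction` is set; ties broken by smallest start offset.
#'
#' @param orfs A [circ_orfs()] result for one circle.
#' @param require_junction Restrict to junction-spanning ORFs.
#' @return One-row tibble, or a zero-row tibble when no ORF qualifies.
#' @export
best_circ_orf <- function(orfs, require_junction = TRUE) {
  x <- if (require_junction) orfs[orfs$spans_junction, , drop = FALSE] else
    orfs
  if (nrow(x) == 0L) return(x)
  x[order(-x$aa_length, x$start_offset), , drop = FALSE][1L, ]
}

#' Screen filter for circORF candidates
#'
#' Keeps records whose ORF spans the backsplice junction (when required)
#' and encodes a peptide strictly shorter than `max_aa` amino acids, the
#' small-peptide window of the screen.
#'
#' @param records Tibble with at least `aa_length` and `spans_junction`.
#' @param require_junction Require `spans_junction`.
#' @param max_aa Strict upper bound on peptide length (default 100 aa).
#' @return The retained rows, with attributes `n_in`, `n_out` and
#'   `retained_fraction`.
#' @export
filter_circorfs <- function(records, require_junction = TRUE, max_aa = 100L) {
  keep <- records$aa_length < max_aa
  if (require_junction) keep <- keep & records$spans_junction
  out <- records[keep, , drop = FALSE]
  attr(out, "n_in") <- nrow(records)
  attr(out, "n_out") <- nrow(out)
  attr(out, "retained_fraction") <-
    if (nrow(records) > 0L) nrow(out) / nrow(records) else NA_real_
  out
}

#' Enumerate main ORFs of a linear transcript
#'
#' Standard ATG-to-stop ORFs on the given (sense) strand, three frames,
#' reporting the longest ORF per stop codon. Used for the circORF versus
#' mORF length comparison.
#'
#' @param seq Linear nucleotide sequence.
#' @return Tibble: `start_offset` (0-based), `nt_length` (stop excluded),
#'   `aa_length`, ordered by position.
#' @export
linear_morfs <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- tibble::tibble(start_offset = integer(), nt_length = integer(),
                          aa_length = integer())
  if (n < 6L) return(empty)
  atg1 <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  atgs <- if (atg1[1] == -1L) integer() else as.integer(atg1) - 1L
  stop1 <- gregexpr("TAA|TAG|TGA", seq)[[1]]
  stops <- if (stop1[1] == -1L) integer() else as.integer(stop1) - 1L
  if (length(atgs) == 0L) return(empty)
  rows <- list()
  for (f in 0:2) {
    fa <- atgs[atgs %% 3L == f]
    fs <- stops[stops %% 3L == f]
    prev_stop <- -3L
    for (p in fs) {
      cand <- fa[fa > prev_stop & fa + 3L <= p]
      if (length(cand) > 0L) {
        s <- cand[1]              # earliest ATG -> longest ORF for this stop
        rows[[length(rows) + 1L]] <- list(start_offset = s,
                                          nt_length = p - s,
                                          aa_length = (p - s) %/% 3L)
      }
      prev_stop <- p
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- tibble::as_tibble(data.table::rbindlist(rows))
  out[order(out$start_offset), ]
}

#' Synthetic worked-example circle (253 nt, 92-aa rolling ORF)
#'
#' Constructs, deterministically, a designed 253-nt circular sequence whose
#' single rolling ORF starts at the junction, spans more than 360 degrees
#' and encodes a 92-aa peptide with a frameshift-derived unique C-terminus —
#' the geometry of the circEZH2/EZH2-92aa worked example (a 253-nt circle
#' from two exons of 100 + 153 nt encoding a 92-aa protein). The sequence
#' itself is synthetic: it reproduces the coding geometry, not the natural
#' bases.
#'
#' @return Character scalar of length 253.
#' @export
circ_demo_sequence <- function() {
  L <- 253L
  set.seed(104729L)  # fixed internal seed: the fixture is a constant
  base <- strsplit(random_dna(L, gc = 0.5), "", fixed = TRUE)[[1]]
  base[1:3] <- c("A", "T", "G")
  base[24:26] <- c("T", "A", "A")   # stop codon of the 92-aa ORF (2nd pass)
  get_circ <- function(ch) paste(ch, collapse = "")
  repeat {
    s <- get_circ(base)
    rolled <- strrep(s, 2L)
    # no ATG anywhere except offset 0 (cyclic)
    atg <- as.integer(gregexpr("ATG", substring(rolled, 1L, L + 2L),
                               fixed = TRUE)[[1]]) - 1L
    atg <- atg[atg >= 0L & atg != 0L]
    if (length(atg) > 0L) {
      base[(atg[1] + 2L) %% L + 1L] <- "C"
      next
    }
    # no in-frame stop among the first 92 codons of the frame-0 ORF
    bad <- NULL
    for (i in 0:91) {
      codon <- substring(rolled, 3L * i + 1L, 3L * i + 3L)
      if (codon %in% c("TAA", "TAG", "TGA")) { bad <- i; break }
    }
    if (!is.null(bad)) {
      base[(3L * bad) %% L + 1L] <- "C"
      next
    }
    break
  }
  get_circ(base)
}
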