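#' File input/output for the screen's standard formats
#'
#' FASTA and FASTQ go through Biostrings; GFF3, BED6 and GMT are simple
#' line formats written/read directly. All coordinates on disk follow each
#' format's own convention (GFF3 1-based closed, BED 0-based half-open).
#'
#' @param genome Named character genome vector.
#' @param path Output file path.
#' @return The path, invisibly (writers); tibbles (readers).
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname screen_io
#' @param genes Gene-model tibble from [sim_genes()].
#' @export
write_genes_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(genes$gene_id)) {
    ex <- genes[genes$gene_id == g, ]
    writeLines(sprintf("%s\tcircscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       ex$chrom[1], min(ex$start) + 1L, max(ex$end),
                       ex$strand[1], g), con)
    writeLines(sprintf(
      "%s\tcircscreen\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
      ex$chrom, ex$start + 1L, ex$end, ex$strand, g, ex$exon, g), con)
  }
  invisible(path)
}

#' @rdname screen_io
#' @export
read_genes_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, function(x) x[3] == "exon", logical(1))]
  attr_field <- vapply(f, `[`, character(1), 9L)
  tibble::tibble(
    gene_id = sub("^.*Parent=([^;]+).*$", "\\1", attr_field),
    chrom = vapply(f, `[`, character(1), 1L),
    strand = vapply(f, `[`, character(1), 7L),
    exon = as.integer(sub("^.*\\.e(\\d+);.*$", "\\1", attr_field)),
    start = as.integer(vapply(f, `[`, character(1), 4L)) - 1L,
    end = as.integer(vapply(f, `[`, character(1), 5L)))
}

#' @rdname screen_io
#' @param junctions Tibble with `chrom`, `acceptor_pos`, `donor_pos`,
#'   `strand`, an id column (`circ_id` or `name`) and optionally a score
#'   (`total_support`).
#' @export
write_junctions_bed <- function(junctions, path) {
  j <- tibble::as_tibble(junctions)
  nm <- j[["circ_id"]] %||% j[["name"]] %||%
    sprintf("junc%04d", seq_len(nrow(j)))
  sc <- j[["total_support"]] %||% rep(0L, nrow(j))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", j$chrom, j$acceptor_pos,
                     j$donor_pos, nm, format(sc), j$strand), path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_junctions_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0L) {
    return(tibble::tibble(chrom = character(), acceptor_pos = integer(),
                          donor_pos = integer(), name = character(),
                          score = numeric(), strand = character()))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = vapply(f, `[`, character(1), 1L),
    acceptor_pos = as.integer(vapply(f, `[`, character(1), 2L)),
    donor_pos = as.integer(vapply(f, `[`, character(1), 3L)),
    name = vapply(f, `[`, character(1), 4L),
    score = as.numeric(vapply(f, `[`, character(1), 5L)),
    strand = vapply(f, `[`, character(1), 6L))
}

#' @rdname screen_io
#' @param reads Reads tibble (`sample`, `read_id`, `seq`).
#' @param dir Directory for per-sample FASTQ files.
#' @return `write_reads_fastq()` returns the named vector of file paths.
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- sort(unique(reads$sample))
  paths <- setNames(file.path(dir, paste0(samples, ".fastq")), samples)
  for (s in samples) {
    rr <- reads[reads$sample == s, ]
    x <- Biostrings::DNAStringSet(rr$seq)
    names(x) <- rr$read_id
    qual <- Biostrings::BStringSet(strrep("I", nchar(rr$seq)))
    Biostrings::writeXStringSet(x, paths[s], format = "fastq",
                                qualities = qual)
  }
  paths
}

#' @rdname screen_io
#' @param sample Sample name to attach to reads read from one FASTQ.
#' @export
read_fastq_tbl <- function(path, sample = NA_character_) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      abort(sprintf("Invalid FASTQ file '%s': %s", path,
                    conditionMessage(e)))
    })
  tibble::tibble(sample = sample, read_id = names(x),
                 seq = unname(as.character(x)))
}

#' @rdname screen_io
#' @export
read_gmt <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  sets <- lapply(f, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(f, `[`, character(1), 1L)
  if (any(lengths(sets) == 0L)) abort("GMT contains an empty gene set.")
  sets
}

#' @rdname screen_io
#' @param sets Named list of character vectors (gene sets).
#' @param description Description field written to column 2.
#' @export
write_gmt <- function(sets, path, description = "na") {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
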