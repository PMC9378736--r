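#' Expression matrix container
#'
#' A thin tibble-based container for features-by-samples abundances with a
#' unit tag. The first column must be `feature_id`; remaining columns are
#' samples. The unit tag is set exactly once at construction.
#'
#' @param x Tibble or data frame with a `feature_id` column and one numeric
#'   column per sample.
#' @param unit One of `"count"`, `"RPM"`, `"FPKM"`, `"expression"`.
#' @return An `expr_mat` tibble with a `unit` attribute.
#' @export
expr_mat <- function(x, unit = c("count", "RPM", "FPKM", "expression")) {
  unit <- match.arg(unit)
  x <- tibble::as_tibble(x)
  if (names(x)[1] != "feature_id") abort("First column must be `feature_id`.")
  vals <- as.matrix(x[, -1])
  if (any(vals < 0, na.rm = TRUE)) abort("Expression values must be >= 0.")
  if (anyDuplicated(x$feature_id)) abort("Duplicate feature ids.")
  structure(x, unit = unit, class = c("expr_mat", class(x)))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> unit=%s, %d features x %d samples\n",
              attr(x, "unit"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' @rdname expr_mat
#' @param em An `expr_mat`.
#' @export
em_values <- function(em) {
  m <- as.matrix(em[, -1, drop = FALSE])
  rownames(m) <- em$feature_id
  m
}

#' @rdname expr_mat
#' @export
em_unit <- function(em) attr(em, "unit")

#' Scale junction-read counts to reads per million mapped reads (RPM)
#'
#' `RPM = count / mapped_total * 1e6`, the scaling used to quantify circRNA
#' backsplice-junction support.
#'
#' @param counts An `expr_mat` of unit `"count"`, or a tibble with
#'   `feature_id` plus per-sample count columns.
#' @param mapped_totals Named numeric vector of per-sample mapped-read totals
#'   (the linear-mapping denominators); all must be > 0.
#' @return An `expr_mat` with unit `"RPM"`.
#' @examples
#' cm <- tibble::tibble(feature_id = "j1", s1 = 5)
#' rpm_normalize(cm, c(s1 = 1e6))
#' @export
rpm_normalize <- function(counts, mapped_totals) {
  counts <- tibble::as_tibble(counts)
  smp <- setdiff(names(counts), "feature_id")
  missing <- setdiff(smp, names(mapped_totals))
  if (length(missing) > 0L) {
    abort(paste0("No mapped total for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- names(mapped_totals)[mapped_totals <= 0]
  bad <- intersect(bad, smp)
  if (length(bad) > 0L) {
    abort(paste0("Zero mapped total for sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- counts
  for (s in smp) out[[s]] <- counts[[s]] / mapped_totals[[s]] * 1e6
  expr_mat(out, unit = "RPM")
}

#' Scale gene counts to FPKM
#'
#' `FPKM = count / (length/1e3) / (mapped_total/1e6)`: fragments per kilobase
#' of transcript per million mapped reads.
#'
#' @param counts Tibble with `feature_id` plus per-sample count columns.
#' @param lengths Named numeric vector of feature lengths in nt (> 0).
#' @param mapped_totals Named numeric vector of per-sample totals (> 0).
#' @return An `expr_mat` with unit `"FPKM"`.
#' @export
fpkm_normalize <- function(counts, lengths, mapped_totals) {
  counts <- tibble::as_tibble(counts)
  smp <- setdiff(names(counts), "feature_id")
  len <- lengths[counts$feature_id]
  if (any(is.na(len))) abort("Missing length for some features.")
  if (any(len <= 0)) abort("Feature lengths must be > 0.")
  bad <- intersect(names(mapped_totals)[mapped_totals <= 0], smp)
  if (length(bad) > 0L) {
    abort(paste0("Zero mapped total for sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- counts
  for (s in smp) {
    out[[s]] <- unname(counts[[s]] / (len / 1e3) /
                         (mapped_totals[[s]] / 1e6))
  }
  expr_mat(out, unit = "FPKM")
}

#' Differential expression between tumour and normal samples
#'
#' Computes, per feature, `log2FC = log2(mean_T + pc) - log2(mean_N + pc)`
#' on the raw scale and a two-sided t test (paired, or Welch when
#' `paired = FALSE`) on `log2(value + pc)`. Features are called `up` when
#' `log2FC >= lfc_cut` and the (optionally BH-adjusted) p value is below
#' `p_cut`; `down` symmetrically; otherwise `ns`.
#'
#' This log-scale t test is an explicit stand-in for negative-binomial
#' count machinery: it keeps the thresholds of the screen contractual while
#' making no dispersion assumptions. The choice is recorded in the returned
#' object (`$method`).
#'
#' @param mat An `expr_mat` or tibble (`feature_id` + sample columns).
#' @param groups Named character vector mapping sample -> `"tumour"` /
#'   `"normal"`.
#' @param paired Use a paired t test (requires `pairs`).
#' @param pairs Named vector mapping sample -> pair id (required when
#'   `paired = TRUE`).
#' @param pseudocount Pseudocount added before logging (default 0.5; junction
#'   counts are sparse).
#' @param lfc_cut,p_cut Call thresholds.
#' @param adjust Apply Benjamini-Hochberg adjustment and threshold the
#'   adjusted p value (FDR) instead of the raw p value.
#' @return A `circ_de` object; use [tidy()] for the per-feature table and
#'   [glance()] for a one-row summary.
#' @export
de_test <- function(mat, groups, paired = TRUE, pairs = NULL,
                    pseudocount = 0.5, lfc_cut = 1, p_cut = 0.05,
                    adjust = FALSE) {
  m <- em_values(tibble::as_tibble(mat) |> expr_mat_passthrough())
  smp <- colnames(m)
  if (!all(smp %in% names(groups))) abort("Every sample needs a group label.")
  grp <- groups[smp]
  tum <- smp[grp == "tumour"]
  nor <- smp[grp == "normal"]
  if (length(tum) < 2L || length(nor) < 2L) {
    abort("Need >= 2 samples per group.")
  }
  if (paired) {
    if (is.null(pairs)) abort("`pairs` is required for a paired test.")
    if (length(tum) != length(nor)) {
      abort("Paired test requires equal group sizes.")
    }
    nor <- nor[match(pairs[tum], pairs[nor])]
    if (any(is.na(nor))) abort("`pairs` does not define a complete pairing.")
  }
  lm_ <- log2(m + pseudocount)
  lfc <- unname(log2(rowMeans(m[, tum, drop = FALSE]) + pseudocount) -
                  log2(rowMeans(m[, nor, drop = FALSE]) + pseudocount))
  p <- vapply(seq_len(nrow(m)), function(i) {
    x <- lm_[i, tum]
    y <- lm_[i, nor]
    out <- tryCatch(
      if (paired) t.test(x - y)$p.value else t.test(x, y)$p.value,
      error = function(e) NA_real_)
    if (is.na(out)) {
      warn(sprintf("Degenerate variance for feature '%s'; p set to 1.",
                   rownames(m)[i]))
      out <- 1
    }
    out
  }, numeric(1))
  padj <- p.adjust(p, method = "BH")
  p_eff <- if (adjust) padj else p
  call <- dplyr::case_when(
    lfc >= lfc_cut & p_eff < p_cut ~ "up",
    lfc <= -lfc_cut & p_eff < p_cut ~ "down",
    TRUE ~ "ns")
  structure(list(
    table = tibble::tibble(feature_id = rownames(m), log2fc = lfc,
                           p = p, padj = padj, call = call),
    method = if (paired) "paired t test on log2(value + pc)" else
      "Welch t test on log2(value + pc)",
    params = list(paired = paired, pseudocount = pseudocount,
                  lfc_cut = lfc_cut, p_cut = p_cut, adjust = adjust,
                  n_tumour = length(tum), n_normal = length(nor))),
    class = "circ_de")
}

# accept both expr_mat and plain tibbles in de_test
expr_mat_passthrough <- function(x) {
  if (inherits(x, "expr_mat")) x else expr_mat(x, unit = "expression")
}

#' @export
print.circ_de <- function(x, ...) {
  cat(sprintf("<circ_de> %s; %d features (%d up, %d down)\n", x$method,
              nrow(x$table), sum(x$table$call == "up"),
              sum(x$table$call == "down")))
  invisible(x)
}
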