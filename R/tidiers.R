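#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#'
#' @param x A `circ_de` object.
#' @param ... Unused.
#' @return The per-feature tibble (`feature_id`, `log2fc`, `p`, `padj`,
#'   `call`).
#' @export
tidy.circ_de <- function(x, ...) x$table

#' @rdname tidy.circ_de
#' @return `glance()` returns a one-row summary tibble.
#' @export
glance.circ_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$table),
    n_up = sum(x$table$call == "up"),
    n_down = sum(x$table$call == "down"),
    lfc_cut = x$params$lfc_cut, p_cut = x$params$p_cut,
    adjust = x$params$adjust, method = x$method)
}

#' Tidy a GSEA result
#'
#' @param x A `circ_gsea` object.
#' @param ... Unused.
#' @return One row per leading-edge gene with the set-level statistics.
#' @export
tidy.circ_gsea <- function(x, ...) {
  if (isTRUE(x$degenerate) || length(x$leading_edge) == 0L) {
    return(tibble::tibble(set_name = character(), gene_id = character(),
                          es = numeric(), nes = numeric(), p = numeric()))
  }
  tibble::tibble(set_name = x$set_name, gene_id = x$leading_edge,
                 es = x$es, nes = x$nes, p = x$p)
}

#' @rdname tidy.circ_gsea
#' @export
glance.circ_gsea <- function(x, ...) {
  tibble::tibble(set_name = x$set_name, es = x$es, nes = x$nes, p = x$p,
                 n_perm = x$n_perm, direction = x$direction,
                 mode = x$mode %||% "gene_set",
                 n_leading_edge = length(x$leading_edge),
                 degenerate = x$degenerate)
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `circ_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.circ_de <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$p),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$lfc_cut,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(object$params$p_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#C0392B", down = "#2471A3",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (tumour / normal)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Running-sum plot of a GSEA result
#'
#' @param object A `circ_gsea` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.circ_gsea <- function(object, ...) {
  if (is.null(object$running)) abort("Degenerate result: nothing to plot.")
  run <- object$running
  ggplot2::ggplot(run, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "#2471A3") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_rug(data = run[run$hit, ], sides = "b", length =
                        ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in correlation-ordered gene list",
                  y = "running enrichment score",
                  title = sprintf("%s: ES = %.2f, p = %.3g", object$set_name,
                                  object$es, object$p)) +
    ggplot2::theme_minimal()
}

#' Compare circORF and mORF peptide length distributions
#'
#' @param circ_aa Numeric vector of circORF peptide lengths (aa).
#' @param morf_aa Numeric vector of linear main-ORF lengths (aa).
#' @return A ggplot (boxplot on a log10 axis).
#' @export
plot_orf_lengths <- function(circ_aa, morf_aa) {
  df <- dplyr::bind_rows(
    tibble::tibble(class = "circORF", aa = circ_aa),
    tibble::tibble(class = "mORF", aa = morf_aa))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$aa)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "peptide length (aa)") +
    ggplot2::theme_minimal()
}
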