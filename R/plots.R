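#' Plot ranked antigen candidates
#'
#' Binomial-tail significance against protein length, the two axes of the
#' method: genuine antigens stand out with small p at moderate length, while
#' very long proteins accumulate chance matches and are flagged
#' `LENGTH_SUSPECT`.
#'
#' @param object A `candidate_results` tibble from [rank_candidates()].
#' @param alpha Reference significance level drawn as a dashed line
#'   (default 0.001, the headline threshold for a real sequential-epitope
#'   antigen).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot candidate_results
#' @export
autoplot.candidate_results <- function(object, alpha = 0.001, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0) abort("No candidates to plot.")
  df$status <- dplyr::case_when(
    stringr::str_detect(dplyr::coalesce(df$flags, ""), "LENGTH_SUSPECT") ~ "length-suspect",
    stringr::str_detect(dplyr::coalesce(df$flags, ""), "MOTIF_COLLAPSED") ~ "motif-collapsed",
    TRUE ~ "independent matches")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_aa,
                                   y = -log10(pmax(.data$p_binomial, 1e-300)),
                                   colour = .data$status,
                                   shape = .data$panel_id)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein length (aa)",
                  y = expression(-log[10] ~ "binomial tail p"),
                  colour = NULL, shape = "panel",
                  title = "Candidate antigens: significance vs protein length") +
    ggplot2::theme_minimal()
}

#' Plot the reversed-peptide null estimate
#'
#' Per-protein length-normalized chance-match frequencies behind the
#' estimate, with the mean and its dispersion band.
#'
#' @param object A [null_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_estimate
#' @export
autoplot.null_estimate <- function(object, ...) {
  df <- object$proteins_used
  if (nrow(df) == 0) abort("Null estimate carries no per-protein frequencies.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_per_1000aa)) +
    ggplot2::geom_histogram(bins = max(10, min(40, nrow(df))),
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$f_mean, colour = "red") +
    ggplot2::geom_vline(xintercept = c(object$f_mean - object$f_sd,
                                       object$f_mean + object$f_sd),
                        colour = "red", linetype = "dotted") +
    ggplot2::labs(x = "chance matches per peptide per 1000 aa",
                  y = "proteins",
                  title = sprintf("Reversed-peptide null: f = %.3g +/- %.3g",
                                  object$f_mean, object$f_sd)) +
    ggplot2::theme_minimal()
}

#' Plot panel clonality
#'
#' Copy-number composition of each peptide panel: clonally expanded inserts
#' versus singletons.
#'
#' @param panels Panel tibble.
#' @return A ggplot object.
#' @export
plot_panel_clonality <- function(panels) {
  df <- panels %>%
    dplyr::group_by(.data$panel_id) %>%
    dplyr::arrange(dplyr::desc(.data$copy_number), .data$sequence,
                   .by_group = TRUE) %>%
    dplyr::mutate(insert = factor(dplyr::row_number())) %>%
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$insert, y = .data$copy_number)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel_id, scales = "free_x") +
    ggplot2::labs(x = "insert (ranked by clonal expansion)",
                  y = "phage copies",
                  title = "Clonal structure of biopanning panels") +
    ggplot2::theme_minimal()
}
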