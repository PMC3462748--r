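#' Plot developmental expression profiles
#'
#' Bar chart of mean per-replicate fold change with standard-deviation
#' error bars, faceted by gene — the standard developmental qPCR figure.
#'
#' @param object a `pepmine_foldchange`.
#' @param genes optional subset of genes.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.pepmine_foldchange <- function(object, genes = NULL, ...) {
  d <- object$by_stage
  if (!is.null(genes)) d <- d |> filter(.data$gene %in% genes)
  stages <- unique(object$replicates$stage)
  d$stage <- factor(d$stage, levels = stages)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$fold_mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$fold_mean - .data$fold_sd, 0),
                   ymax = .data$fold_mean + .data$fold_sd),
      width = 0.25) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "developmental stage",
                  y = "relative expression (2^-ddCt)") +
    ggplot2::theme_bw()
}

#' Plot settlement bioassay results
#'
#' Mean metamorphosis percentage per treatment group and timepoint with
#' standard-deviation error bars and significance tiers vs the control.
#'
#' @param object a `pepmine_settlement`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.pepmine_settlement <- function(object, ...) {
  d <- object$wells |>
    group_by(.data$group, .data$timepoint) |>
    summarise(mean_pct = 100 * mean(.data$prop),
              sd_pct = 100 * sd(.data$prop), .groups = "drop") |>
    left_join(object$contrasts |> select("timepoint", "group", "sig"),
              by = c("timepoint", "group")) |>
    mutate(sig = ifelse(is.na(.data$sig) | .data$sig == "ns", "", .data$sig),
           timepoint = paste0(.data$timepoint, " h"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_pct - .data$sd_pct, 0),
                   ymax = .data$mean_pct + .data$sd_pct), width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig,
                                    y = .data$mean_pct + .data$sd_pct + 3)) +
    ggplot2::facet_wrap(~timepoint) +
    ggplot2::labs(x = "treatment", y = "metamorphosis (%)") +
    ggplot2::theme_bw()
}

#' Draw a precursor feature map
#'
#' Signal peptide, cleavage sites and mature peptides of one annotated
#' precursor on a single residue axis.
#'
#' @param annotation a `pepmine_annotation`.
#' @return a ggplot object.
#' @export
plot_precursor <- function(annotation) {
  tr <- feature_track(annotation)
  if (nrow(tr) == 0) abort("nothing to plot: annotation has no features")
  tr$feature <- factor(tr$feature,
                       levels = c("signal", "cleavage_site", "peptide"))
  ggplot2::ggplot(tr) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start - 0.4, xend = .data$end + 0.4,
                   y = .data$feature, yend = .data$feature,
                   colour = .data$feature),
      linewidth = 6, show.legend = FALSE) +
    ggplot2::xlim(1, nchar(annotation$protein)) +
    ggplot2::labs(title = annotation$precursor_id,
                  x = "residue", y = NULL) +
    ggplot2::theme_minimal()
}
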