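#' Read a tidy Ct table
#'
#' Delimited text with columns gene, stage, batch, replicate, ct.
#'
#' @param path file path (tab- or comma-separated, autodetected by readr).
#' @return tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_delim(path, show_col_types = FALSE)
  validate_ct(tab)
  tab
}

validate_ct <- function(records) {
  need <- c("gene", "stage", "batch", "replicate", "ct")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("Ct table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(records$ct <= 0 | records$ct >= 50)) {
    abort("Ct values must lie in (0, 50)")
  }
  invisible(records)
}

#' Relative expression by the 2^-ddCt method
#'
#' For each gene, stage, batch and replicate: dCt = Ct_target - Ct_reference
#' measured in the same cell; ddCt = dCt - mean(dCt at the calibrator
#' stage); fold = 2^-ddCt. Per-replicate folds are retained for ANOVA; the
#' per-stage `fold` is the geometric mean 2^-mean(ddCt), so the calibrator
#' stage has fold 1 by construction. Pairing against the same-cell reference
#' measurement is the default; `pairing = "mean"` instead subtracts the mean
#' reference Ct of the (stage, batch) cell.
#'
#' @param records tidy Ct tibble (gene, stage, batch, replicate, ct).
#' @param reference_gene internal reference (housekeeping) gene label.
#' @param calibrator_stage stage whose expression defines fold = 1.
#' @param pairing `"cell"` (replicate-paired) or `"mean"`.
#' @return object of class `pepmine_foldchange`: list with `by_stage`
#'   (gene, stage, fold, fold_mean, fold_sd, n) and `replicates`
#'   (gene, stage, batch, replicate, dct, ddct, fold, log2_fold).
#' @export
ddct <- function(records, reference_gene, calibrator_stage,
                 pairing = c("cell", "mean")) {
  pairing <- match.arg(pairing)
  validate_ct(records)
  if (!reference_gene %in% records$gene) {
    abort(paste0("reference gene '", reference_gene, "' not in table"))
  }
  ref <- records |> filter(.data$gene == reference_gene)
  if (pairing == "mean") {
    ref <- ref |> group_by(.data$stage, .data$batch) |>
      summarise(ref_ct = mean(.data$ct), .groups = "drop")
    targets <- records |> filter(.data$gene != reference_gene) |>
      left_join(ref, by = c("stage", "batch"))
  } else {
    ref <- ref |> select("stage", "batch", "replicate", ref_ct = "ct")
    targets <- records |> filter(.data$gene != reference_gene) |>
      left_join(ref, by = c("stage", "batch", "replicate"))
  }
  bad <- which(is.na(targets$ref_ct))
  if (length(bad)) {
    b <- targets[bad[1], ]
    abort(paste0("no reference measurement for cell (stage=", b$stage,
                 ", batch=", b$batch, ", replicate=", b$replicate, ")"))
  }
  reps <- targets |>
    mutate(dct = .data$ct - .data$ref_ct) |>
    group_by(.data$gene) |>
    mutate(ddct = .data$dct -
             mean(.data$dct[.data$stage == calibrator_stage])) |>
    ungroup() |>
    mutate(fold = 2^(-.data$ddct), log2_fold = -.data$ddct) |>
    select("gene", "stage", "batch", "replicate", "dct", "ddct",
           "fold", "log2_fold")
  if (any(!is.finite(reps$ddct))) {
    abort(paste0("calibrator stage '", calibrator_stage,
                 "' missing for some gene"))
  }
  by_stage <- reps |>
    group_by(.data$gene, .data$stage) |>
    summarise(fold = 2^(-mean(.data$ddct)),
              fold_mean = mean(.data$fold),
              fold_sd = sd(.data$fold), n = n(), .groups = "drop")
  structure(list(by_stage = by_stage, replicates = reps,
                 reference_gene = reference_gene,
                 calibrator_stage = calibrator_stage),
            class = "pepmine_foldchange")
}

#' @export
print.pepmine_foldchange <- function(x, ...) {
  cat("2^-ddCt fold changes (reference:", x$reference_gene,
      "; calibrator:", x$calibrator_stage, ")\n")
  print(x$by_stage)
  invisible(x)
}

#' @export
tidy.pepmine_foldchange <- function(x, ...) x$by_stage

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Classical fixed-effects one-way ANOVA followed by Tukey's honestly
#' significant difference test (studentized-range distribution), with
#' per-pair significance flags at alpha 0.05 and 0.01. Degenerate input
#' (zero variance everywhere) yields an NA F statistic and no flagged
#' pairs rather than an error.
#'
#' @param data tibble holding one value column and one group column.
#' @param value,group column names (tidy-eval).
#' @return object of class `pepmine_anova`: `f`, `df1`, `df2`, `p_value`,
#'   `tukey` tibble (pair, diff, conf.low, conf.high, p_adj, sig_05,
#'   sig_01), `degenerate`.
#' @export
anova_tukey <- function(data, value, group) {
  d <- tibble(value = dplyr::pull(data, {{ value }}),
              group = as.character(dplyr::pull(data, {{ group }})))
  counts <- table(d$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("anova_tukey needs >= 2 groups with >= 2 replicates each")
  }
  d$group <- factor(d$group)
  pairs_of <- function(levs) {
    cmb <- utils::combn(levs, 2)
    paste(cmb[2, ], cmb[1, ], sep = "-")
  }
  if (stats::var(d$value) == 0) {
    levs <- levels(d$group)
    tk <- tibble(pair = pairs_of(levs), diff = 0, conf.low = 0,
                 conf.high = 0, p_adj = NA_real_,
                 sig_05 = FALSE, sig_01 = FALSE)
    return(structure(list(f = NA_real_, df1 = length(levs) - 1L,
                          df2 = nrow(d) - length(levs),
                          p_value = NA_real_, tukey = tk,
                          degenerate = TRUE, fit = NULL),
                     class = "pepmine_anova"))
  }
  fit <- aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk_raw <- TukeyHSD(fit)$group
  tk <- tibble(pair = rownames(tk_raw), diff = tk_raw[, "diff"],
               conf.low = tk_raw[, "lwr"], conf.high = tk_raw[, "upr"],
               p_adj = tk_raw[, "p adj"]) |>
    mutate(sig_05 = .data$p_adj < 0.05, sig_01 = .data$p_adj < 0.01)
  structure(list(f = an[["F value"]][1], df1 = an[["Df"]][1],
                 df2 = an[["Df"]][2], p_value = an[["Pr(>F)"]][1],
                 tukey = tk, degenerate = FALSE, fit = fit),
            class = "pepmine_anova")
}

#' @export
print.pepmine_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s\n", x$df1, x$df2,
              format(x$f, digits = 4), format(x$p_value, digits = 4)))
  print(x$tukey)
  invisible(x)
}

#' @export
tidy.pepmine_anova <- function(x, ...) x$tukey

#' @export
glance.pepmine_anova <- function(x, ...) {
  tibble(statistic = x$f, df = x$df1, df.residual = x$df2,
         p.value = x$p_value, degenerate = x$degenerate)
}

#' Developmental-profile ANOVA for one gene
#'
#' Runs [anova_tukey()] across stages on the per-replicate log2 fold
#' changes (-ddCt) of a [ddct()] result — the log scale restores variance
#' homogeneity under Gaussian Ct noise. `scale = "fold"` uses raw folds.
#'
#' @param fc a `pepmine_foldchange`.
#' @param gene gene label.
#' @param scale `"log2"` (default) or `"fold"`.
#' @return a `pepmine_anova`.
#' @export
qpcr_anova <- function(fc, gene, scale = c("log2", "fold")) {
  scale <- match.arg(scale)
  d <- fc$replicates |> filter(.data$gene == !!gene)
  if (nrow(d) == 0) abort(paste0("gene '", gene, "' not in fold changes"))
  col <- if (scale == "log2") "log2_fold" else "fold"
  anova_tukey(d, !!rlang::sym(col), "stage")
}

#' Arcsine square-root transform of a proportion
#'
#' y = arcsin(sqrt(p)); strictly monotone on [0, 1], 0 at p = 0 and pi/2
#' at p = 1.
#'
#' @param p proportion(s) in [0, 1].
#' @return transformed values.
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1)) abort("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Settlement (metamorphosis) bioassay analysis
#'
#' Per timepoint: metamorphosis proportions per well are arcsine-square-root
#' transformed and compared across treatment groups (seawater control, DMSO
#' vehicle control and the dose series) by one-way ANOVA with Tukey HSD.
#' Contrasts against the seawater control are reported with significance
#' tiers (`ns`, `*` p<0.05, `**` p<0.01, `***` p<0.001).
#'
#' @param wells tibble with columns dose (0 for controls), vehicle
#'   (e.g. "AFSW", "DMSO"), timepoint (hours), batch, well, n_meta, n_total.
#' @param control group label of the reference control (default "AFSW").
#' @return object of class `pepmine_settlement`: `wells` (with group and
#'   transformed proportion), `fits` (named list of `pepmine_anova` per
#'   timepoint), `contrasts` tibble (timepoint, group, diff, p_adj, sig,
#'   significant).
#' @export
settlement_analysis <- function(wells, control = "AFSW") {
  need <- c("dose", "vehicle", "timepoint", "n_meta", "n_total")
  missing <- setdiff(need, names(wells))
  if (length(missing)) {
    abort(paste0("well table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(wells$n_total <= 0)) abort("wells with n_total = 0 are invalid")
  if (any(wells$n_meta > wells$n_total | wells$n_meta < 0)) {
    abort("n_meta must lie in [0, n_total]")
  }
  w <- wells |>
    mutate(group = ifelse(.data$dose == 0, .data$vehicle,
                          paste0(.data$dose, "uM")),
           prop = .data$n_meta / .data$n_total,
           y = arcsine_transform(.data$prop))
  fits <- list()
  contrasts <- list()
  for (tp in sort(unique(w$timepoint))) {
    d <- w |> filter(.data$timepoint == tp)
    fit <- anova_tukey(d, "y", "group")
    fits[[as.character(tp)]] <- fit
    vs <- fit$tukey |>
      filter(grepl(paste0("(^", control, "-)|(-", control, "$)"),
                   .data$pair)) |>
      mutate(group = sub(paste0("^", control, "-"), "",
                         sub(paste0("-", control, "$"), "", .data$pair)),
             timepoint = tp,
             sig = dplyr::case_when(
               is.na(.data$p_adj) ~ "ns",
               .data$p_adj < 0.001 ~ "***",
               .data$p_adj < 0.01 ~ "**",
               .data$p_adj < 0.05 ~ "*",
               TRUE ~ "ns"),
             significant = !is.na(.data$p_adj) & .data$p_adj < 0.05) |>
      select("timepoint", "group", "diff", "p_adj", "sig", "significant")
    contrasts[[as.character(tp)]] <- vs
  }
  structure(list(wells = w, fits = fits,
                 contrasts = list_rbind(contrasts), control = control),
            class = "pepmine_settlement")
}

#' @export
print.pepmine_settlement <- function(x, ...) {
  cat("Settlement bioassay vs", x$control, "control\n")
  print(x$contrasts)
  invisible(x)
}

#' @export
tidy.pepmine_settlement <- function(x, ...) x$contrasts

#' @export
glance.pepmine_settlement <- function(x, ...) {
  list_rbind(imap(x$fits, function(f, tp) {
    glance(f) |> mutate(timepoint = as.numeric(tp), .before = 1)
  }))
}
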