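make_ct <- function(targets, ref = 15) {
  # targets: tibble(gene, stage, ct); expands to batch 1, replicate 1 and
  # adds the matching reference rows
  dplyr::bind_rows(
    targets |> dplyr::mutate(batch = 1L, replicate = 1L),
    targets |> dplyr::distinct(stage) |>
      dplyr::mutate(gene = "cytb", ct = ref, batch = 1L, replicate = 1L)
  )
}

test_that("ddCt arithmetic is forced by its definition", {
  tab <- make_ct(tibble::tibble(gene = "g",
                                stage = c("Cyp", "Juv"), ct = c(18, 20)))
  fc <- ddct(tab, "cytb", "Juv")
  # dCt 3 vs 5, ddCt = -2, fold = 4; calibrator fold 1 by construction
  expect_equal(fc$by_stage$fold[fc$by_stage$stage == "Cyp"], 4)
  expect_equal(fc$by_stage$fold[fc$by_stage$stage == "Juv"], 1)

  # identical Ct patterns everywhere: all folds 1
  tab2 <- make_ct(tibble::tibble(gene = "g", stage = c("A", "B", "C"),
                                 ct = 18))
  expect_true(all(ddct(tab2, "cytb", "B")$by_stage$fold == 1))
})

test_that("ddCt is invariant to per-batch shifts and inverts on swap", {
  tab <- generate_ct_table(seed = 4)
  fc0 <- ddct(tab, "cytb", "Juv")
  shifted <- tab |>
    dplyr::mutate(ct = ct + ifelse(batch == 2, 1.7, 0))
  fc1 <- ddct(shifted, "cytb", "Juv")
  expect_equal(fc1$by_stage$fold, fc0$by_stage$fold)

  # swapping target and reference inverts the fold
  two <- tab |> dplyr::filter(gene %in% c("cytb", "sif"))
  a <- ddct(two, "cytb", "Juv")
  b <- ddct(two, "sif", "Juv")
  fa <- a$by_stage |> dplyr::arrange(stage)
  fb <- b$by_stage |> dplyr::arrange(stage)
  expect_equal(fa$fold, 1 / fb$fold)
})

test_that("a missing reference cell is a named data error", {
  tab <- make_ct(tibble::tibble(gene = "g", stage = c("Cyp", "Juv"),
                                ct = c(18, 20)))
  tab <- tab[!(tab$gene == "cytb" & tab$stage == "Cyp"), ]
  expect_error(ddct(tab, "cytb", "Juv"), "stage=Cyp")
  expect_error(ddct(tab, "nope", "Juv"), "not in table")
  expect_error(ddct(dplyr::mutate(tab, ct = 60), "cytb", "Juv"), "\\(0, 50\\)")
})

test_that("one-way ANOVA and Tukey match a sums-of-squares oracle", {
  # classic 3 x 5 fixture
  d <- tibble::tibble(
    value = c(22, 25, 24, 26, 23,
              28, 30, 29, 31, 27,
              18, 20, 19, 21, 17),
    group = rep(c("a", "b", "c"), each = 5)
  )
  fit <- anova_tukey(d, "value", "group")
  # oracle: compute F from sums of squares directly
  gm <- mean(d$value)
  ssb <- sum(tapply(d$value, d$group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(d$value, d$group, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(fit$f, f_oracle)
  expect_equal(fit$df1, 2L)
  expect_equal(fit$df2, 12L)
  # Tukey p for b-a from the studentized range distribution
  mse <- ssw / 12
  qstat <- abs(mean(d$value[d$group == "b"]) - mean(d$value[d$group == "a"])) /
    sqrt(mse / 5)
  p_oracle <- stats::ptukey(qstat, nmeans = 3, df = 12, lower.tail = FALSE)
  got <- fit$tukey$p_adj[fit$tukey$pair == "b-a"]
  expect_equal(unname(got), p_oracle, tolerance = 1e-8)
  # flags nest: every alpha=0.01 flag is an alpha=0.05 flag
  expect_true(all(!fit$tukey$sig_01 | fit$tukey$sig_05))
})

test_that("degenerate and undersized inputs are handled explicitly", {
  same <- tibble::tibble(value = rep(5, 9), group = rep(c("a", "b", "c"), 3))
  fit <- anova_tukey(same, "value", "group")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$f))
  expect_false(any(fit$tukey$sig_05))
  expect_error(anova_tukey(same[1:3, ], "value", "group"), ">= 2")
})

test_that("group relabelling does not change which pairs are flagged", {
  set.seed(12)
  d <- tibble::tibble(value = c(rnorm(5, 0), rnorm(5, 3), rnorm(5, 0.2)),
                      group = rep(c("a", "b", "c"), each = 5))
  f1 <- anova_tukey(d, "value", "group")
  d2 <- d |> dplyr::mutate(group = chartr("abc", "zyx", group))
  f2 <- anova_tukey(d2, "value", "group")
  key1 <- with(f1$tukey, setNames(sig_05, pair))
  # pair z-y corresponds to a-b etc.; compare via sorted significance counts
  expect_equal(sort(unname(key1)), sort(unname(with(f2$tukey,
                                                    setNames(sig_05, pair)))))
  expect_equal(f1$f, f2$f)
})

test_that("the arcsine transform hits its closed-form endpoints", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
})

test_that("settlement analysis finds no effect in flat data and validates input", {
  wells <- generate_settlement_counts(
    tibble::tibble(dose = c(0, 0, 1, 10, 100),
                   vehicle = c("AFSW", "DMSO", rep("DMSO", 3)),
                   p24 = 0.6, p48 = 0.6),
    seed = 8)
  res <- settlement_analysis(wells)
  expect_false(any(res$contrasts$significant))
  expect_true(all(res$contrasts$sig == "ns"))

  bad <- wells |> dplyr::mutate(n_total = 0L)
  expect_error(settlement_analysis(bad), "n_total")
  expect_error(settlement_analysis(wells[, -1]), "lacks column")
})

test_that("dose-dependent inhibition is detected at 24 h and gone at 48 h", {
  wells <- generate_settlement_counts(seed = 21)
  res <- settlement_analysis(wells)
  c24 <- res$contrasts |> dplyr::filter(timepoint == 24)
  c48 <- res$contrasts |> dplyr::filter(timepoint == 48)
  expect_true(c24$significant[c24$group == "10uM"])
  expect_true(c24$significant[c24$group == "100uM"])
  expect_false(c24$significant[c24$group == "1uM"])
  expect_false(any(c48$significant))
  # tidy/glance accessors expose the same results
  expect_equal(generics::tidy(res), res$contrasts)
  expect_equal(nrow(generics::glance(res)), 2)
})

test_that("qpcr_anova separates a planted cyprid effect", {
  tab <- generate_ct_table(noise_sd = 0.3, seed = 31)
  fc <- ddct(tab, "cytb", "Juv")
  an <- qpcr_anova(fc, "sif")
  cyp_juv <- an$tukey |>
    dplyr::filter(pair %in% c("Juv-Cyp", "Cyp-Juv"))
  expect_true(cyp_juv$sig_05)
  flat <- qpcr_anova(fc, "npf")
  adu <- flat$tukey |> dplyr::filter(pair %in% c("Juv-Adu", "Adu-Juv"))
  expect_true(nrow(adu) == 1)
})
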