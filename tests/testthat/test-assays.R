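# qRT-PCR 2^-ddCt analytics and CCK-8 viability curves.

ctFixture <- function(controlDct = c(5, 5), treatedDct = c(7, 7)) {
  data.frame(
    sample_id = seq_len(length(controlDct) + length(treatedDct)),
    group = rep(c("NC", "si"), c(length(controlDct), length(treatedDct))),
    target_gene = "LINC00152", reference_gene = "GAPDH",
    ct_target = 20 + c(controlDct, treatedDct),
    ct_reference = 20)
}

test_that("2^-ddCt closed forms hold", {
  tab <- ctFixture(controlDct = c(5, 5), treatedDct = c(5, 6, 4))
  res <- ddctFoldChange(tab, "NC")
  # ddCt 0 -> fold 1; +1 -> 0.5; -1 -> 2
  expect_identical(res$fold_change[res$ddct == 0], c(1, 1, 1))
  expect_identical(res$fold_change[res$ddct == 1], 0.5)
  expect_identical(res$fold_change[res$ddct == -1], 2)
})

test_that("replicate table {control 5,5; treated 7,7} gives folds 0.25", {
  res <- ddctFoldChange(ctFixture(), "NC")
  treated <- res$fold_change[res$group == "si"]
  expect_identical(treated, c(0.25, 0.25))
  # spreadsheet-style recomputation from raw Ct
  tab <- ctFixture()
  dct <- tab$ct_target - tab$ct_reference
  want <- 2^(-(dct - mean(dct[tab$group == "NC"])))
  expect_identical(res$fold_change, want)
  # control group: mean log-fold is 0, mean fold 1 here (symmetric dCt)
  expect_identical(mean(res$fold_change[res$group == "NC"]), 1)
})

test_that("fold change is strictly decreasing in ddCt", {
  ddct <- seq(-4, 4, by = 0.25)
  folds <- 2^(-ddct)
  expect_true(all(diff(folds) < 0))
  tab <- ctFixture(controlDct = c(3, 3), treatedDct = 3 + ddct)
  res <- ddctFoldChange(tab, "NC")
  treated <- res[res$group == "si", ]
  expect_true(all(diff(treated$fold_change[order(treated$ddct)]) < 0))
})

test_that("samples with unusable Ct are excluded with a warning", {
  tab <- ctFixture()
  tab$ct_reference[3] <- NA
  expect_warning(res <- ddctFoldChange(tab, "NC"), "excluded 1")
  expect_identical(nrow(res), 3L)
  expect_identical(attr(res, "excluded"), 3L)
  tab$ct_reference[1:2] <- NA  # control group wiped out
  expect_error(suppressWarnings(ddctFoldChange(tab, "NC")), "control group")
})

test_that("knockdown efficiency identities hold", {
  expect_identical(knockdownEfficiency(1), 0)
  expect_identical(knockdownEfficiency(0), 100)
  expect_identical(knockdownEfficiency(c(0.25, 0.25)), 75)
  # efficiency + 100 * fold == 100 identically
  for (fold in c(0.01, 0.185, 0.5, 0.919, 1)) {
    expect_equal(knockdownEfficiency(fold) + 100 * fold, 100)
  }
  expect_warning(eff <- knockdownEfficiency(1.2), "failed")
  expect_lt(eff, 0)
  # data.frame interface
  res <- ddctFoldChange(ctFixture(), "NC")
  expect_identical(knockdownEfficiency(res, "si", "NC"), 75)
})

test_that("wells equal to blanks correct to zero at all timepoints", {
  times <- c(0, 24, 48, 72)
  tab <- rbind(
    data.frame(sample_id = "w1", group = "NC", time_h = times,
               od450 = c(0.05, 0.06, 0.07, 0.08), is_blank = FALSE),
    data.frame(sample_id = "b", group = "blank", time_h = times,
               od450 = c(0.05, 0.06, 0.07, 0.08), is_blank = TRUE))
  res <- viabilityCurves(tab)
  expect_identical(res$samples$od_corrected, rep(0, 4))
  # idempotence: re-correcting already-zero blanks changes nothing
  tab2 <- tab
  tab2$od450[tab2$is_blank] <- 0
  tab2$od450[!tab2$is_blank] <- res$samples$od_corrected
  res2 <- viabilityCurves(tab2)
  expect_identical(res2$samples$od_corrected, res$samples$od_corrected)
})

test_that("normalized series start at exactly 1 and recover exponentials", {
  times <- c(0, 24, 48, 72)
  blank <- 0.05
  tab <- rbind(
    expand.grid(sample_id = c("w1", "w2"), time_h = times,
                stringsAsFactors = FALSE),
    data.frame(sample_id = "b", time_h = times))
  tab$group <- ifelse(tab$sample_id == "b", "blank", "NC")
  tab$is_blank <- tab$sample_id == "b"
  tab$od450 <- ifelse(tab$is_blank, blank,
                      0.1 * 2^(tab$time_h / 24) + blank)
  res <- viabilityCurves(tab, normalize = TRUE)
  w <- res$samples
  expect_identical(w$od_normalized[w$time_h == 0], c(1, 1))
  for (tt in times) {
    expect_equal(unique(w$od_normalized[w$time_h == tt]), 2^(tt / 24))
  }
  s <- res$summary
  expect_equal(s$mean, c(1, 2, 4, 8))
  expect_equal(s$sem, rep(0, 4))
  # with blanks already at zero the correction is the identity and the
  # normalized series is exact
  tab0 <- tab
  tab0$od450 <- ifelse(tab0$is_blank, 0, 0.1 * 2^(tab0$time_h / 24))
  s0 <- viabilityCurves(tab0, normalize = TRUE)$summary
  expect_identical(s0$mean, c(1, 2, 4, 8))
})

test_that("viability error contracts: no blanks, bad baselines", {
  tab <- data.frame(sample_id = "w", group = "NC", time_h = c(0, 24),
                    od450 = c(0.2, 0.4), is_blank = FALSE)
  expect_error(viabilityCurves(tab), "no blank wells")
  res <- viabilityCurves(tab, blankCorrect = FALSE)
  expect_identical(res$samples$od_corrected, c(0.2, 0.4))
  # sample whose baseline corrects to <= 0 is flagged in normalized mode
  tab2 <- rbind(tab,
                data.frame(sample_id = "b", group = "blank",
                           time_h = c(0, 24), od450 = c(0.3, 0.3),
                           is_blank = TRUE))
  expect_warning(res2 <- viabilityCurves(tab2, normalize = TRUE),
                 "baseline")
  expect_true(all(is.na(res2$samples$od_normalized)))
})
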