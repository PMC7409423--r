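# In-vitro assay analytics: 2^-ddCt relative expression and CCK-8
# viability time courses.

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(reference); ddCt = dCt - mean(dCt of
#' the control group); fold change = 2^(-ddCt). Because the control group is
#' referenced to its own mean dCt, the control fold changes average 1 on the
#' log scale by construction. Samples with a missing target or reference Ct
#' are flagged, excluded and reported via a warning.
#'
#' @param ctTable data.frame with columns sample_id, group, ct_target,
#'   ct_reference (extra columns such as target_gene, reference_gene,
#'   replicate are carried through).
#' @param controlGroup name of the reference group; must be present.
#' @return the input table with columns dct, ddct and fold_change appended
#'   (excluded rows are dropped; their ids are in attribute "excluded").
#' @examples
#' ct <- data.frame(sample_id = 1:4, group = c("NC", "NC", "si", "si"),
#'                  ct_target = c(25, 25, 27, 27), ct_reference = 20)
#' ddctFoldChange(ct, "NC")$fold_change
#' @export
ddctFoldChange <- function(ctTable, controlGroup) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(ctTable)))
    stop("ctTable must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(ctTable$ct_target) | !is.finite(ctTable$ct_reference) |
    ctTable$ct_target <= 0 | ctTable$ct_reference <= 0
  excluded <- ctTable$sample_id[bad]
  if (length(excluded))
    warning("excluded ", length(excluded),
            " sample(s) with missing/invalid Ct: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  tab <- ctTable[!bad, , drop = FALSE]
  if (!controlGroup %in% tab$group)
    stop("control group '", controlGroup, "' has no usable samples",
         call. = FALSE)
  tab$dct <- tab$ct_target - tab$ct_reference
  controlDct <- mean(tab$dct[tab$group == controlGroup])
  tab$ddct <- tab$dct - controlDct
  tab$fold_change <- 2^(-tab$ddct)
  attr(tab, "excluded") <- excluded
  attr(tab, "control_group") <- controlGroup
  tab
}

#' Knockdown efficiency in percent
#'
#' efficiency = (1 - mean fold change of the treated group) x 100. With
#' fold changes already expressed relative to the control group (see
#' [ddctFoldChange()]), a mean treated fold of 0.25 gives 75% knockdown.
#' A mean treated fold above 1 yields a negative efficiency and a warning
#' (the knockdown failed).
#'
#' @param foldChanges data.frame from [ddctFoldChange()] (columns group,
#'   fold_change), or a numeric vector of treated-group fold changes.
#' @param treatedGroup,controlGroup group names; `controlGroup` is only
#'   checked for presence when `foldChanges` is a data.frame.
#' @return efficiency in percent.
#' @examples
#' knockdownEfficiency(c(0.25, 0.25))  # 75
#' @export
knockdownEfficiency <- function(foldChanges, treatedGroup = NULL,
                                controlGroup = NULL) {
  folds <- if (is.data.frame(foldChanges)) {
    if (!is.null(controlGroup) && !controlGroup %in% foldChanges$group)
      stop("control group '", controlGroup, "' absent", call. = FALSE)
    if (is.null(treatedGroup) || !treatedGroup %in% foldChanges$group)
      stop("treated group absent from fold-change table", call. = FALSE)
    foldChanges$fold_change[foldChanges$group == treatedGroup]
  } else as.numeric(foldChanges)
  eff <- (1 - mean(folds)) * 100
  if (eff < 0)
    warning("mean treated fold change exceeds 1: knockdown failed ",
            "(negative efficiency)", call. = FALSE)
  eff
}

#' Summarise CCK-8 viability time courses
#'
#' Blank-corrects each well by the mean blank OD450 at the same timepoint,
#' then summarises each group per timepoint as mean +/- SEM of the corrected
#' values. In normalized mode each sample's series is divided by its own
#' corrected value at the earliest timepoint, so every series starts at 1;
#' samples whose baseline corrected OD is <= 0 are flagged and excluded from
#' normalized summaries.
#'
#' @param viabilityTable data.frame with columns sample_id, group, time_h,
#'   od450 and logical is_blank.
#' @param blankCorrect subtract the per-timepoint mean blank OD (default
#'   TRUE; requires at least one blank well).
#' @param normalize divide each sample's corrected series by its value at
#'   the earliest timepoint.
#' @return list with `samples` (per-well corrected, and normalized when
#'   requested, values) and `summary` (group x time_h: n, mean, sem).
#' @examples
#' tab <- expand.grid(sample_id = c("a", "b"), time_h = c(0, 24, 48, 72))
#' tab$group <- "NC"; tab$is_blank <- FALSE
#' tab$od450 <- 0.1 * 2^(tab$time_h / 24) + 0.05
#' blank <- data.frame(sample_id = "blank", time_h = c(0, 24, 48, 72),
#'                     group = "blank", is_blank = TRUE, od450 = 0.05)
#' viabilityCurves(rbind(tab, blank), normalize = TRUE)$summary
#' @export
viabilityCurves <- function(viabilityTable, blankCorrect = TRUE,
                            normalize = FALSE) {
  need <- c("sample_id", "group", "time_h", "od450", "is_blank")
  if (!all(need %in% names(viabilityTable)))
    stop("viabilityTable must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- viabilityTable
  if (any(tab$time_h < 0)) stop("time_h must be non-negative", call. = FALSE)

  if (blankCorrect) {
    blanks <- tab[tab$is_blank, , drop = FALSE]
    if (!nrow(blanks))
      stop("blank correction requested but no blank wells present",
           call. = FALSE)
    blankMean <- tapply(blanks$od450, blanks$time_h, mean)
    corr <- blankMean[as.character(tab$time_h)]
    corr[is.na(corr)] <- mean(blanks$od450)  # timepoint without its own blank
    tab$od_corrected <- tab$od450 - as.numeric(corr)
  } else {
    tab$od_corrected <- tab$od450
  }
  wells <- tab[!tab$is_blank, , drop = FALSE]

  if (normalize) {
    t0 <- min(wells$time_h)
    base <- wells[wells$time_h == t0, c("sample_id", "od_corrected")]
    baseline <- stats::setNames(base$od_corrected, base$sample_id)
    wells$od_normalized <- wells$od_corrected /
      baseline[as.character(wells$sample_id)]
    badSamples <- names(baseline)[baseline <= 0]
    if (length(badSamples)) {
      warning("baseline corrected OD <= 0 for sample(s): ",
              paste(badSamples, collapse = ", "),
              "; excluded from normalized summaries", call. = FALSE)
      wells$od_normalized[wells$sample_id %in% badSamples] <- NA_real_
    }
  }

  value <- if (normalize) wells$od_normalized else wells$od_corrected
  keep <- !is.na(value)
  summary <- do.call(rbind, lapply(
    split(seq_len(nrow(wells))[keep],
          interaction(wells$group[keep], wells$time_h[keep], drop = TRUE)),
    function(ii) data.frame(
      group = wells$group[ii[1]], time_h = wells$time_h[ii[1]],
      n = length(ii), mean = mean(value[ii]),
      sem = if (length(ii) > 1) stats::sd(value[ii]) / sqrt(length(ii))
            else NA_real_)))
  if (is.null(summary))
    summary <- data.frame(group = character(0), time_h = numeric(0),
                          n = integer(0), mean = numeric(0), sem = numeric(0))
  summary <- summary[order(summary$group, summary$time_h), , drop = FALSE]
  rownames(summary) <- NULL
  list(samples = wells, summary = summary)
}
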