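# Group-comparison statistics: unpaired Student's t (pooled variance),
# mean +/- SEM summaries, significance stars, and the 2x2
# knockdown-by-drug combination analysis.

#' Significance stars
#'
#' `p < 0.05` -> "*", `p < 0.01` -> "**", `p < 0.001` -> "***", otherwise
#' "ns".
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector.
#' @export
significanceStars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("ns", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Unpaired Student's t-test (pooled variance)
#'
#' Implements the equal-variance two-sample t statistic from its closed
#' form: t = (mean(a) - mean(b)) / sqrt(sp2 (1/na + 1/nb)) with the pooled
#' variance sp2 on na + nb - 2 degrees of freedom, and a two-sided p-value
#' from the t distribution. `welch = TRUE` switches to the
#' Welch-Satterthwaite unequal-variance form.
#'
#' Degenerate input (zero pooled variance) returns t = 0, p = 1 when the
#' means are equal and raises an error when they differ (the statistic is
#' undefined).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the unequal-variance form (default FALSE, matching the
#'   classical unpaired Student's t).
#' @return data.frame: group_a_mean, group_b_mean, t_statistic,
#'   degrees_of_freedom, p_value, stars.
#' @examples
#' studentsTTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
studentsTTest <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("both groups need at least 2 observations", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (ma == mb)
        return(data.frame(group_a_mean = ma, group_b_mean = mb,
                          t_statistic = 0,
                          degrees_of_freedom = as.numeric(na + nb - 2),
                          p_value = 1, stars = "ns"))
      stop("zero variance with unequal means: t statistic undefined",
           call. = FALSE)
    }
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    df <- as.numeric(na + nb - 2)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    if (sp2 == 0) {
      if (ma == mb)
        return(data.frame(group_a_mean = ma, group_b_mean = mb,
                          t_statistic = 0, degrees_of_freedom = df,
                          p_value = 1, stars = "ns"))
      stop("zero pooled variance with unequal means: t statistic undefined",
           call. = FALSE)
    }
    tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(group_a_mean = ma, group_b_mean = mb, t_statistic = tstat,
             degrees_of_freedom = df, p_value = p,
             stars = significanceStars(p))
}

#' Per-group mean +/- SEM summaries
#'
#' @param metricsTable data.frame of per-sample metrics.
#' @param metric column name to summarise; missing values are dropped (their
#'   count is reported in `n_missing`).
#' @param groupCol grouping column (default "group_label").
#' @return data.frame: group, n, n_missing, mean, sem (sem is NA when
#'   n <= 1; mean is NA when n == 0).
#' @examples
#' d <- data.frame(group_label = rep(c("NC", "si"), each = 3),
#'                 yolk_area_um2 = c(5, 6, 7, 3, 4, 5))
#' summarizeGroups(d, "yolk_area_um2")
#' @export
summarizeGroups <- function(metricsTable, metric, groupCol = "group_label") {
  if (!metric %in% names(metricsTable))
    stop("unknown metric '", metric, "'", call. = FALSE)
  if (!groupCol %in% names(metricsTable))
    stop("unknown grouping column '", groupCol, "'", call. = FALSE)
  groups <- unique(metricsTable[[groupCol]])
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- metricsTable[[metric]][metricsTable[[groupCol]] == g]
    miss <- sum(is.na(v))
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(group = g, n = n, n_missing = miss,
               mean = if (n) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise comparison of every group against a control
#'
#' Convenience wrapper running [studentsTTest()] of each non-control group
#' against the control on one metric.
#'
#' @inheritParams summarizeGroups
#' @param controlGroup name of the reference group.
#' @param welch passed to [studentsTTest()].
#' @return data.frame with one row per comparison.
#' @export
compareGroups <- function(metricsTable, metric, controlGroup,
                          groupCol = "group_label", welch = FALSE) {
  if (!controlGroup %in% metricsTable[[groupCol]])
    stop("control group '", controlGroup, "' absent", call. = FALSE)
  others <- setdiff(unique(metricsTable[[groupCol]]), controlGroup)
  ctrl <- metricsTable[[metric]][metricsTable[[groupCol]] == controlGroup]
  out <- do.call(rbind, lapply(others, function(g) {
    res <- studentsTTest(metricsTable[[metric]][metricsTable[[groupCol]] == g],
                         ctrl, welch = welch)
    cbind(data.frame(metric = metric, group_a = g,
                     group_b = controlGroup), res)
  }))
  rownames(out) <- NULL
  out
}

#' 2x2 knockdown-by-drug combination analysis
#'
#' For a factorial design with knockdown in {control, knockdown} and drug in
#' {vehicle, drug}, runs the uncorrected pairwise Student's t comparisons
#' used for such designs -- each treated cell against the double control,
#' and the combination against each single treatment -- plus an exploratory
#' additive-scale interaction estimate
#' mean(kd,drug) - mean(kd,vehicle) - mean(ctrl,drug) + mean(ctrl,vehicle)
#' with a pooled-variance standard error on N - 4 degrees of freedom. A
#' negative interaction means the combination suppresses the metric more
#' than the sum of the single effects.
#'
#' @param table data.frame holding the metric and two factor columns.
#' @param metric metric column name.
#' @param knockdownCol,drugCol factor column names (default "knockdown",
#'   "drug").
#' @param controlLevels character(2): the reference level of each factor
#'   (default c("NC", "vehicle")).
#' @return list with `pairwise` (data.frame of comparisons) and
#'   `interaction` (estimate, se, t, df, p, labelled exploratory).
#' @examples
#' d <- expand.grid(knockdown = c("NC", "si"), drug = c("vehicle", "afatinib"),
#'                  rep = 1:5)
#' d$area <- c(NC.vehicle = 10, si.vehicle = 6, NC.afatinib = 6,
#'             si.afatinib = 2)[paste(d$knockdown, d$drug, sep = ".")] +
#'           rep(c(-0.2, -0.1, 0, 0.1, 0.2), each = 4)
#' combinationContrast(d, "area")
#' @export
combinationContrast <- function(table, metric, knockdownCol = "knockdown",
                                drugCol = "drug",
                                controlLevels = c("NC", "vehicle")) {
  for (col in c(metric, knockdownCol, drugCol))
    if (!col %in% names(table)) stop("missing column '", col, "'", call. = FALSE)
  kd <- as.character(table[[knockdownCol]])
  dr <- as.character(table[[drugCol]])
  kdLevels <- c(controlLevels[1], setdiff(unique(kd), controlLevels[1]))
  drLevels <- c(controlLevels[2], setdiff(unique(dr), controlLevels[2]))
  if (length(kdLevels) != 2L || length(drLevels) != 2L)
    stop("both factors must have exactly two levels", call. = FALSE)

  cellValues <- function(k, d) {
    v <- table[[metric]][kd == k & dr == d]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop("design cell (", k, ", ", d, ") needs >= 2 observations",
           call. = FALSE)
    v
  }
  v00 <- cellValues(kdLevels[1], drLevels[1])  # control / vehicle
  v01 <- cellValues(kdLevels[1], drLevels[2])  # control / drug
  v10 <- cellValues(kdLevels[2], drLevels[1])  # knockdown / vehicle
  v11 <- cellValues(kdLevels[2], drLevels[2])  # knockdown / drug

  lab <- function(k, d) paste(k, d, sep = "+")
  comparisons <- list(
    c(lab(kdLevels[1], drLevels[2]), lab(kdLevels[1], drLevels[1])),
    c(lab(kdLevels[2], drLevels[1]), lab(kdLevels[1], drLevels[1])),
    c(lab(kdLevels[2], drLevels[2]), lab(kdLevels[1], drLevels[1])),
    c(lab(kdLevels[2], drLevels[2]), lab(kdLevels[1], drLevels[2])),
    c(lab(kdLevels[2], drLevels[2]), lab(kdLevels[2], drLevels[1]))
  )
  cells <- stats::setNames(list(v00, v01, v10, v11),
                           c(lab(kdLevels[1], drLevels[1]),
                             lab(kdLevels[1], drLevels[2]),
                             lab(kdLevels[2], drLevels[1]),
                             lab(kdLevels[2], drLevels[2])))
  pairwise <- do.call(rbind, lapply(comparisons, function(cmp) {
    res <- studentsTTest(cells[[cmp[1]]], cells[[cmp[2]]])
    cbind(data.frame(group_a = cmp[1], group_b = cmp[2]), res)
  }))
  rownames(pairwise) <- NULL

  ns <- vapply(cells, length, integer(1))
  sp2 <- sum(vapply(cells, function(v) (length(v) - 1) * stats::var(v),
                    numeric(1))) / (sum(ns) - 4)
  est <- mean(v11) - mean(v10) - mean(v01) + mean(v00)
  se <- sqrt(sp2 * sum(1 / ns))
  df <- sum(ns) - 4
  tstat <- if (se > 0) est / se else ifelse(est == 0, 0, NA_real_)
  p <- if (!is.na(tstat)) 2 * stats::pt(-abs(tstat), df) else NA_real_
  list(pairwise = pairwise,
       interaction = data.frame(estimate = est, se = se, t_statistic = tstat,
                                degrees_of_freedom = df, p_value = p,
                                note = "exploratory additive-scale interaction"))
}
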