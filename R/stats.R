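#' Aggregate measurements into a condition summary
#'
#' Mean and standard error of the permeability coefficients of one condition
#' and probe, excluding focal-leak-flagged and failed measurements by
#' default. A single surviving point reports SEM 0 with a warning instead of
#' erroring, to keep batch runs alive.
#'
#' @param measurements data.frame from [measureDevice()] /
#'   [simulateCondition()], or a bare numeric vector of permeabilities.
#' @param condition,probe labels carried into the summary.
#' @param excludeLeaks drop focal-leak-flagged points (default TRUE).
#' @return One-row data.frame: \code{condition}, \code{probe}, \code{n},
#'   \code{n_excluded}, \code{mean_Pd}, \code{sem_Pd}.
#' @examples
#' aggregateCondition(c(1, 2, 3) * 1e-5, condition = "untreated",
#'                    probe = "10 kDa dextran")
#' @export
aggregateCondition <- function(measurements, condition = "condition",
                               probe = "probe", excludeLeaks = TRUE) {
  if (is.numeric(measurements)) {
    pd <- measurements
    nExcl <- 0L
  } else {
    keep <- is.na(measurements$error) & is.finite(measurements$Pd_cm_s)
    if (excludeLeaks) keep <- keep & !measurements$focal_leak
    pd <- measurements$Pd_cm_s[keep]
    nExcl <- nrow(measurements) - sum(keep)
  }
  if (!length(pd)) stop("no measurements left after QC exclusion")
  n <- length(pd)
  sem <- if (n == 1L) {
    warning("n = 1: SEM reported as 0")
    0
  } else sd(pd) / sqrt(n)
  data.frame(condition = condition, probe = probe, n = n,
             n_excluded = nExcl, mean_Pd = mean(pd), sem_Pd = sem)
}

#' Student's t-test between two permeability groups
#'
#' Two-sample, two-tailed, pooled-variance Student's t-test (Welch's
#' correction available as an option), with the fold change of the group
#' means.
#'
#' @param a,b numeric vectors of permeabilities (each n >= 2).
#' @param labelA,labelB group labels.
#' @param welch use Welch's unequal-variance form (default FALSE).
#' @param alpha significance level (default 0.05).
#' @return One-row data.frame: \code{group_a}, \code{group_b},
#'   \code{t_statistic}, \code{df}, \code{p_value}, \code{significant},
#'   \code{fold_change} (mean(a)/mean(b)).
#' @examples
#' pdTTest(c(3.2, 3.6, 3.9), c(1.1, 1.4, 1.2))
#' @export
pdTTest <- function(a, b, labelA = "a", labelB = "b", welch = FALSE,
                    alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(data.frame(group_a = labelA, group_b = labelB, t_statistic = 0,
                        df = length(a) + length(b) - 2L, p_value = 1,
                        significant = FALSE,
                        fold_change = mean(a) / mean(b)))
    stop("zero variance in both groups with unequal means")
  }
  tt <- t.test(a, b, var.equal = !welch)
  data.frame(group_a = labelA, group_b = labelB,
             t_statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, significant = tt$p.value < alpha,
             fold_change = mean(a) / mean(b))
}

#' Fold change between two condition summaries
#'
#' Ratio of the baseline mean permeability to the treated mean (a
#' fold-decrease under barrier-tightening treatment), reported to three
#' significant figures.
#'
#' @param baseline,treated one-row summaries from [aggregateCondition()], or
#'   bare mean permeabilities.
#' @return Dimensionless ratio, 3 significant figures.
#' @examples
#' foldChange(3.50e-5, 2.23e-5)   # 1.57
#' @export
foldChange <- function(baseline, treated) {
  mb <- if (is.data.frame(baseline)) baseline$mean_Pd else baseline
  mt <- if (is.data.frame(treated)) treated$mean_Pd else treated
  if (!is.finite(mt) || mt <= 0) stop("treated mean permeability must be > 0")
  signif(mb / mt, 3)
}

#' Tumor-to-normal permeability ratio
#'
#' \eqn{TNR = P_{d,tumor} / P_{d,normal}} for one probe, with uncertainty
#' propagated from the two SEMs:
#' \eqn{\sigma_{TNR} = TNR\sqrt{(sem_t/\mu_t)^2 + (sem_n/\mu_n)^2}}.
#' Values above 1 indicate preferential extravasation through leaky
#' (tumor-like) vasculature.
#'
#' @param tumor,normal one-row summaries from [aggregateCondition()] for the
#'   same probe.
#' @return One-row data.frame: \code{probe}, \code{Pd_tumor},
#'   \code{Pd_normal}, \code{tnr}, \code{tnr_se}.
#' @export
computeTNR <- function(tumor, normal) {
  if (!identical(tumor$probe, normal$probe))
    stop("probe mismatch: '", tumor$probe, "' vs '", normal$probe, "'")
  if (normal$mean_Pd <= 0) stop("normal mean permeability must be > 0")
  tnr <- tumor$mean_Pd / normal$mean_Pd
  se <- tnr * sqrt((tumor$sem_Pd / tumor$mean_Pd)^2 +
                     (normal$sem_Pd / normal$mean_Pd)^2)
  data.frame(probe = tumor$probe, Pd_tumor = tumor$mean_Pd,
             Pd_normal = normal$mean_Pd, tnr = tnr, tnr_se = se)
}

#' Size-selectivity table
#'
#' Permeability against hydrodynamic diameter: per-size mean and SEM, ordered
#' by increasing size, with a Student's t-test between each adjacent pair of
#' sizes.
#'
#' @param measurements data.frame with a permeability column and a numeric
#'   probe-size column (e.g. from [simulateCondition()] with size labels).
#' @param sizeCol name of the size column, nm (default \code{"d_h"}).
#' @param pdCol name of the permeability column (default \code{"Pd_cm_s"}).
#' @param excludeLeaks drop focal-leak-flagged points when the columns are
#'   present (default TRUE).
#' @param alpha significance level for the adjacent tests.
#' @return data.frame sorted by size: \code{d_h}, \code{n}, \code{mean_Pd},
#'   \code{sem_Pd}, \code{p_adjacent} (vs the previous size; NA for the
#'   first), \code{significant_adjacent}.
#' @export
sizeSelectivityTable <- function(measurements, sizeCol = "d_h",
                                 pdCol = "Pd_cm_s", excludeLeaks = TRUE,
                                 alpha = 0.05) {
  df <- measurements
  if (excludeLeaks && "focal_leak" %in% names(df))
    df <- df[!df$focal_leak & is.na(df$error), , drop = FALSE]
  sizes <- sort(unique(df[[sizeCol]]))
  if (length(sizes) < 2L) stop("need at least 2 probe sizes")
  groups <- lapply(sizes, function(s) df[[pdCol]][df[[sizeCol]] == s])
  out <- data.frame(
    d_h = sizes,
    n = vapply(groups, length, integer(1)),
    mean_Pd = vapply(groups, mean, numeric(1)),
    sem_Pd = vapply(groups, function(x)
      if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0, numeric(1)),
    p_adjacent = NA_real_, significant_adjacent = NA)
  for (i in 2:length(sizes)) {
    tt <- pdTTest(groups[[i - 1L]], groups[[i]], alpha = alpha)
    out$p_adjacent[i] <- tt$p_value
    out$significant_adjacent[i] <- tt$significant
  }
  out
}
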