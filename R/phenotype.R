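## Phenotype preparation: derived blood-pressure traits (MAP, PP) and the
## reduction of longitudinal covariate-laden measurements to a single
## standardized "average" quantitative trait per individual.

#' Median arterial pressure
#'
#' \eqn{MAP = 2/3\, DBP + 1/3\, SBP} (mmHg). Requires SBP > DBP > 0, so
#' MAP always lies strictly between DBP and SBP.
#'
#' @param dbp,sbp diastolic and systolic pressure in mmHg (vectorized).
#' @return MAP in mmHg.
#' @examples
#' deriveMAP(80, 120)  # 93.33
#' @export
deriveMAP <- function(dbp, sbp) {
  if (any(sbp <= dbp, na.rm = TRUE)) stop("SBP must exceed DBP")
  if (any(dbp <= 0, na.rm = TRUE)) stop("DBP must be positive")
  2 / 3 * dbp + 1 / 3 * sbp
}

#' Pulse pressure
#'
#' \eqn{PP = SBP - DBP} (mmHg), strictly positive by the SBP > DBP
#' precondition.
#'
#' @inheritParams deriveMAP
#' @return PP in mmHg.
#' @export
derivePP <- function(dbp, sbp) {
  if (any(sbp <= dbp, na.rm = TRUE)) stop("SBP must exceed DBP")
  sbp - dbp
}

# Per-exam least-squares covariate adjustment; constant covariates are
# dropped with a warning. Returns residuals aligned to rows of df.
adjustOnce <- function(y, covdf) {
  keep <- vapply(covdf, function(v) length(unique(v)) > 1L, TRUE)
  if (any(!keep))
    warning("constant covariate(s) dropped: ",
            paste(names(covdf)[!keep], collapse = ", "))
  covdf <- covdf[, keep, drop = FALSE]
  if (ncol(covdf) == 0L) return(y - mean(y))
  stats::residuals(lm(y ~ ., data = covdf))
}

#' Collapse longitudinal phenotypes to one adjusted, averaged trait
#'
#' For each exam, the trait is adjusted for the covariates (age,
#' smoking, medication) by least squares across individuals; the
#' residuals are then averaged over each individual's available exams
#' and the result standardized to mean 0, variance 1. The alternative
#' order (average raw values over exams, then adjust averaged
#' covariates once) is available via \code{order = "average_first"}.
#' MAP and PP are derived per record before adjustment. HTN (0/1) is
#' treated as a quantitative trait throughout.
#'
#' Individuals with no non-missing exam for the trait are absent from
#' the output (never zero-filled).
#'
#' @param pheno long-format phenotype data.frame (see
#'   \code{\link{simulateLongitudinalPhenotypes}} for the layout).
#' @param traitName one of "SBP", "DBP", "HTN", "MAP", "PP".
#' @param covariates covariate column names to adjust for.
#' @param order "adjust_first" (default) or "average_first".
#' @return data.frame with family_id, individual_id, value,
#'   n_exams_used; attribute \code{trait} records the trait name.
#' @export
adjustAndAverage <- function(pheno, traitName = c("SBP", "DBP", "HTN", "MAP", "PP"),
                             covariates = c("age", "smoking", "medication"),
                             order = c("adjust_first", "average_first")) {
  traitName <- match.arg(traitName)
  order <- match.arg(order)
  y <- switch(traitName,
    MAP = deriveMAP(pheno$DBP, pheno$SBP),
    PP = derivePP(pheno$DBP, pheno$SBP),
    pheno[[traitName]])
  if (all(is.na(y))) stop("trait ", traitName, " is entirely missing")
  key <- makeSampleKeys(pheno$family_id, pheno$individual_id)
  covdf <- pheno[, covariates, drop = FALSE]
  ok <- !is.na(y) & complete.cases(covdf)

  if (order == "adjust_first") {
    res <- rep(NA_real_, length(y))
    for (e in unique(pheno$exam)) {
      idx <- which(ok & pheno$exam == e)
      if (length(idx) < 2L) next
      res[idx] <- adjustOnce(y[idx], covdf[idx, , drop = FALSE])
    }
    agg <- tapply(res, key, mean, na.rm = TRUE)
    nUsed <- tapply(!is.na(res), key, sum)
    keep <- nUsed > 0 & is.finite(agg)
    val <- agg[keep]
  } else {
    ymean <- tapply(ifelse(ok, y, NA), key, mean, na.rm = TRUE)
    cmean <- lapply(covdf, function(v) tapply(ifelse(ok, v, NA), key, mean, na.rm = TRUE))
    nUsed <- tapply(ok, key, sum)
    keep <- nUsed > 0 & is.finite(ymean)
    val <- adjustOnce(as.numeric(ymean[keep]),
                      as.data.frame(lapply(cmean, function(v) as.numeric(v[keep]))))
    names(val) <- names(ymean)[keep]
  }

  ids <- do.call(rbind, strsplit(names(val), "/", fixed = TRUE))
  out <- data.frame(family_id = ids[, 1], individual_id = ids[, 2],
                    value = zscore(as.numeric(val)),
                    n_exams_used = as.integer(nUsed[keep][names(val)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- names(val)
  attr(out, "trait") <- traitName
  out
}

#' Extract a named trait vector from an adjusted-trait table
#'
#' @param derived output of \code{\link{adjustAndAverage}} (or any
#'   data.frame with family_id, individual_id, value).
#' @return named numeric vector keyed by sample key.
#' @export
traitVector <- function(derived) {
  setNames(derived$value,
           makeSampleKeys(derived$family_id, derived$individual_id))
}
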