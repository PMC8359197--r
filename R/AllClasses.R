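#' @import methods
NULL

#' Per-period adverse-event count data
#'
#' Container for the per-period patient-by-AE-type count matrices of a
#' multi-study design, together with per-patient exposures (treatment
#' cycles), the period design table and the shared AE-type vocabulary.
#' Every matrix shares the same `J` columns (one per AE type, i.e. per
#' (name, severity) pair); rows are the patients enrolled in that period,
#' ordered by patient id, so the row sets may differ across periods
#' (dropout).
#'
#' @slot counts named list of integer matrices, one per period; names are
#'   period ids, rownames are patient ids, colnames are AE-type labels.
#' @slot exposure named list of positive numeric vectors parallel to
#'   `counts` rows: the exposure constant of each patient in that period
#'   (number of treatment cycles; baseline periods use a configured
#'   constant).
#' @slot design data.frame with columns `period_id`, `study_id`,
#'   `treatment_id`, `mechanism_id`, `n_cycles`, `is_baseline`.
#' @slot typeIndex data.frame with columns `label`, `name`, `severity`,
#'   `column` describing the shared AE-type vocabulary.
#' @export
setClass("AECountData",
  representation(
    counts = "list",
    exposure = "list",
    design = "data.frame",
    typeIndex = "data.frame"
  )
)

setValidity("AECountData", function(object) {
  msgs <- character()
  des <- object@design
  need <- c("period_id", "study_id", "treatment_id", "mechanism_id",
            "n_cycles", "is_baseline")
  if (!all(need %in% names(des)))
    return(paste("design lacks columns:",
                 paste(setdiff(need, names(des)), collapse = ", ")))
  pids <- as.character(des$period_id)
  if (!identical(sort(names(object@counts)), sort(pids)))
    msgs <- c(msgs, "count matrix names must match design period ids")
  if (!identical(names(object@exposure), names(object@counts)))
    msgs <- c(msgs, "exposure names must match count names")
  J <- nrow(object@typeIndex)
  for (p in names(object@counts)) {
    Y <- object@counts[[p]]
    if (!is.matrix(Y) || ncol(Y) != J) {
      msgs <- c(msgs, sprintf("period %s: matrix must have %d columns", p, J))
      next
    }
    if (any(Y < 0) || any(Y != round(Y)))
      msgs <- c(msgs, sprintf("period %s: counts must be nonnegative integers", p))
    if (is.null(rownames(Y)))
      msgs <- c(msgs, sprintf("period %s: rownames (patient ids) required", p))
    else if (anyDuplicated(rownames(Y)))
      msgs <- c(msgs, sprintf("period %s: duplicated patient ids", p))
    C <- object@exposure[[p]]
    if (length(C) != nrow(Y) || any(C <= 0))
      msgs <- c(msgs, sprintf("period %s: exposure must be positive, one per row", p))
  }
  if (length(msgs)) msgs else TRUE
})

#' Model hyperparameters
#'
#' Fixed hyperparameters of the hierarchical Poisson factorization:
#' numbers of treatment (`K`) and study (`L`) patterns and the scales of
#' the Gaussian severity-chain and anchoring priors.
#'
#' @slot K number of treatment-specific AE patterns (default 15).
#' @slot L number of study-specific background patterns (default 2; 0
#'   switches the study term off).
#' @slot sigmaG random-walk scale linking adjacent severities of one AE
#'   name (default 1.5).
#' @slot sigmaM anchor scale of the mechanism mean-effect matrices
#'   (default 5).
#' @slot sigmaR anchor scale of the treatment random-effect matrices
#'   (default 0.5, about 10 percent of the mean effect).
#' @slot sigmaS anchor scale of the study-effect matrices (default 5).
#' @export
setClass("AEHyperParams",
  representation(K = "numeric", L = "numeric", sigmaG = "numeric",
                 sigmaM = "numeric", sigmaR = "numeric", sigmaS = "numeric")
)

setValidity("AEHyperParams", function(object) {
  if (length(object@K) != 1 || object@K < 1 || object@K != round(object@K))
    return("K must be a single integer >= 1")
  if (length(object@L) != 1 || object@L < 0 || object@L != round(object@L))
    return("L must be a single integer >= 0")
  for (s in c("sigmaG", "sigmaM", "sigmaR", "sigmaS"))
    if (slot(object, s) <= 0) return(paste(s, "must be > 0"))
  TRUE
})

#' Free model parameters
#'
#' All free parameters of the joint log-posterior. Patient loadings are
#' stored on the unconstrained log scale (`theta = exp(thetaTilde)`,
#' `xi = exp(xiTilde)`); pattern matrices `M` (mechanism mean effects),
#' `R` (treatment random effects, only for treatments in the
#' random-effect set) and `S` (study effects) are unconstrained real
#' matrices whose softmaxed rows give the simplex patterns `phi` and
#' `eta`.
#'
#' Row registries are carried by rownames: `thetaTilde[[t]]` has one row
#' per patient ever treated with `t` (shared across that treatment's
#' periods), `xiTilde[[s]]` one row per patient of study `s` (shared
#' across baseline and treatment periods of the study).
#'
#' @slot thetaTilde named list (by treatment id) of patients x K matrices.
#' @slot M named list (by mechanism id) of K x J matrices.
#' @slot R named list (by treatment id, random-effect set only) of K x J
#'   matrices.
#' @slot xiTilde named list (by study id) of patients x L matrices.
#' @slot S named list (by study id) of L x J matrices.
#' @export
setClass("AEModelParams",
  representation(thetaTilde = "list", M = "list", R = "list",
                 xiTilde = "list", S = "list")
)

setValidity("AEModelParams", function(object) {
  for (nm in names(object@thetaTilde))
    if (is.null(rownames(object@thetaTilde[[nm]])))
      return(sprintf("thetaTilde[['%s']] must carry patient ids as rownames", nm))
  for (nm in names(object@xiTilde))
    if (is.null(rownames(object@xiTilde[[nm]])))
      return(sprintf("xiTilde[['%s']] must carry patient ids as rownames", nm))
  if (length(object@M)) {
    dims <- vapply(object@M, dim, integer(2))
    if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1)
      return("all M matrices must share K x J dimensions")
    for (nm in names(object@R))
      if (!identical(dim(object@R[[nm]]), dim(object@M[[1]])))
        return("R matrices must match M dimensions")
  }
  TRUE
})

#' MAP fit result
#'
#' @slot params the MAP [AEModelParams-class] estimate.
#' @slot logPosterior value of the joint log-posterior at the optimum.
#' @slot breakdown named list of the log-posterior components.
#' @slot trace best-so-far log-posterior after each objective evaluation
#'   (non-decreasing).
#' @slot converged logical; TRUE when the optimizer reported convergence.
#' @slot contributions named list (by treatment) of data.frames with the
#'   per-pattern log-probability increase, descending order and
#'   cumulative share.
#' @slot config echo of the fit configuration (including the seed used).
#' @export
setClass("AEFit",
  representation(params = "AEModelParams", logPosterior = "numeric",
                 breakdown = "list", trace = "numeric",
                 converged = "logical", contributions = "list",
                 config = "list")
)

#' Patient-level safety-profile estimate
#'
#' @slot thetaHat nonnegative loadings of the patient on the K patterns.
#' @slot thetaTilde the unconstrained optimum (log scale).
#' @slot logProb log-probability at the optimum.
#' @slot converged logical.
#' @slot exposure the exposure constant used.
#' @export
setClass("AEProfileEstimate",
  representation(thetaHat = "numeric", thetaTilde = "numeric",
                 logProb = "numeric", converged = "logical",
                 exposure = "numeric")
)

setValidity("AEProfileEstimate", function(object) {
  if (any(!is.finite(object@thetaHat)) || any(object@thetaHat < 0))
    return("thetaHat must be finite and nonnegative")
  TRUE
})

setMethod("show", "AECountData", function(object) {
  des <- object@design
  np <- vapply(object@counts, nrow, integer(1))
  cat(sprintf(
    "AECountData: %d periods (%d baseline), %d studies, %d treatments\n",
    nrow(des), sum(des$is_baseline), length(unique(des$study_id)),
    length(unique(stats::na.omit(des$treatment_id)))))
  cat(sprintf("  %d AE types, %d patient-period rows, %d events\n",
              nrow(object@typeIndex), sum(np),
              sum(vapply(object@counts, sum, numeric(1)))))
})

setMethod("show", "AEHyperParams", function(object) {
  cat(sprintf(
    "AEHyperParams: K=%d, L=%d, sigmaG=%g, sigmaM=%g, sigmaR=%g, sigmaS=%g\n",
    object@K, object@L, object@sigmaG, object@sigmaM, object@sigmaR,
    object@sigmaS))
})

setMethod("show", "AEModelParams", function(object) {
  cat(sprintf(
    "AEModelParams: %d mechanism M, %d treatment R, %d study S matrices\n",
    length(object@M), length(object@R), length(object@S)))
  if (length(object@M))
    cat(sprintf("  K=%d patterns over J=%d AE types\n",
                nrow(object@M[[1]]), ncol(object@M[[1]])))
  if (length(object@S))
    cat(sprintf("  L=%d study patterns\n", nrow(object@S[[1]])))
})

setMethod("show", "AEFit", function(object) {
  cat(sprintf("AEFit: log-posterior %.4f (%s), %d evaluations\n",
              object@logPosterior,
              if (object@converged) "converged" else "iteration cap",
              length(object@trace)))
})

setMethod("show", "AEProfileEstimate", function(object) {
  cat(sprintf("AEProfileEstimate: K=%d, logProb %.4f, exposure %g\n",
              length(object@thetaHat), object@logProb, object@exposure))
  print(round(object@thetaHat, 4))
})
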