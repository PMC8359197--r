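#' Simulation specification
#'
#' Describes a multi-study AE dataset to simulate: the arm structure
#' (studies, baseline/treatment periods, cycle counts, patient counts,
#' dropout), the AE vocabulary (names x severity grids), the model
#' dimensions and the generation scales of the ground-truth parameters.
#'
#' The loading generator is a sparse mixture mirroring the observation
#' that most patients carry a near-zero amount of most patterns: with
#' probability `piZero` a loading sits at the lower bound (theta = 0
#' numerically), otherwise `thetaTilde ~ Normal(muTheta, sdTheta^2)`.
#' `patternSeparation` boosts a disjoint block of signature AE names per
#' pattern in the mechanism mean effects, producing the well-separated
#' sparse co-occurrence patterns typical of distinct toxicity clusters.
#' `fracStudyOnlyNames` / `fracTreatmentOnlyNames` reserve a fraction of
#' AE names for the study background (disease-driven AEs never loaded by
#' treatment patterns) and for treatments respectively, by masking the
#' other component's effects at those columns.
#'
#' @param arms list of arms; each arm is
#'   `list(study =, n =, periods = list(list(treatment = NA or id,
#'   mechanism = NA or id, cycles = NA or int), ...), dropout = )` with
#'   `dropout` the per-transition fraction lost between consecutive
#'   periods of the arm.
#' @param aeNames named list: AE name -> integer vector of observed
#'   severity grades.
#' @param K,L model dimensions.
#' @param sigmaG,sigmaM,sigmaR,sigmaS generation scales of the pattern
#'   matrices (drawn from their anchoring + random-walk chain law).
#' @param piZero,muTheta,sdTheta sparse-mixture law of thetaTilde.
#' @param piZeroXi,muXi,sdXi sparse-mixture law of xiTilde.
#' @param patternSeparation additive boost of each pattern's signature
#'   block in M (0 disables).
#' @param fracStudyOnlyNames,fracTreatmentOnlyNames reserved-name
#'   fractions.
#' @param baselineExposure exposure constant of baseline periods.
#' @param lowerBound loading value representing "zero" (default -15).
#' @return list of class `aeSimSpec`.
#' @export
aeSimSpec <- function(arms, aeNames, K = 3, L = 1,
                      sigmaG = 1.5, sigmaM = 5, sigmaR = 0.5, sigmaS = 5,
                      piZero = 0.6, muTheta = 0.4, sdTheta = 0.6,
                      piZeroXi = 0.2, muXi = -1.2, sdXi = 0.5,
                      patternSeparation = 3,
                      fracStudyOnlyNames = 0.15,
                      fracTreatmentOnlyNames = 0.7,
                      baselineExposure = 1, lowerBound = -15) {
  ok <- vapply(arms, function(a)
    a$dropout >= 0 && a$dropout < 1 && a$n >= 1, logical(1))
  if (!all(ok)) stop("each arm needs n >= 1 and dropout in [0, 1)")
  structure(mget(setdiff(names(formals()), "...")), class = "aeSimSpec")
}

#' Small single-study preset
#'
#' One study, one baseline period plus one treatment period, for quick
#' structural tests.
#'
#' @param n patients (default 60).
#' @param nNames AE names (default 6), each with severities 1..2.
#' @param K,L dimensions.
#' @param ... passed to [aeSimSpec()].
#' @return an `aeSimSpec`.
#' @export
simSpecMinimal <- function(n = 60, nNames = 6, K = 2, L = 1, ...) {
  arms <- list(list(study = 1, n = n, dropout = 0,
                    periods = list(
                      list(treatment = NA, mechanism = NA, cycles = NA),
                      list(treatment = "T1", mechanism = "M1", cycles = 4))))
  nm <- sprintf("AE%02d", seq_len(nNames))
  aeNames <- stats::setNames(rep(list(1:2), nNames), nm)
  aeSimSpec(arms, aeNames, K = K, L = L, ...)
}

#' Recovery-study preset
#'
#' The parameter-recovery condition: one study of `n = 600` patients,
#' baseline plus one 4-cycle treatment period, 20 AE names x 3
#' severities (J = 60), K = 3 well-separated sparse patterns, L = 1
#' study pattern, sparse loadings giving a mean load of roughly 10 AEs
#' per patient over the treatment period.
#'
#' @param n patients (default 600).
#' @param ... passed to [aeSimSpec()].
#' @return an `aeSimSpec`.
#' @export
simSpecRecovery <- function(n = 600, ...) {
  arms <- list(list(study = 1, n = n, dropout = 0,
                    periods = list(
                      list(treatment = NA, mechanism = NA, cycles = NA),
                      list(treatment = "T1", mechanism = "M1", cycles = 4))))
  nm <- sprintf("AE%02d", 1:20)
  aeNames <- stats::setNames(rep(list(1:3), 20), nm)
  aeSimSpec(arms, aeNames, K = 3, L = 1, ...)
}

#' Three-study oncology-like preset
#'
#' Emulates the pooled breast-cancer design: 3 studies, 10 periods (3
#' baseline), 5 treatments (AC, FAC, A, CMF, T), 2 mechanisms of action
#' (nucleic-acid-synthesis inhibition for AC/FAC/A/CMF; mitosis
#' inhibition for T), per-arm patient counts 1625/731/480/481 with the
#' observed dropout, and cycle counts 4/4/6/4/3/4/3.
#'
#' @param scale factor on the per-arm patient counts (default 1; use a
#'   small fraction for fast tests).
#' @param aeNames vocabulary (default 12 names with varying severity
#'   grids).
#' @param ... passed to [aeSimSpec()].
#' @return an `aeSimSpec`.
#' @export
simSpecThreeStudy <- function(scale = 1, aeNames = NULL, ...) {
  n <- function(x) max(2L, as.integer(round(x * scale)))
  arms <- list(
    list(study = 1, n = n(1625), dropout = 42 / 1625,
         periods = list(
           list(treatment = NA, mechanism = NA, cycles = NA),
           list(treatment = "AC", mechanism = "NAS", cycles = 4),
           list(treatment = "T", mechanism = "MIT", cycles = 4))),
    list(study = 2, n = n(731), dropout = 0,
         periods = list(
           list(treatment = "FAC", mechanism = "NAS", cycles = 6))),
    list(study = 3, n = n(480), dropout = 21 / 480,
         periods = list(
           list(treatment = NA, mechanism = NA, cycles = NA),
           list(treatment = "A", mechanism = "NAS", cycles = 4),
           list(treatment = "CMF", mechanism = "NAS", cycles = 3))),
    list(study = 3, n = n(481), dropout = 9 / 481,
         periods = list(
           list(treatment = NA, mechanism = NA, cycles = NA),
           list(treatment = "AC", mechanism = "NAS", cycles = 4),
           list(treatment = "CMF", mechanism = "NAS", cycles = 3))))
  if (is.null(aeNames)) {
    nm <- sprintf("AE%02d", 1:12)
    grids <- rep(list(1:3, 1:2, 1:4, 1L), 3)
    aeNames <- stats::setNames(grids, nm)
  }
  aeSimSpec(arms, aeNames, K = 3, L = 2, ...)
}

#' Build the design and enrollment tables of a simulation
#'
#' Deterministic given the seed. Patients are labelled
#' `P<arm><serial>`; later periods of an arm contain a seeded random
#' subset of the previous period's patients, thinned by the arm's
#' dropout fraction.
#'
#' @param spec an `aeSimSpec`.
#' @param seed integer seed.
#' @return list with `design` and `enrollment` data.frames in the
#'   dialect of [readAEEvents()].
#' @export
makeDesign <- function(spec, seed = 1) {
  set.seed(as.integer(seed))
  design <- NULL
  enrollment <- NULL
  pcount <- 0
  for (ai in seq_along(spec$arms)) {
    arm <- spec$arms[[ai]]
    pat <- sprintf("P%d-%04d", ai, seq_len(arm$n))
    current <- pat
    for (pi in seq_along(arm$periods)) {
      per <- arm$periods[[pi]]
      pcount <- pcount + 1
      pid <- sprintf("p%02d", pcount)
      if (pi > 1 && arm$dropout > 0) {
        keep <- max(1L, round(length(current) * (1 - arm$dropout)))
        current <- sort(sample(current, keep))
      }
      design <- rbind(design, data.frame(
        period_id = pid, study_id = arm$study,
        treatment_id = if (is.na(per$treatment)) NA_character_
                       else as.character(per$treatment),
        mechanism_id = if (is.na(per$mechanism)) NA_character_
                       else as.character(per$mechanism),
        n_cycles = if (is.null(per$cycles) || is.na(per$cycles)) NA_real_
                   else per$cycles,
        is_baseline = is.na(per$treatment), stringsAsFactors = FALSE))
      enrollment <- rbind(enrollment, data.frame(
        period_id = pid, patient_id = current, stringsAsFactors = FALSE))
    }
  }
  list(design = design, enrollment = enrollment)
}

#' Draw ground-truth parameters
#'
#' Pattern matrices are drawn from their prior as a generative law:
#' anchor columns (lowest severity per name) `~ Normal(0, sigma^2)`,
#' then each higher adjacent severity `~ Normal(previous, sigmaG^2)`
#' along the chain. Signature-name blocks and study-only /
#' treatment-only masks are applied to M and S as described in
#' [aeSimSpec()]. Loadings follow the sparse mixture. Deterministic
#' given the seed.
#'
#' @param design,enrollment tables from [makeDesign()].
#' @param spec the `aeSimSpec`.
#' @param seed integer seed.
#' @return list with `params` ([AEModelParams-class]), `index`,
#'   `adjacency`, `phi` (per treatment), `eta` (per study), and the
#'   mask bookkeeping (`studyOnlyCols`, `treatmentOnlyCols`).
#' @export
drawTrueParams <- function(design, enrollment, spec, seed = 1) {
  set.seed(as.integer(seed) + 1L)
  evFake <- do.call(rbind, lapply(names(spec$aeNames), function(nm)
    data.frame(ae_name = nm, severity = spec$aeNames[[nm]],
               stringsAsFactors = FALSE)))
  index <- buildAETypeIndex(data.frame(ae_name = evFake$ae_name,
                                       severity = evFake$severity,
                                       patient_id = "x", period_id = "x",
                                       count = 1))
  adjacency <- buildAdjacency(index)
  J <- nrow(index)
  K <- spec$K
  L <- spec$L

  names_all <- names(spec$aeNames)
  nStudyOnly <- floor(spec$fracStudyOnlyNames * length(names_all))
  nTrtOnly <- floor(spec$fracTreatmentOnlyNames * length(names_all))
  shuffled <- sample(names_all)
  studyOnly <- shuffled[seq_len(nStudyOnly)]
  trtOnly <- shuffled[nStudyOnly + seq_len(nTrtOnly)]
  studyOnlyCols <- index$column[index$name %in% studyOnly]
  trtOnlyCols <- index$column[index$name %in% trtOnly]

  drawChain <- function(nrows, sigmaAnchor) {
    A <- matrix(0, nrows, J, dimnames = list(NULL, index$label))
    A[, adjacency$anchors] <- stats::rnorm(nrows * length(adjacency$anchors),
                                           0, sigmaAnchor)
    prs <- adjacency$pairs
    for (r in seq_len(nrow(prs)))
      A[, prs[r, "jprime"]] <- A[, prs[r, "j"]] +
        stats::rnorm(nrows, 0, spec$sigmaG)
    A
  }

  trt <- unique(design[!design$is_baseline,
                       c("treatment_id", "mechanism_id")])
  mechs <- sort(unique(trt$mechanism_id))
  # signature blocks: treatment-pattern names split across the K patterns
  sigNames <- if (length(trtOnly)) trtOnly else names_all
  blocks <- split(sigNames, factor(rep_len(seq_len(K), length(sigNames)),
                                   levels = seq_len(K)))
  M <- list()
  for (m in mechs) {
    A <- drawChain(K, spec$sigmaM)
    if (spec$patternSeparation > 0)
      for (k in seq_len(K)) {
        cols <- index$column[index$name %in% blocks[[k]]]
        A[k, cols] <- A[k, cols] + spec$patternSeparation
      }
    A[, studyOnlyCols] <- -20  # disease-only AE types never treatment-loaded
    M[[as.character(m)]] <- A
  }
  reTrts <- .randomEffectSet(design)
  R <- lapply(stats::setNames(nm = sort(reTrts)), function(t)
    drawChain(K, spec$sigmaR))
  studies <- sort(unique(as.character(design$study_id)))
  S <- list()
  if (L > 0) for (s in studies) {
    A <- drawChain(L, spec$sigmaS)
    # background patterns live exclusively on the disease-reserved names
    # (when any are reserved); otherwise only the treatment-reserved
    # names are excluded
    if (length(studyOnlyCols))
      A[, -studyOnlyCols] <- -20
    else if (length(trtOnlyCols))
      A[, trtOnlyCols] <- -20
    S[[s]] <- A
  }

  regTheta <- list()
  regXi <- list()
  for (k in seq_len(nrow(design))) {
    p <- design$period_id[k]
    pat <- sort(enrollment$patient_id[enrollment$period_id == p])
    s <- as.character(design$study_id[k])
    regXi[[s]] <- union(regXi[[s]], pat)
    if (!design$is_baseline[k]) {
      t <- as.character(design$treatment_id[k])
      regTheta[[t]] <- union(regTheta[[t]], pat)
    }
  }
  drawMix <- function(pat, ncol, piZero, mu, sdv) {
    n <- length(pat) * ncol
    v <- ifelse(stats::runif(n) < piZero, spec$lowerBound,
                stats::rnorm(n, mu, sdv))
    matrix(v, length(pat), ncol, dimnames = list(sort(pat), NULL))
  }
  thetaTilde <- lapply(regTheta, function(pat)
    drawMix(sort(pat), K, spec$piZero, spec$muTheta, spec$sdTheta))
  xiTilde <- if (L > 0) lapply(regXi, function(pat)
    drawMix(sort(pat), L, spec$piZeroXi, spec$muXi, spec$sdXi)) else list()

  params <- new("AEModelParams", thetaTilde = thetaTilde, M = M, R = R,
                xiTilde = xiTilde, S = S)
  phi <- list()
  for (r in seq_len(nrow(trt))) {
    t <- as.character(trt$treatment_id[r])
    phi[[t]] <- computePhi(M[[as.character(trt$mechanism_id[r])]], R[[t]])
  }
  list(params = params, index = index, adjacency = adjacency,
       phi = phi, eta = lapply(S, computeEta),
       studyOnlyCols = studyOnlyCols, treatmentOnlyCols = trtOnlyCols)
}

#' Simulate count matrices from ground truth
#'
#' `Y_ijp ~ Poisson(C_i lambda_ijp)` independently, with the baseline
#' periods driven by the study background only. Deterministic given the
#' seed.
#'
#' @param truth output of [drawTrueParams()].
#' @param design,enrollment tables from [makeDesign()].
#' @param spec the `aeSimSpec`.
#' @param seed integer seed.
#' @return an [AECountData-class] object.
#' @export
simulateCounts <- function(truth, design, enrollment, spec, seed = 1) {
  set.seed(as.integer(seed) + 2L)
  index <- truth$index
  counts <- list()
  exposure <- list()
  # empty container first so computeLambda can resolve rows
  for (k in seq_len(nrow(design))) {
    p <- design$period_id[k]
    pat <- sort(enrollment$patient_id[enrollment$period_id == p])
    counts[[p]] <- matrix(0L, length(pat), nrow(index),
                          dimnames = list(pat, index$label))
    C <- rep(if (design$is_baseline[k]) spec$baselineExposure
             else design$n_cycles[k], length(pat))
    names(C) <- pat
    exposure[[p]] <- C
  }
  shell <- new("AECountData", counts = counts, exposure = exposure,
               design = design, typeIndex = index)
  for (k in seq_len(nrow(design))) {
    p <- design$period_id[k]
    lam <- computeLambda(p, truth$params, shell)
    mu <- exposure[[p]] * lam
    if (any(!is.finite(mu))) stop("simulateCounts: non-finite intensity")
    Y <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
                dimnames = dimnames(mu))
    storage.mode(Y) <- "integer"
    counts[[p]] <- Y
  }
  new("AECountData", counts = counts, exposure = exposure,
      design = design, typeIndex = index)
}

#' One-call simulation of a full dataset
#'
#' Runs [makeDesign()], [drawTrueParams()] and [simulateCounts()] and
#' also returns the long-format event export, so the result can be
#' round-tripped through the ingestion pipeline.
#'
#' @param spec an `aeSimSpec`.
#' @param seed integer seed (all three stages derive from it).
#' @return list with `data` ([AECountData-class]), `truth`, `design`,
#'   `enrollment`, `events`.
#' @export
simulateAEData <- function(spec, seed = 1) {
  d <- makeDesign(spec, seed)
  truth <- drawTrueParams(d$design, d$enrollment, spec, seed)
  data <- simulateCounts(truth, d$design, d$enrollment, spec, seed)
  list(data = data, truth = truth, design = d$design,
       enrollment = d$enrollment, events = exportEvents(data))
}
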