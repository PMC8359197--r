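#' Fit configuration
#'
#' @param seed integer seed controlling initialization (and restarts:
#'   restart r uses `seed + r - 1`).
#' @param initScale sd of the Gaussian initialization noise (default 0.1).
#' @param maxIter L-BFGS iteration cap (default 2000).
#' @param gradTol projected-gradient tolerance (default 1e-6).
#' @param nRestarts number of random restarts; the best final
#'   log-posterior wins, ties broken by lowest restart seed (default 1).
#' @param bounds box bounds for the loading parameters thetaTilde and
#'   xiTilde (default c(-15, 15); exp(-15) is numerically zero on the
#'   intensity scale, so an all-zero profile sits at the lower bound).
#' @param factr L-BFGS-B relative-reduction factor (default 1e7).
#' @return list of class `aeFitConfig`.
#' @export
aeFitConfig <- function(seed = 1, initScale = 0.1, maxIter = 2000,
                        gradTol = 1e-6, nRestarts = 1,
                        bounds = c(-15, 15), factr = 1e7) {
  stopifnot(initScale > 0, maxIter >= 1, gradTol > 0, nRestarts >= 1,
            length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(seed = as.integer(seed), initScale = initScale,
                 maxIter = as.integer(maxIter), gradTol = gradTol,
                 nRestarts = as.integer(nRestarts), bounds = bounds,
                 factr = factr),
            class = "aeFitConfig")
}

# Row registries: which patients own a row of thetaTilde (per treatment)
# and xiTilde (per study). A patient treated with the same treatment in
# two periods shares one row; study rows are shared across that study's
# baseline and treatment periods.
.buildRegistries <- function(data) {
  des <- aeDesign(data)
  theta <- list()
  xi <- list()
  for (k in seq_len(nrow(des))) {
    p <- as.character(des$period_id[k])
    pat <- rownames(aeCounts(data)[[p]])
    s <- as.character(des$study_id[k])
    xi[[s]] <- union(xi[[s]], pat)
    if (!des$is_baseline[k]) {
      t <- as.character(des$treatment_id[k])
      theta[[t]] <- union(theta[[t]], pat)
    }
  }
  list(theta = lapply(theta, sort), xi = lapply(xi, sort))
}

# Treatments that get a random-effect matrix R: by default every
# treatment whose mechanism is shared by >= 2 treatments (a lone
# treatment of its mechanism is fully described by M).
.randomEffectSet <- function(design) {
  trt <- unique(design[!design$is_baseline,
                       c("treatment_id", "mechanism_id")])
  tab <- table(trt$mechanism_id)
  as.character(trt$treatment_id[tab[as.character(trt$mechanism_id)] >= 2])
}

#' Seeded parameter initialization
#'
#' Pattern matrices start near the data: each row of a mechanism's M is
#' the log pooled per-cycle AE-type rate of that mechanism's treatment
#' periods, each row of a study's S the log rate of its baseline
#' periods (the empirical background), both plus iid
#' Normal(0, initScale^2) jitter that differentiates the K (or L) rows;
#' R entries are pure jitter. This warm start anchors the study
#' patterns at the baseline profile and breaks the treatment/background
#' symmetry. Loading rows start at
#' the log of the patient's mean per-cycle event rate divided by the
#' number of patterns (so initial intensities roughly match the data),
#' plus Normal(0, initScale^2) jitter, floored at the lower box bound
#' (all-zero count rows land exactly on the bound). Deterministic given
#' the seed.
#'
#' @param data an [AECountData-class] object.
#' @param hyper an [AEHyperParams-class] object.
#' @param seed integer seed.
#' @param initScale jitter sd.
#' @param bounds loading box bounds.
#' @param randomEffectTreatments treatments receiving an R matrix;
#'   default as described in [fitMAP()].
#' @return an [AEModelParams-class] object.
#' @export
initParams <- function(data, hyper, seed = 1, initScale = 0.1,
                       bounds = c(-15, 15),
                       randomEffectTreatments = NULL) {
  set.seed(as.integer(seed))
  des <- aeDesign(data)
  reg <- .buildRegistries(data)
  J <- nrow(aeTypeIndex(data))
  K <- hyper@K
  L <- hyper@L
  if (is.null(randomEffectTreatments))
    randomEffectTreatments <- .randomEffectSet(des)

  # pooled per-cycle column rates over a set of periods, on the log scale;
  # used to start pattern rows near the empirical AE-type profile (a
  # standard NMF warm start), with seeded jitter differentiating rows
  colRate <- function(periods) {
    tot <- numeric(J)
    n <- 0
    for (p in periods) {
      Y <- aeCounts(data)[[p]]
      C <- aeExposure(data)[[p]]
      tot <- tot + colSums(Y / C)
      n <- n + nrow(Y)
    }
    if (n == 0) return(numeric(J))
    tot / n
  }
  pid <- as.character(des$period_id)
  mechs <- sort(unique(stats::na.omit(as.character(des$mechanism_id))))
  M <- lapply(stats::setNames(nm = mechs), function(m) {
    base <- log(colRate(pid[!des$is_baseline &
                            as.character(des$mechanism_id) == m]) + 1e-3)
    matrix(rep(base, each = K) + stats::rnorm(K * J, 0, initScale), K, J,
           dimnames = list(NULL, aeTypeIndex(data)$label))
  })
  R <- lapply(stats::setNames(nm = sort(randomEffectTreatments)), function(t)
    matrix(stats::rnorm(K * J, 0, initScale), K, J,
           dimnames = list(NULL, aeTypeIndex(data)$label)))
  studies <- if (L > 0) sort(unique(as.character(des$study_id))) else character()
  S <- lapply(stats::setNames(nm = studies), function(s) {
    bl <- pid[des$is_baseline & as.character(des$study_id) == s]
    if (length(bl) == 0)  # study without baseline: fall back to all periods
      bl <- pid[as.character(des$study_id) == s]
    base <- log(colRate(bl) + 1e-3)
    matrix(rep(base, each = L) + stats::rnorm(L * J, 0, initScale), L, J,
           dimnames = list(NULL, aeTypeIndex(data)$label))
  })

  # mean per-cycle event rate of each patient within the relevant periods
  rateRows <- function(pat, periods) {
    rate <- numeric(length(pat))
    nper <- numeric(length(pat))
    for (p in periods) {
      Y <- aeCounts(data)[[p]]
      C <- aeExposure(data)[[p]]
      i <- match(rownames(Y), pat)
      rate[i] <- rate[i] + rowSums(Y) / C
      nper[i] <- nper[i] + 1
    }
    ifelse(nper > 0, rate / pmax(nper, 1), 0)
  }
  thetaTilde <- list()
  for (t in names(reg$theta)) {
    pat <- reg$theta[[t]]
    periods <- as.character(des$period_id[!des$is_baseline &
                                          as.character(des$treatment_id) == t])
    base <- log(rateRows(pat, periods) / K)
    A <- matrix(base + stats::rnorm(length(pat) * K, 0, initScale),
                length(pat), K, dimnames = list(pat, NULL))
    A[A < bounds[1] | !is.finite(A)] <- bounds[1]
    A[A > bounds[2]] <- bounds[2]
    thetaTilde[[t]] <- A
  }
  xiTilde <- list()
  if (L > 0) for (s in names(reg$xi)) {
    pat <- reg$xi[[s]]
    periods <- as.character(des$period_id[as.character(des$study_id) == s])
    base <- log(rateRows(pat, periods) / L)
    A <- matrix(base + stats::rnorm(length(pat) * L, 0, initScale),
                length(pat), L, dimnames = list(pat, NULL))
    A[A < bounds[1] | !is.finite(A)] <- bounds[1]
    A[A > bounds[2]] <- bounds[2]
    xiTilde[[s]] <- A
  }
  new("AEModelParams", thetaTilde = thetaTilde, M = M, R = R,
      xiTilde = xiTilde, S = S)
}

# flatten/unflatten between an AEModelParams and one numeric vector,
# with matching box bounds (loadings bounded, pattern matrices free)
.flattenParams <- function(params) {
  unlist(list(M = lapply(params@M, as.numeric),
              R = lapply(params@R, as.numeric),
              S = lapply(params@S, as.numeric),
              theta = lapply(params@thetaTilde, as.numeric),
              xi = lapply(params@xiTilde, as.numeric)),
         use.names = FALSE)
}

.unflattenParams <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0
  take <- function(A) {
    n <- length(A)
    v <- vec[pos + seq_len(n)]
    pos <<- pos + n
    array(v, dim(A), dimnames(A))
  }
  out@M <- lapply(skeleton@M, take)
  out@R <- lapply(skeleton@R, take)
  out@S <- lapply(skeleton@S, take)
  out@thetaTilde <- lapply(skeleton@thetaTilde, take)
  out@xiTilde <- lapply(skeleton@xiTilde, take)
  out
}

.flattenGrad <- function(g) {
  unlist(list(lapply(g$M, as.numeric), lapply(g$R, as.numeric),
              lapply(g$S, as.numeric), lapply(g$thetaTilde, as.numeric),
              lapply(g$xiTilde, as.numeric)), use.names = FALSE)
}

.paramBounds <- function(params, bounds) {
  nFree <- sum(vapply(c(params@M, params@R, params@S), length, integer(1)))
  nLoad <- sum(vapply(c(params@thetaTilde, params@xiTilde), length,
                      integer(1)))
  list(lower = c(rep(-Inf, nFree), rep(bounds[1], nLoad)),
       upper = c(rep(Inf, nFree), rep(bounds[2], nLoad)))
}

#' MAP estimation of the joint log-posterior
#'
#' Maximizes the joint log-posterior over all free parameters in one
#' box-constrained L-BFGS-B run with analytic gradients, optionally
#' restarted from `nRestarts` seeded initializations (best final value
#' wins). The returned trace is the best-so-far objective after each
#' evaluation of the winning restart.
#'
#' @param data an [AECountData-class] object.
#' @param adjacency adjacency structure from [buildAdjacency()].
#' @param hyper an [AEHyperParams-class] object.
#' @param config an [aeFitConfig()] list.
#' @param init optional [AEModelParams-class] to start from (overrides
#'   the seeded initialization; restarts are then ignored).
#' @param randomEffectTreatments treatments receiving an R matrix
#'   (default: every treatment whose mechanism has at least two
#'   treatments).
#' @return an [AEFit-class] object.
#' @export
fitMAP <- function(data, adjacency, hyper, config = aeFitConfig(),
                   init = NULL, randomEffectTreatments = NULL) {
  runOne <- function(start) {
    skeleton <- start
    evals <- numeric(0)
    fn <- function(v) {
      p <- .unflattenParams(v, skeleton)
      val <- logPosterior(p, data, adjacency, hyper)$total
      if (!is.finite(val)) {
        bd <- logPosterior(p, data, adjacency, hyper)
        badp <- names(bd$poisson_by_period)[!is.finite(bd$poisson_by_period)]
        stop("non-finite log-posterior during optimization (",
             if (length(badp)) paste("Poisson term, period",
                                     paste(badp, collapse = ","))
             else "prior term", ")")
      }
      evals[length(evals) + 1] <<- val
      -val
    }
    gr <- function(v) {
      p <- .unflattenParams(v, skeleton)
      -.flattenGrad(logPosteriorGradient(p, data, adjacency, hyper))
    }
    b <- .paramBounds(start, config$bounds)
    opt <- stats::optim(.flattenParams(start), fn, gr, method = "L-BFGS-B",
                        lower = b$lower, upper = b$upper,
                        control = list(maxit = config$maxIter,
                                       pgtol = config$gradTol,
                                       factr = config$factr))
    list(params = .unflattenParams(opt$par, skeleton), value = -opt$value,
         converged = opt$convergence == 0, trace = cummax(evals))
  }

  runs <- if (!is.null(init)) {
    list(runOne(init))
  } else {
    lapply(seq_len(config$nRestarts), function(r)
      runOne(initParams(data, hyper, seed = config$seed + r - 1,
                        initScale = config$initScale,
                        bounds = config$bounds,
                        randomEffectTreatments = randomEffectTreatments)))
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.max(vals)]]  # which.max: ties -> lowest seed

  bd <- logPosterior(best$params, data, adjacency, hyper)
  fit <- new("AEFit", params = best$params, logPosterior = bd$total,
             breakdown = bd, trace = best$trace,
             converged = best$converged, contributions = list(),
             config = c(unclass(config),
                        list(nEvaluations = length(best$trace))))
  fit@contributions <- patternContributions(fit, data, adjacency, hyper)
  fit
}

#' Per-pattern log-probability increase and ordering
#'
#' The contribution of pattern k of treatment t is the drop in the joint
#' log-posterior when that treatment's loading column k is forced to the
#' lower bound (theta ~ 0), everything else fixed. Patterns are numbered
#' in descending order of this increase, with the cumulative share of
#' the total reported (used for the "first patterns carrying > 80%"
#' reading rule).
#'
#' @param fit an [AEFit-class] object.
#' @inheritParams fitMAP
#' @return named list (by treatment) of data.frames with columns
#'   `pattern`, `contribution`, `cumulative_fraction`, sorted descending.
#' @export
patternContributions <- function(fit, data, adjacency, hyper) {
  params <- fit@params
  base <- logPosterior(params, data, adjacency, hyper)$total
  lb <- if (!is.null(fit@config$bounds)) fit@config$bounds[1] else -15
  out <- list()
  for (t in names(params@thetaTilde)) {
    K <- ncol(params@thetaTilde[[t]])
    contrib <- vapply(seq_len(K), function(k) {
      p2 <- params
      p2@thetaTilde[[t]][, k] <- lb
      base - logPosterior(p2, data, adjacency, hyper)$total
    }, numeric(1))
    ord <- order(contrib, decreasing = TRUE)
    tot <- sum(contrib)
    out[[t]] <- data.frame(pattern = ord, contribution = contrib[ord],
                           cumulative_fraction = if (tot > 0)
                             cumsum(contrib[ord]) / tot else rep(NA_real_, K))
  }
  out
}

#' Align estimated patterns to a reference
#'
#' Factorizations are identifiable only up to pattern order. Finds the
#' row permutation of the estimated pattern matrix maximizing the total
#' cosine similarity with the reference rows: exhaustively for K <= 6,
#' greedily (best available pair first) for larger K.
#'
#' @param phiEst,phiRef K x J matrices (same shape).
#' @return list with `permutation` (phiEst row index matched to each
#'   reference row), `similarity` (per matched pair) and `meanSimilarity`.
#' @export
matchPatterns <- function(phiEst, phiRef) {
  if (!identical(dim(phiEst), dim(phiRef)))
    stop("matchPatterns: shape mismatch")
  K <- nrow(phiRef)
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  simMat <- outer(seq_len(K), seq_len(K),
                  Vectorize(function(i, j) cosine(phiRef[i, ], phiEst[j, ])))
  if (K <= 6) {
    perms <- .permutations(K)
    scores <- apply(perms, 1, function(pm) sum(simMat[cbind(seq_len(K), pm)]))
    perm <- perms[which.max(scores), ]
  } else {
    perm <- integer(K)
    m <- simMat
    for (step in seq_len(K)) {
      # greedy: best remaining (reference, estimate) pair
      best <- which(m == max(m), arr.ind = TRUE)[1, ]
      perm[best[1]] <- best[2]
      m[best[1], ] <- -Inf
      m[, best[2]] <- -Inf
    }
  }
  perm <- unname(perm)
  sims <- simMat[cbind(seq_len(K), perm)]
  list(permutation = perm, similarity = sims, meanSimilarity = mean(sims))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

#' Pattern matrices of a fitted model
#'
#' @param fit an [AEFit-class] object (or an [AEModelParams-class]).
#' @param design the period design data.frame (to map treatments to
#'   mechanisms).
#' @return named list (by treatment) of K x J row-stochastic matrices.
#' @export
fittedPhi <- function(fit, design) {
  params <- if (is(fit, "AEFit")) fit@params else fit
  trt <- unique(design[!design$is_baseline,
                       c("treatment_id", "mechanism_id")])
  out <- list()
  for (r in seq_len(nrow(trt))) {
    t <- as.character(trt$treatment_id[r])
    m <- as.character(trt$mechanism_id[r])
    out[[t]] <- computePhi(params@M[[m]], params@R[[t]])
  }
  out
}

#' Study background matrices of a fitted model
#'
#' @param fit an [AEFit-class] object (or an [AEModelParams-class]).
#' @return named list (by study) of L x J row-stochastic matrices.
#' @export
fittedEta <- function(fit) {
  params <- if (is(fit, "AEFit")) fit@params else fit
  lapply(params@S, computeEta)
}
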