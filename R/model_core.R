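#' Row-wise softmax
#'
#' Numerically stable (max-subtracted) softmax of each row: outputs are
#' nonnegative and each row sums to 1. Adding a constant to a row leaves
#' its output unchanged, which is why the pattern matrices need
#' anchoring priors for identification.
#'
#' @param A real matrix (finite).
#' @return row-stochastic matrix of the same shape.
#' @export
softmaxRows <- function(A) {
  if (!is.matrix(A)) A <- matrix(A, nrow = 1)
  if (nrow(A) == 0 || ncol(A) == 0) return(A)
  if (any(!is.finite(A))) stop("softmaxRows: non-finite input")
  m <- apply(A, 1, max)
  E <- exp(A - m)
  E / rowSums(E)
}

#' Treatment pattern matrix
#'
#' `phi = softmaxRows(M + R)`: the mechanism mean effect plus, for
#' treatments in the random-effect set, the treatment-specific random
#' effect. Rows are simplex-normalized occurrence-intensity patterns.
#'
#' @param M K x J mechanism mean-effect matrix.
#' @param R K x J treatment random-effect matrix, or NULL for a
#'   treatment without one (e.g. the sole treatment of its mechanism).
#' @return K x J row-stochastic pattern matrix.
#' @export
computePhi <- function(M, R = NULL) {
  if (is.null(R)) return(softmaxRows(M))
  if (!identical(dim(M), dim(R))) stop("computePhi: M and R shapes differ")
  softmaxRows(M + R)
}

#' Study background pattern matrix
#'
#' @param S L x J study-effect matrix.
#' @return L x J row-stochastic matrix `eta = softmaxRows(S)`.
#' @export
computeEta <- function(S) softmaxRows(S)

#' Poisson mean intensities of one period
#'
#' For a treatment period, `lambda = exp(thetaTilde) phi + exp(xiTilde)
#' eta`; for a baseline period the treatment term is identically zero
#' and only the study background contributes. Rows follow the period's
#' enrollment (the rownames of its count matrix); patient loadings are
#' looked up by id in the parameter row registries.
#'
#' @param periodId period id (character or coercible).
#' @param params an [AEModelParams-class] object.
#' @param data an [AECountData-class] object.
#' @return N_p x J matrix of nonnegative intensities.
#' @export
computeLambda <- function(periodId, params, data) {
  periodId <- as.character(periodId)
  des <- aeDesign(data)
  k <- match(periodId, as.character(des$period_id))
  if (is.na(k)) stop("unknown period ", periodId)
  Y <- aeCounts(data)[[periodId]]
  pat <- rownames(Y)
  J <- ncol(Y)
  lam <- matrix(0, length(pat), J, dimnames = dimnames(Y))
  s <- as.character(des$study_id[k])
  if (length(params@S) && s %in% names(params@S)) {
    xiT <- params@xiTilde[[s]]
    i <- match(pat, rownames(xiT))
    if (anyNA(i)) stop("period ", periodId, ": patient ",
                       pat[which(is.na(i))[1]], " not in study registry")
    lam <- lam + exp(xiT[i, , drop = FALSE]) %*% computeEta(params@S[[s]])
  }
  if (!des$is_baseline[k]) {
    t <- as.character(des$treatment_id[k])
    m <- as.character(des$mechanism_id[k])
    thT <- params@thetaTilde[[t]]
    i <- match(pat, rownames(thT))
    if (anyNA(i)) stop("period ", periodId, ": patient ",
                       pat[which(is.na(i))[1]], " not in treatment registry")
    phi <- computePhi(params@M[[m]], params@R[[t]])
    lam <- lam + exp(thT[i, , drop = FALSE]) %*% phi
  }
  lam
}

#' Poisson log-likelihood of one period
#'
#' `sum_ij [ Y log(C lambda) - C lambda - log(Y!) ]`, with the exposure
#' `C` per patient row. Cells with `lambda = 0, Y = 0` contribute 0;
#' `lambda = 0` with `Y > 0` yields `-Inf`. The `log(Y!)` constant is
#' included so the value is a true log-probability, comparable across
#' fits.
#'
#' @param Y N x J nonnegative integer matrix.
#' @param C positive exposure vector of length N.
#' @param lambda N x J nonnegative intensity matrix.
#' @return scalar log-likelihood.
#' @export
poissonLogLik <- function(Y, C, lambda) {
  if (!identical(dim(Y), dim(lambda))) stop("poissonLogLik: shape mismatch")
  if (length(C) != nrow(Y)) stop("poissonLogLik: C length mismatch")
  if (any(Y < 0) || any(lambda < 0)) stop("poissonLogLik: negative input")
  mu <- C * lambda  # recycles C down each column
  ll <- -mu - lfactorial(Y)
  pos <- Y > 0
  ll[pos] <- ll[pos] + Y[pos] * log(mu[pos])
  sum(ll)
}

#' Gaussian random-walk (NDLM) + anchoring log-prior of a pattern matrix
#'
#' For each row k of `A`: Normal(0, sigmaAnchor^2) log-density on the
#' anchor columns (lowest observed severity of each AE name) plus
#' Normal(A[k, j], sigmaG^2) log-density of `A[k, jprime]` for each
#' adjacent-severity pair (j, jprime). The anchors identify the matrix
#' under the softmax's translation invariance; the chain smooths
#' intensities across severity grades of one name.
#'
#' @param A K x J real matrix.
#' @param adjacency adjacency structure from [buildAdjacency()].
#' @param sigmaG chain (random-walk) scale.
#' @param sigmaAnchor anchor scale.
#' @return scalar log-prior.
#' @export
ndlmLogPrior <- function(A, adjacency, sigmaG, sigmaAnchor) {
  t <- .ndlmTerms(A, adjacency, sigmaG, sigmaAnchor)
  t[["anchor"]] + t[["chain"]]
}

.ndlmTerms <- function(A, adjacency, sigmaG, sigmaAnchor) {
  if (sigmaG <= 0 || sigmaAnchor <= 0) stop("sigma must be > 0")
  J <- ncol(A)
  anc <- adjacency$anchors
  prs <- adjacency$pairs
  if (length(anc) && max(anc) > J) stop("anchor column outside matrix")
  if (nrow(prs) && max(prs) > J) stop("adjacency column outside matrix")
  aterm <- sum(stats::dnorm(A[, anc, drop = FALSE], 0, sigmaAnchor, log = TRUE))
  cterm <- if (nrow(prs))
    sum(stats::dnorm(A[, prs[, "jprime"], drop = FALSE],
                     A[, prs[, "j"], drop = FALSE], sigmaG, log = TRUE))
  else 0
  c(anchor = aterm, chain = cterm)
}

.ndlmGrad <- function(A, adjacency, sigmaG, sigmaAnchor) {
  G <- matrix(0, nrow(A), ncol(A))
  anc <- adjacency$anchors
  G[, anc] <- G[, anc, drop = FALSE] - A[, anc, drop = FALSE] / sigmaAnchor^2
  prs <- adjacency$pairs
  for (r in seq_len(nrow(prs))) {
    j <- prs[r, "j"]; jp <- prs[r, "jprime"]
    d <- (A[, jp] - A[, j]) / sigmaG^2
    G[, jp] <- G[, jp] - d
    G[, j] <- G[, j] + d
  }
  G
}

#' Joint log-posterior of the hierarchical Poisson factorization
#'
#' Sums the Poisson log-likelihood over all periods (with the
#' treatment term zeroed at baseline) and the NDLM + anchoring
#' log-priors of every mechanism mean-effect matrix M (anchor scale
#' `sigmaM`), treatment random-effect matrix R (`sigmaR`) and study
#' effect matrix S (`sigmaS`), all with chain scale `sigmaG`. The
#' patient loadings thetaTilde and xiTilde carry no prior (flat,
#' box-bounded during optimization).
#'
#' @param params an [AEModelParams-class] object.
#' @param data an [AECountData-class] object.
#' @param adjacency adjacency structure from [buildAdjacency()].
#' @param hyper an [AEHyperParams-class] object.
#' @return list with `total` and the breakdown: `poisson_by_period`
#'   (named vector), `ndlm_M`, `ndlm_R`, `ndlm_S`, `anchor_M`,
#'   `anchor_R`, `anchor_S`.
#' @export
logPosterior <- function(params, data, adjacency, hyper) {
  des <- aeDesign(data)
  pois <- numeric(nrow(des))
  names(pois) <- as.character(des$period_id)
  for (p in names(pois)) {
    lam <- computeLambda(p, params, data)
    pois[p] <- poissonLogLik(aeCounts(data)[[p]], aeExposure(data)[[p]], lam)
  }
  sumTerms <- function(mats, sigmaAnchor) {
    a <- 0; ch <- 0
    for (A in mats) {
      t <- .ndlmTerms(A, adjacency, hyper@sigmaG, sigmaAnchor)
      a <- a + t[["anchor"]]; ch <- ch + t[["chain"]]
    }
    c(a, ch)
  }
  tm <- sumTerms(params@M, hyper@sigmaM)
  tr <- sumTerms(params@R, hyper@sigmaR)
  ts <- sumTerms(params@S, hyper@sigmaS)
  list(total = sum(pois) + sum(tm) + sum(tr) + sum(ts),
       poisson_by_period = pois,
       ndlm_M = tm[2], ndlm_R = tr[2], ndlm_S = ts[2],
       anchor_M = tm[1], anchor_R = tr[1], anchor_S = ts[1])
}

#' Analytic gradient of the joint log-posterior
#'
#' Exact gradient with respect to every free parameter, computed by
#' backpropagation through the exp and row-softmax reparametrizations.
#' Pattern-matrix gradients accumulate the likelihood signal over all
#' periods sharing the treatment (or study) before the softmax
#' backprop, then add the prior terms.
#'
#' @inheritParams logPosterior
#' @return an [AEModelParams-class]-shaped list of gradients (slots
#'   `thetaTilde`, `M`, `R`, `xiTilde`, `S`).
#' @export
logPosteriorGradient <- function(params, data, adjacency, hyper) {
  des <- aeDesign(data)
  zeros <- function(lst) lapply(lst, function(A) array(0, dim(A), dimnames(A)))
  g <- list(thetaTilde = zeros(params@thetaTilde), M = zeros(params@M),
            R = zeros(params@R), xiTilde = zeros(params@xiTilde),
            S = zeros(params@S))
  # upstream gradients w.r.t. phi (per treatment) and eta (per study)
  gPhi <- zeros(params@R)
  for (t in setdiff(names(params@thetaTilde), names(gPhi)))
    gPhi[[t]] <- array(0, dim(params@M[[1]]))
  gEta <- zeros(params@S)

  phis <- list()
  for (k in which(!des$is_baseline)) {
    t <- as.character(des$treatment_id[k])
    if (is.null(phis[[t]])) {
      m <- as.character(des$mechanism_id[k])
      phis[[t]] <- computePhi(params@M[[m]], params@R[[t]])
    }
  }
  etas <- lapply(params@S, computeEta)

  for (k in seq_len(nrow(des))) {
    p <- as.character(des$period_id[k])
    Y <- aeCounts(data)[[p]]
    C <- aeExposure(data)[[p]]
    lam <- computeLambda(p, params, data)
    G <- -matrix(C, nrow(Y), ncol(Y))
    pos <- Y > 0
    G[pos] <- G[pos] + Y[pos] / lam[pos]
    s <- as.character(des$study_id[k])
    if (length(params@S) && s %in% names(params@S)) {
      xiT <- params@xiTilde[[s]]
      i <- match(rownames(Y), rownames(xiT))
      xi <- exp(xiT[i, , drop = FALSE])
      g$xiTilde[[s]][i, ] <- g$xiTilde[[s]][i, , drop = FALSE] +
        (G %*% t(etas[[s]])) * xi
      gEta[[s]] <- gEta[[s]] + t(xi) %*% G
    }
    if (!des$is_baseline[k]) {
      t <- as.character(des$treatment_id[k])
      thT <- params@thetaTilde[[t]]
      i <- match(rownames(Y), rownames(thT))
      th <- exp(thT[i, , drop = FALSE])
      g$thetaTilde[[t]][i, ] <- g$thetaTilde[[t]][i, , drop = FALSE] +
        (G %*% t(phis[[t]])) * th
      gPhi[[t]] <- gPhi[[t]] + t(th) %*% G
    }
  }

  softmaxBack <- function(P, up) P * (up - rowSums(up * P))

  for (k in which(!des$is_baseline)) {
    t <- as.character(des$treatment_id[k])
    if (is.null(phis[[t]])) next
    m <- as.character(des$mechanism_id[k])
    dA <- softmaxBack(phis[[t]], gPhi[[t]])
    g$M[[m]] <- g$M[[m]] + dA
    if (t %in% names(g$R)) g$R[[t]] <- g$R[[t]] + dA
    phis[[t]] <- NULL  # each treatment backpropagated once
  }
  for (s in names(params@S))
    g$S[[s]] <- g$S[[s]] + softmaxBack(etas[[s]], gEta[[s]])

  for (m in names(params@M))
    g$M[[m]] <- g$M[[m]] +
      .ndlmGrad(params@M[[m]], adjacency, hyper@sigmaG, hyper@sigmaM)
  for (t in names(params@R))
    g$R[[t]] <- g$R[[t]] +
      .ndlmGrad(params@R[[t]], adjacency, hyper@sigmaG, hyper@sigmaR)
  for (s in names(params@S))
    g$S[[s]] <- g$S[[s]] +
      .ndlmGrad(params@S[[s]], adjacency, hyper@sigmaG, hyper@sigmaS)
  g
}

#' Hyperparameter constructor
#'
#' Defaults suit a pooled oncology meta-analysis: K = 15 treatment
#' patterns, L = 2 study patterns, sigmaG = 1.5 (severity grades span
#' only 1-4), sigmaM = sigmaS = 5 (wide enough for any pattern),
#' sigmaR = 0.5 (random effects about 10 percent of the mean effect).
#'
#' @param K,L pattern counts.
#' @param sigmaG,sigmaM,sigmaR,sigmaS prior scales.
#' @return an [AEHyperParams-class] object.
#' @export
aeHyperParams <- function(K = 15, L = 2, sigmaG = 1.5, sigmaM = 5,
                          sigmaR = 0.5, sigmaS = 5) {
  new("AEHyperParams", K = K, L = L, sigmaG = sigmaG, sigmaM = sigmaM,
      sigmaR = sigmaR, sigmaS = sigmaS)
}
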