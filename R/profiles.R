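#' Fast patient-level safety-profile estimation with fixed patterns
#'
#' For a new patient on a treatment whose pattern matrix `phi` has
#' already been estimated, maximizes the Poisson log-probability of the
#' patient's cumulative AE counts over the K loadings only:
#' `sum_j log Poisson(y_j | C sum_k exp(thetaTilde_k) phi_kj)`.
#' The study background term is omitted (its influence on a single new
#' patient is assumed negligible). An optional Normal prior on
#' thetaTilde turns the optimum into a MAP estimate; the default prior
#' is flat within box bounds.
#'
#' @param y length-J nonnegative integer count vector.
#' @param C positive exposure (treatment cycles observed so far).
#' @param phi K x J row-stochastic pattern matrix.
#' @param prior optional `list(mean =, sd =)` Normal prior on each
#'   thetaTilde component (default NULL: flat).
#' @param bounds box bounds on thetaTilde (default c(-15, 15)).
#' @param warmStart optional length-K thetaTilde starting point (e.g.
#'   the previous estimate when re-estimating after each new AE); the
#'   optimum is insensitive to it at the optimizer tolerance.
#' @return an [AEProfileEstimate-class] object.
#' @export
estimateProfile <- function(y, C, phi, prior = NULL, bounds = c(-15, 15),
                            warmStart = NULL) {
  if (!is.matrix(phi)) phi <- matrix(phi, nrow = 1)
  J <- ncol(phi)
  K <- nrow(phi)
  if (length(y) != J) stop("estimateProfile: length(y) != ncol(phi)")
  if (any(y < 0) || any(y != round(y))) stop("y must be nonnegative integers")
  if (C <= 0) stop("C must be positive")
  dead <- colSums(phi) == 0 & y > 0
  if (any(dead))
    warning("counts observed on AE types with zero pattern mass (column ",
            which(dead)[1], "): those cells cannot be fitted")

  fn <- function(tt) {
    lam <- as.numeric(exp(tt) %*% phi)
    mu <- C * lam
    ll <- sum(-mu - lfactorial(y)) + sum(y[y > 0] * log(mu[y > 0]))
    if (!is.null(prior))
      ll <- ll + sum(stats::dnorm(tt, prior$mean, prior$sd, log = TRUE))
    -ll
  }
  gr <- function(tt) {
    th <- exp(tt)
    lam <- as.numeric(th %*% phi)
    g <- numeric(J)
    g <- -rep(C, J)
    pos <- y > 0
    g[pos] <- g[pos] + y[pos] / lam[pos]
    gt <- as.numeric(phi %*% g) * th
    if (!is.null(prior))
      gt <- gt - (tt - prior$mean) / prior$sd^2
    -gt
  }
  start <- if (!is.null(warmStart)) pmin(pmax(warmStart, bounds[1]), bounds[2])
           else rep(max(log(sum(y) / (C * K)), bounds[1]), K)
  if (!all(is.finite(start))) start <- rep(bounds[1], K)
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = bounds[1], upper = bounds[2],
                      control = list(maxit = 1000, pgtol = 1e-10,
                                     factr = 1e3))
  new("AEProfileEstimate", thetaHat = exp(opt$par), thetaTilde = opt$par,
      logProb = -opt$value, converged = opt$convergence == 0,
      exposure = C)
}

#' Predicted per-cycle AE intensities
#'
#' `lambda_j = sum_k thetaHat_k phi_kj`: the mean number of occurrences
#' of AE type j per future treatment cycle. High-lambda types are the
#' ones to monitor.
#'
#' @param thetaHat length-K nonnegative loadings (or an
#'   [AEProfileEstimate-class]).
#' @param phi K x J row-stochastic pattern matrix.
#' @return named length-J nonnegative vector.
#' @export
predictLambda <- function(thetaHat, phi) {
  if (is(thetaHat, "AEProfileEstimate")) thetaHat <- thetaHat@thetaHat
  if (!is.matrix(phi)) phi <- matrix(phi, nrow = 1)
  if (length(thetaHat) != nrow(phi))
    stop("predictLambda: length(thetaHat) != nrow(phi)")
  lam <- as.numeric(thetaHat %*% phi)
  names(lam) <- colnames(phi)
  lam
}

#' Rank AE types by predicted intensity
#'
#' Descending-lambda table of the AE types most likely to occur, with
#' ties broken by label lexicographic order. `minSeverity` restricts to
#' severe types first (e.g. 3 for the severe block of a monitoring
#' table).
#'
#' @param lambda length-J intensity vector.
#' @param index AE-type index data.frame.
#' @param topN number of rows returned (more than J returns all).
#' @param minSeverity optional minimum severity filter applied before
#'   ranking.
#' @return data.frame with columns `label`, `name`, `severity`,
#'   `lambda`.
#' @export
rankAETypes <- function(lambda, index, topN = 10, minSeverity = NULL) {
  if (length(lambda) != nrow(index))
    stop("rankAETypes: lambda length != index size")
  d <- data.frame(label = index$label, name = index$name,
                  severity = index$severity, lambda = as.numeric(lambda),
                  stringsAsFactors = FALSE)
  if (!is.null(minSeverity)) d <- d[d$severity >= minSeverity, , drop = FALSE]
  d <- d[order(-d$lambda, d$label), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, topN)
}

#' Compare two safety-profile estimates
#'
#' Stability report between two estimates of the same patient (e.g.
#' profiles at the end of cycle 2 vs cycle 4): componentwise
#' differences, maximum absolute deviation and Spearman rank
#' correlation of the loadings. Estimates near the diagonal (small
#' deviations, high correlation) indicate a stable profile.
#'
#' @param a,b [AEProfileEstimate-class] objects (or numeric loading
#'   vectors) with the same K.
#' @return list with `difference`, `maxAbsDeviation`,
#'   `rankCorrelation`.
#' @export
compareProfiles <- function(a, b) {
  va <- if (is(a, "AEProfileEstimate")) a@thetaHat else as.numeric(a)
  vb <- if (is(b, "AEProfileEstimate")) b@thetaHat else as.numeric(b)
  if (length(va) != length(vb)) stop("compareProfiles: K mismatch")
  rc <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_
        else stats::cor(va, vb, method = "spearman")
  list(difference = va - vb, maxAbsDeviation = max(abs(va - vb)),
       rankCorrelation = rc)
}
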