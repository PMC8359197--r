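test_that("softmax rows are simplex, translation-invariant and stable", {
  expect_equal(softmaxRows(matrix(0, 1, 4)), matrix(0.25, 1, 4))
  expect_equal(softmaxRows(matrix(log(1:3), 1)), matrix((1:3) / 6, 1))
  A <- matrix(rnorm(12), 3, 4)
  expect_equal(softmaxRows(A + 7.3), softmaxRows(A))
  expect_equal(unname(rowSums(softmaxRows(A))), rep(1, 3),
               tolerance = 1e-12)
  # large magnitudes: max-subtraction keeps it finite
  big <- matrix(c(1000, 1001, -1000, 5), 2, 2)
  expect_true(all(is.finite(softmaxRows(big))))
  expect_error(softmaxRows(matrix(c(1, NaN), 1)), "non-finite")
})

test_that("phi and eta construction matches direct evaluation", {
  M <- matrix(c(0.3, -1, 2, 0.5, 0, 1), 2, 3)
  R <- matrix(c(0.1, 0.2, -0.3, 0, 0.4, -0.1), 2, 3)
  direct <- t(apply(M + R, 1, function(v) exp(v) / sum(exp(v))))
  expect_equal(computePhi(M, R), direct)
  # a treatment without a random-effect matrix uses M alone
  expect_equal(computePhi(M, NULL),
               t(apply(M, 1, function(v) exp(v) / sum(exp(v)))))
  expect_equal(computePhi(matrix(0, 2, 3), matrix(0, 2, 3)),
               matrix(1 / 3, 2, 3))
  expect_error(computePhi(M, R[, 1:2]), "shape")
  expect_equal(computeEta(matrix(0, 1, 5)), matrix(0.2, 1, 5))
})

test_that("lambda assembles treatment and study terms; baseline ignores treatment parameters", {
  sim <- tinySim(n = 8, nNames = 3, K = 2, L = 1, seed = 3)
  params <- randomizeParams(sim$truth$params, seed = 1)
  lamBase <- computeLambda("p01", params, sim$data)
  # perturbing thetaTilde / M / R leaves the baseline period untouched
  p2 <- params
  p2@thetaTilde <- lapply(p2@thetaTilde, function(A) A + 3)
  p2@M <- lapply(p2@M, function(A) A - 1)
  expect_equal(computeLambda("p01", p2, sim$data), lamBase)
  # but the treatment period responds
  expect_false(isTRUE(all.equal(computeLambda("p02", p2, sim$data),
                                computeLambda("p02", params, sim$data))))
  # adding ln 2 to thetaTilde exactly doubles the treatment component
  p3 <- params
  p3@thetaTilde <- lapply(p3@thetaTilde, function(A) A + log(2))
  lam1 <- computeLambda("p02", params, sim$data)
  lam2 <- computeLambda("p02", p3, sim$data)
  alpha <- computeLambda("p02", params, sim$data) * 0
  # isolate alpha by zeroing theta (push to -Inf is not allowed; use L-only params)
  pAlpha <- params
  pAlpha@thetaTilde <- lapply(pAlpha@thetaTilde, function(A) A * 0 - 700)
  alpha <- computeLambda("p02", pAlpha, sim$data)
  expect_equal(lam2 - alpha, 2 * (lam1 - alpha), tolerance = 1e-8)
  expect_true(all(lamBase > 0))
})

test_that("lambda arithmetic: single uniform pattern", {
  # K=1, L=1, theta=2, xi=1, both rows uniform over J=4 -> every cell 0.75
  events <- data.frame(patient_id = "A", period_id = "p1",
                       ae_name = paste0("AE", 1:4), severity = 1, count = 0)
  design <- data.frame(period_id = "p1", study_id = 1, treatment_id = "T1",
                       mechanism_id = "M1", n_cycles = 1,
                       is_baseline = FALSE)
  enrollment <- data.frame(period_id = "p1", patient_id = "A")
  idx <- buildAETypeIndex(events)
  cd <- assembleCounts(events, design, enrollment, idx)
  params <- new("AEModelParams",
                thetaTilde = list(T1 = matrix(log(2), 1, 1,
                                              dimnames = list("A", NULL))),
                M = list(M1 = matrix(0, 1, 4)), R = list(),
                xiTilde = list(`1` = matrix(0, 1, 1,
                                            dimnames = list("A", NULL))),
                S = list(`1` = matrix(0, 1, 4)))
  expect_equal(unname(computeLambda("p1", params, cd)),
               matrix(0.75, 1, 4))
})

test_that("Poisson log-likelihood matches the pmf and its invariances", {
  # single cell y=3, C=2, lambda=1.5: Poisson(3) at 3
  Y <- matrix(3L, 1, 1)
  expect_equal(poissonLogLik(Y, 2, matrix(1.5, 1, 1)),
               3 * log(3) - 3 - log(6))
  expect_equal(poissonLogLik(Y, 2, matrix(1.5, 1, 1)),
               dpois(3, 3, log = TRUE))
  # all-zero counts: -sum(C * lambda)
  Y0 <- matrix(0L, 2, 3)
  lam <- matrix(runif(6), 2, 3)
  C <- c(2, 5)
  expect_equal(poissonLogLik(Y0, C, lam), -sum(C * lam))
  # C and lambda only enter through their product
  Y <- matrix(rpois(6, 2), 2, 3)
  expect_equal(poissonLogLik(Y, C * 3, lam / 3), poissonLogLik(Y, C, lam))
  # lambda=0, Y=0 contributes 0; lambda=0, Y>0 gives -Inf
  expect_equal(poissonLogLik(matrix(0L), 1, matrix(0)), 0)
  expect_equal(poissonLogLik(matrix(2L), 1, matrix(0)), -Inf)
  expect_error(poissonLogLik(matrix(-1), 1, matrix(1)), "negative")
})

test_that("NDLM prior closed forms and brute-force agreement", {
  idx <- buildAETypeIndex(data.frame(
    patient_id = "P", period_id = "p",
    ae_name = c("A", "A", "B", "B"), severity = c(1, 2, 1, 2), count = 1))
  adj <- buildAdjacency(idx)
  sG <- 1.5; sA <- 5
  # zero matrix: anchors at their mode, pairs identical
  A <- matrix(0, 3, 4)
  expect_equal(ndlmLogPrior(A, adj, sG, sA),
               3 * (2 * dnorm(0, 0, sA, log = TRUE) +
                    2 * dnorm(0, 0, sG, log = TRUE)))
  # random matrix vs naive summation
  set.seed(9)
  A <- matrix(rnorm(8), 2, 4)
  naive <- 0
  for (k in 1:2) {
    for (j in adj$anchors) naive <- naive + dnorm(A[k, j], 0, sA, log = TRUE)
    for (r in seq_len(nrow(adj$pairs)))
      naive <- naive + dnorm(A[k, adj$pairs[r, "jprime"]],
                             A[k, adj$pairs[r, "j"]], sG, log = TRUE)
  }
  expect_equal(ndlmLogPrior(A, adj, sG, sA), naive, tolerance = 1e-12)
  expect_error(ndlmLogPrior(A[, 1:2], adj, sG, sA), "outside")
})

test_that("log-posterior equals the naive loop oracle on small instances", {
  # several shapes: with/without baseline, L=0 and L=1, K in {1,2}
  for (cfg in list(list(n = 4, nm = 3, K = 2, L = 1, seed = 11),
                   list(n = 5, nm = 2, K = 1, L = 1, seed = 12),
                   list(n = 3, nm = 3, K = 2, L = 1, seed = 13))) {
    sim <- tinySim(n = cfg$n, nNames = cfg$nm, K = cfg$K, L = cfg$L,
                   seed = cfg$seed)
    hyper <- aeHyperParams(K = cfg$K, L = cfg$L)
    params <- randomizeParams(sim$truth$params, seed = cfg$seed + 1)
    lp <- logPosterior(params, sim$data, sim$truth$adjacency, hyper)
    expect_equal(lp$total,
                 naiveLogPosterior(params, sim$data, sim$truth$adjacency,
                                   hyper),
                 tolerance = 1e-10)
    # breakdown components sum to the total
    expect_equal(lp$total,
                 sum(lp$poisson_by_period) + lp$ndlm_M + lp$ndlm_R +
                   lp$ndlm_S + lp$anchor_M + lp$anchor_R + lp$anchor_S,
                 tolerance = 1e-9)
  }
})

test_that("a loading row of a patient absent from all periods is inert", {
  sim <- tinySim(n = 5, nNames = 3, K = 2, L = 1, seed = 4)
  hyper <- aeHyperParams(K = 2, L = 1)
  params <- randomizeParams(sim$truth$params, seed = 5)
  ghost <- matrix(0.3, 1, 2, dimnames = list("GHOST", NULL))
  params@thetaTilde$T1 <- rbind(params@thetaTilde$T1, ghost)
  lp1 <- logPosterior(params, sim$data, sim$truth$adjacency, hyper)$total
  params@thetaTilde$T1["GHOST", ] <- 99
  lp2 <- logPosterior(params, sim$data, sim$truth$adjacency, hyper)$total
  expect_identical(lp1, lp2)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(20)
  worst <- 0
  for (rep in 1:6) {
    sim <- tinySim(n = 4, nNames = 3, K = 2, L = 1, seed = 30 + rep)
    hyper <- aeHyperParams(K = 2, L = 1)
    params <- randomizeParams(sim$truth$params, seed = 60 + rep)
    g <- AEpatterns:::.flattenGrad(
      logPosteriorGradient(params, sim$data, sim$truth$adjacency, hyper))
    num <- numericLPGradient(params, sim$data, sim$truth$adjacency, hyper)
    rel <- max(abs(g - num) / pmax(abs(num), 1))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("translation of pattern-matrix rows moves only the prior", {
  sim <- tinySim(n = 5, nNames = 3, K = 2, L = 1, seed = 8)
  hyper <- aeHyperParams(K = 2, L = 1)
  params <- randomizeParams(sim$truth$params, seed = 9)
  adj <- sim$truth$adjacency
  lp <- logPosterior(params, sim$data, adj, hyper)
  shifted <- params
  shifted@M$M1 <- shifted@M$M1 + 2   # constant on every row
  lps <- logPosterior(shifted, sim$data, adj, hyper)
  expect_equal(lps$poisson_by_period, lp$poisson_by_period,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(lps$anchor_M, lp$anchor_M)))
  shiftedS <- params
  shiftedS@S$`1` <- shiftedS@S$`1` - 1.3
  lpS <- logPosterior(shiftedS, sim$data, adj, hyper)
  expect_equal(lpS$poisson_by_period, lp$poisson_by_period,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(lpS$anchor_S, lp$anchor_S)))
})

test_that("phi and eta rows stay on the simplex for any finite parameters", {
  set.seed(77)
  for (rep in 1:10) {
    A <- matrix(rnorm(12, sd = 10^runif(1, -2, 2)), 3, 4)
    expect_equal(unname(rowSums(softmaxRows(A))), rep(1, 3),
                 tolerance = 1e-12)
    expect_true(all(softmaxRows(A) >= 0))
  }
})
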