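# Small in-code fixtures shared across test files.

# simulate a small dataset; returns the full simulateAEData() list
tinySim <- function(n = 12, nNames = 3, K = 2, L = 1, seed = 7, ...) {
  simulateAEData(simSpecMinimal(n = n, nNames = nNames, K = K, L = L, ...),
                 seed = seed)
}

# replace every free parameter by iid Normal(0, scale) draws, away from
# the box bounds, for oracle and gradient checks
randomizeParams <- function(params, seed, scale = 0.5) {
  set.seed(seed)
  jig <- function(A) array(stats::rnorm(length(A), 0, scale), dim(A),
                           dimnames(A))
  params@M <- lapply(params@M, jig)
  params@R <- lapply(params@R, jig)
  params@S <- lapply(params@S, jig)
  params@thetaTilde <- lapply(params@thetaTilde, jig)
  params@xiTilde <- lapply(params@xiTilde, jig)
  params
}

# central finite differences of the log-posterior along every
# coordinate, with steps scaled to the coordinate magnitude
numericLPGradient <- function(params, data, adjacency, hyper) {
  v <- AEpatterns:::.flattenParams(params)
  f <- function(vv) logPosterior(AEpatterns:::.unflattenParams(vv, params),
                                 data, adjacency, hyper)$total
  vapply(seq_along(v), function(i) {
    h <- 1e-6 * max(1, abs(v[i]))
    e <- v
    e[i] <- v[i] + h
    up <- f(e)
    e[i] <- v[i] - h
    (up - f(e)) / (2 * h)
  }, numeric(1))
}

# write an events/design/enrollment CSV triple into a temp dir
writeCSVTriple <- function(events, design, enrollment,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ep <- file.path(dir, "events.csv")
  dp <- file.path(dir, "design.csv")
  np <- file.path(dir, "enrollment.csv")
  utils::write.csv(events, ep, row.names = FALSE, na = "")
  utils::write.csv(design, dp, row.names = FALSE, na = "")
  utils::write.csv(enrollment, np, row.names = FALSE, na = "")
  list(events = ep, design = dp, enrollment = np)
}

# the three-study, ten-period pooled breast-cancer design as tables
threeStudyTables <- function() {
  design <- data.frame(
    period_id = sprintf("p%02d", 1:10),
    study_id = c(1, 1, 1, 2, 3, 3, 3, 3, 3, 3),
    treatment_id = c(NA, "AC", "T", "FAC", NA, "A", "CMF", NA, "AC", "CMF"),
    mechanism_id = c(NA, "NAS", "MIT", "NAS", NA, "NAS", "NAS", NA, "NAS",
                     "NAS"),
    n_cycles = c(NA, 4, 4, 6, NA, 4, 3, NA, 4, 3),
    is_baseline = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                    FALSE, FALSE),
    stringsAsFactors = FALSE)
  counts <- c(1625, 1625, 1583, 731, 480, 480, 459, 481, 481, 472)
  arm <- c(1, 1, 1, 2, 3, 3, 3, 4, 4, 4)
  enrollment <- do.call(rbind, lapply(1:10, function(k)
    data.frame(period_id = design$period_id[k],
               patient_id = sprintf("A%d-%04d", arm[k], seq_len(counts[k])),
               stringsAsFactors = FALSE)))
  list(design = design, enrollment = enrollment, n_per_period = counts)
}
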