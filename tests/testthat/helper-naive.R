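# Independent loop-based oracle for the joint log-posterior: plain
# dpois/dnorm element loops, softmax recomputed per row from first
# principles. Deliberately shares no code with the package internals.
naiveLogPosterior <- function(params, data, adjacency, hyper) {
  des <- aeDesign(data)
  total <- 0
  for (k in seq_len(nrow(des))) {
    p <- as.character(des$period_id[k])
    Y <- aeCounts(data)[[p]]
    C <- aeExposure(data)[[p]]
    s <- as.character(des$study_id[k])
    for (i in seq_len(nrow(Y))) {
      for (j in seq_len(ncol(Y))) {
        lam <- 0
        if (length(params@S) && s %in% names(params@S)) {
          S <- params@S[[s]]
          xi <- exp(params@xiTilde[[s]][rownames(Y)[i], ])
          for (l in seq_len(nrow(S))) {
            w <- exp(S[l, ]) / sum(exp(S[l, ]))
            lam <- lam + xi[l] * w[j]
          }
        }
        if (!des$is_baseline[k]) {
          tr <- as.character(des$treatment_id[k])
          m <- as.character(des$mechanism_id[k])
          A <- params@M[[m]]
          if (tr %in% names(params@R)) A <- A + params@R[[tr]]
          th <- exp(params@thetaTilde[[tr]][rownames(Y)[i], ])
          for (kk in seq_len(nrow(A))) {
            w <- exp(A[kk, ]) / sum(exp(A[kk, ]))
            lam <- lam + th[kk] * w[j]
          }
        }
        total <- total + stats::dpois(Y[i, j], C[i] * lam, log = TRUE)
      }
    }
  }
  priorOne <- function(A, sigmaAnchor) {
    v <- 0
    for (kk in seq_len(nrow(A))) {
      for (j in adjacency$anchors)
        v <- v + stats::dnorm(A[kk, j], 0, sigmaAnchor, log = TRUE)
      if (nrow(adjacency$pairs) > 0)
        for (r in seq_len(nrow(adjacency$pairs)))
          v <- v + stats::dnorm(A[kk, adjacency$pairs[r, "jprime"]],
                                A[kk, adjacency$pairs[r, "j"]],
                                hyper@sigmaG, log = TRUE)
    }
    v
  }
  for (m in names(params@M)) total <- total + priorOne(params@M[[m]], hyper@sigmaM)
  for (tr in names(params@R)) total <- total + priorOne(params@R[[tr]], hyper@sigmaR)
  for (s in names(params@S)) total <- total + priorOne(params@S[[s]], hyper@sigmaS)
  unname(total)
}
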