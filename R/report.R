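#' Pattern intensity table
#'
#' Human-readable listing of one treatment's patterns in descending
#' order of log-probability increase. For each pattern, AE types are
#' sorted by occurrence intensity (the softmax-normalized phi row,
#' expressed in percent) and filtered by a floor; a severe sub-listing
#' shows the top types at or above a severity threshold. Default floors
#' follow the usual reading rule: top 8 types above 1 percent, plus top 2
#' types of severity >= 3 above 0.1 percent.
#'
#' @param phi K x J row-stochastic pattern matrix of one treatment.
#' @param index AE-type index data.frame.
#' @param order pattern order (e.g. from [patternOrder()]); default
#'   1..K.
#' @param topN types listed per pattern (default 8).
#' @param floor minimum intensity listed, as a fraction (default 0.01).
#' @param severeTopN severe types listed per pattern (default 2).
#' @param severeFloor severe-listing floor (default 0.001).
#' @param minSeverity severity threshold of the severe listing
#'   (default 3).
#' @return data.frame with columns `pattern` (position in `order`),
#'   `ae_type`, `intensity_pct`, `severe` (logical: row comes from the
#'   severe sub-listing).
#' @export
patternTable <- function(phi, index, order = NULL, topN = 8, floor = 0.01,
                         severeTopN = 2, severeFloor = 0.001,
                         minSeverity = 3) {
  K <- nrow(phi)
  if (is.null(order)) order <- seq_len(K)
  out <- NULL
  for (pos in seq_along(order)) {
    k <- order[pos]
    v <- phi[k, ]
    main <- rankAETypes(v, index, topN = topN)
    main <- main[main$lambda > floor, , drop = FALSE]
    sev <- rankAETypes(v, index, topN = severeTopN,
                       minSeverity = minSeverity)
    sev <- sev[sev$lambda > severeFloor, , drop = FALSE]
    sev <- sev[!sev$label %in% main$label, , drop = FALSE]
    block <- rbind(
      if (nrow(main)) data.frame(pattern = pos, ae_type = main$label,
                                 intensity_pct = 100 * main$lambda,
                                 severe = FALSE),
      if (nrow(sev)) data.frame(pattern = pos, ae_type = sev$label,
                                intensity_pct = 100 * sev$lambda,
                                severe = TRUE))
    out <- rbind(out, block)
  }
  if (is.null(out))
    out <- data.frame(pattern = integer(), ae_type = character(),
                      intensity_pct = numeric(), severe = logical())
  rownames(out) <- NULL
  out
}

#' Distribution summary of the patient loadings of one treatment
#'
#' For each pattern k of the treatment: quantiles of the theta column,
#' the fraction of patients with a near-zero loading, and histogram
#' counts (most patients typically carry almost none of a pattern, a
#' few carry a lot).
#'
#' @param fit an [AEFit-class] object.
#' @param treatment treatment id.
#' @param nearZero near-zero threshold on the theta scale
#'   (default 0.01).
#' @param breaks histogram breaks passed to [graphics::hist()]-style
#'   binning via [base::cut()] (default 20 equal bins).
#' @return list with `quantiles` (patterns x probs matrix),
#'   `nearZeroFraction` (per pattern) and `histogram` (long data.frame
#'   pattern/bin_low/bin_high/count).
#' @export
thetaSummary <- function(fit, treatment, nearZero = 0.01, breaks = 20) {
  treatment <- as.character(treatment)
  if (!treatment %in% names(fit@params@thetaTilde))
    stop("unknown treatment '", treatment, "'; fitted treatments: ",
         paste(names(fit@params@thetaTilde), collapse = ", "))
  th <- exp(fit@params@thetaTilde[[treatment]])
  probs <- c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1)
  qs <- t(apply(th, 2, stats::quantile, probs = probs))
  rownames(qs) <- paste0("pattern", seq_len(nrow(qs)))
  nz <- colMeans(th < nearZero)
  hists <- NULL
  for (k in seq_len(ncol(th))) {
    rng <- range(th[, k])
    if (rng[1] == rng[2]) rng[2] <- rng[1] + 1e-9
    edges <- seq(rng[1], rng[2], length.out = breaks + 1)
    cnt <- table(cut(th[, k], edges, include.lowest = TRUE))
    hists <- rbind(hists, data.frame(
      pattern = k, bin_low = edges[-length(edges)], bin_high = edges[-1],
      count = as.integer(cnt)))
  }
  list(quantiles = qs, nearZeroFraction = nz, histogram = hists)
}
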