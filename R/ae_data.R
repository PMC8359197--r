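#' Read patient-level AE event and design tables
#'
#' Reads the three delimited text files describing a pooled multi-study
#' AE dataset: the long-format event table (one row per patient, period,
#' AE name, severity), the period design table, and the per-period
#' enrollment table. All cross-references are validated: severities must
#' be CTCAE grades 1-4, counts nonnegative integers, every event must
#' refer to a (patient, period) pair present in the enrollment, the
#' baseline flag must agree with missing treatment/mechanism ids, and
#' the mechanism must be a function of the treatment.
#'
#' @param eventsPath CSV with columns `patient_id`, `period_id`,
#'   `ae_name`, `severity`, `count`.
#' @param designPath CSV with columns `period_id`, `study_id`,
#'   `treatment_id`, `mechanism_id`, `n_cycles`, `is_baseline`
#'   (treatment/mechanism/cycles empty or NA on baseline rows).
#' @param enrollmentPath CSV with columns `period_id`, `patient_id` and
#'   optionally `exposure` (per-patient override of the period's cycle
#'   count, e.g. for mid-period discontinuation).
#' @return list with elements `events`, `design`, `enrollment`
#'   (data.frames).
#' @export
readAEEvents <- function(eventsPath, designPath, enrollmentPath) {
  for (p in c(eventsPath, designPath, enrollmentPath))
    if (!file.exists(p)) stop("file not found: ", p)
  events <- utils::read.csv(eventsPath, stringsAsFactors = FALSE)
  design <- utils::read.csv(designPath, stringsAsFactors = FALSE)
  enrollment <- utils::read.csv(enrollmentPath, stringsAsFactors = FALSE)

  .requireCols(events, c("patient_id", "period_id", "ae_name", "severity",
                         "count"), eventsPath)
  .requireCols(design, c("period_id", "study_id", "treatment_id",
                         "mechanism_id", "n_cycles", "is_baseline"),
               designPath)
  .requireCols(enrollment, c("period_id", "patient_id"), enrollmentPath)

  events$patient_id <- as.character(events$patient_id)
  events$period_id <- as.character(events$period_id)
  events$ae_name <- as.character(events$ae_name)
  enrollment$patient_id <- as.character(enrollment$patient_id)
  enrollment$period_id <- as.character(enrollment$period_id)
  design$period_id <- as.character(design$period_id)
  design$treatment_id[design$treatment_id %in% c("", "NA")] <- NA
  design$mechanism_id[design$mechanism_id %in% c("", "NA")] <- NA
  design$is_baseline <- as.logical(design$is_baseline)

  validateAEEvents(events)
  validateAEDesign(design, enrollment)

  bad <- !paste(events$patient_id, events$period_id) %in%
    paste(enrollment$patient_id, enrollment$period_id)
  if (any(bad))
    stop("events reference (patient, period) pairs absent from enrollment, ",
         "e.g. row ", which(bad)[1], " (patient ", events$patient_id[which(bad)[1]],
         ", period ", events$period_id[which(bad)[1]], ")")

  list(events = events, design = design, enrollment = enrollment)
}

.requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
}

#' Validate an AE event table
#'
#' @param events data.frame with the event columns of [readAEEvents()].
#' @return the events, invisibly; errors name the first offending row.
#' @export
validateAEEvents <- function(events) {
  sev <- suppressWarnings(as.integer(events$severity))
  bad <- is.na(sev) | sev < 1 | sev > 4
  if (any(bad))
    stop("severity outside CTCAE grades 1..4 at row ", which(bad)[1],
         " (value '", events$severity[which(bad)[1]], "')")
  cnt <- suppressWarnings(as.numeric(events$count))
  bad <- is.na(cnt) | cnt < 0 | cnt != round(cnt)
  if (any(bad))
    stop("count must be a nonnegative integer at row ", which(bad)[1])
  invisible(events)
}

#' @keywords internal
validateAEDesign <- function(design, enrollment) {
  bl <- design$is_baseline
  if (any(bl != is.na(design$treatment_id)) ||
      any(bl != is.na(design$mechanism_id)))
    stop("is_baseline must hold exactly when treatment_id and mechanism_id ",
         "are missing")
  trt <- design[!bl, c("treatment_id", "mechanism_id")]
  map <- unique(trt)
  if (anyDuplicated(map$treatment_id))
    stop("mechanism_id must be a function of treatment_id")
  if (any(!bl & (is.na(design$n_cycles) | design$n_cycles <= 0)))
    stop("treatment periods need a positive n_cycles")
  if (anyDuplicated(design$period_id)) stop("duplicated period_id in design")
  dup <- duplicated(enrollment[c("period_id", "patient_id")])
  if (any(dup))
    stop("duplicated enrollment of patient ",
         enrollment$patient_id[which(dup)[1]], " in period ",
         enrollment$period_id[which(dup)[1]])
  unknown <- !enrollment$period_id %in% design$period_id
  if (any(unknown))
    stop("enrollment references unknown period ",
         enrollment$period_id[which(unknown)[1]])
  invisible(design)
}

#' Apply the pre-analysis filtering rules
#'
#' Removes stopword AE names (names so frequent that they would dominate
#' every pattern, such as alopecia in anticancer studies) and then drops
#' patients left without any AE from every period's enrollment: their
#' safety profiles would be estimated as zero and they carry no
#' information about the patterns. An optional frequency rule removes
#' any name occurring in more than `freqThreshold` of enrolled patients.
#'
#' @param events validated event data.frame.
#' @param enrollment enrollment data.frame (`period_id`, `patient_id`,
#'   optional `exposure`).
#' @param stopwords character vector of AE names removed at every
#'   severity (default none).
#' @param dropZeroAEPatients drop patients with no remaining events
#'   (default TRUE).
#' @param freqThreshold optional fraction in (0, 1]; names observed in
#'   more than this fraction of distinct enrolled patients are removed
#'   (default NULL, off).
#' @return list with `events`, `enrollment` (both filtered) and `report`,
#'   a list holding `removed_names` (data.frame name/events_removed) and
#'   `removed_patients` (character vector).
#' @export
applyAEFilters <- function(events, enrollment, stopwords = character(),
                           dropZeroAEPatients = TRUE, freqThreshold = NULL) {
  stopwords <- as.character(stopwords)
  if (!is.null(freqThreshold)) {
    nPat <- length(unique(enrollment$patient_id))
    byName <- tapply(events$patient_id, events$ae_name,
                     function(x) length(unique(x)))
    frequent <- names(byName)[byName / nPat > freqThreshold]
    stopwords <- union(stopwords, frequent)
  }
  drop <- events$ae_name %in% stopwords
  removedNames <- if (any(drop)) {
    agg <- stats::aggregate(count ~ ae_name, data = events[drop, ], FUN = sum)
    names(agg) <- c("name", "events_removed")
    agg
  } else data.frame(name = character(), events_removed = numeric())
  events <- events[!drop, , drop = FALSE]

  removedPatients <- character()
  if (dropZeroAEPatients) {
    keep <- unique(events$patient_id)
    removedPatients <- setdiff(unique(enrollment$patient_id), keep)
    enrollment <- enrollment[enrollment$patient_id %in% keep, , drop = FALSE]
  }
  rownames(events) <- NULL
  rownames(enrollment) <- NULL
  list(events = events, enrollment = enrollment,
       report = list(removed_names = removedNames,
                     removed_patients = removedPatients))
}

#' Build the shared AE-type vocabulary
#'
#' One column per observed (name, severity) pair, ordered
#' lexicographically by name then severity ascending, labelled
#' `"NAME_severity"` (e.g. `"VOMIT_2"`).
#'
#' @param events filtered event data.frame.
#' @return data.frame with columns `label`, `name`, `severity`, `column`.
#' @export
buildAETypeIndex <- function(events) {
  if (nrow(events) == 0) {
    warning("no events: empty AE-type index")
    return(data.frame(label = character(), name = character(),
                      severity = integer(), column = integer()))
  }
  u <- unique(data.frame(name = events$ae_name,
                         severity = as.integer(events$severity)))
  u <- u[order(u$name, u$severity), , drop = FALSE]
  data.frame(label = paste0(u$name, "_", u$severity),
             name = u$name, severity = u$severity,
             column = seq_len(nrow(u)), stringsAsFactors = FALSE)
}

#' Severity-adjacency structure of the vocabulary
#'
#' For each AE name, the observed severities are sorted ascending;
#' consecutive pairs in that sorted list form the random-walk adjacency
#' set (so observed grades \{1, 3\} are chained 1 to 3 when grade 2 is
#' never observed, keeping each name's chain connected), and the lowest
#' observed severity is the anchor column that receives the
#' identification prior.
#'
#' @param index AE-type index from [buildAETypeIndex()].
#' @return list with `pairs` (two-column integer matrix `j`, `jprime`
#'   with `j < jprime`) and `anchors` (integer columns, named by AE
#'   name).
#' @export
buildAdjacency <- function(index) {
  pairs <- matrix(integer(), 0, 2, dimnames = list(NULL, c("j", "jprime")))
  anchors <- integer()
  for (nm in unique(index$name)) {
    rows <- index[index$name == nm, , drop = FALSE]
    rows <- rows[order(rows$severity), , drop = FALSE]
    anchors[nm] <- rows$column[1]
    if (nrow(rows) > 1)
      pairs <- rbind(pairs, cbind(j = rows$column[-nrow(rows)],
                                  jprime = rows$column[-1]))
  }
  list(pairs = pairs, anchors = anchors)
}

#' Assemble per-period count matrices with exposures
#'
#' Aggregates the long-format events into one `N_p x J` integer matrix
#' per period over the shared vocabulary. Rows are each period's
#' enrolled patients in sorted id order (patients who dropped out are
#' simply absent from later matrices). Exposure is the period's cycle
#' count, the configured constant for baseline periods, or a per-patient
#' `exposure` column of the enrollment when present.
#'
#' @param events filtered event data.frame.
#' @param design period design data.frame.
#' @param enrollment enrollment data.frame.
#' @param index AE-type index from [buildAETypeIndex()].
#' @param baselineExposure exposure constant of baseline periods
#'   (default 1: one pre-treatment interval).
#' @return an [AECountData-class] object.
#' @export
assembleCounts <- function(events, design, enrollment, index,
                           baselineExposure = 1) {
  J <- nrow(index)
  lab <- paste0(events$ae_name, "_", events$severity)
  col <- match(lab, index$label)
  if (anyNA(col))
    stop("event AE type not in index: ", lab[which(is.na(col))[1]])
  counts <- list()
  exposure <- list()
  for (k in seq_len(nrow(design))) {
    p <- design$period_id[k]
    pat <- sort(enrollment$patient_id[enrollment$period_id == p])
    Y <- matrix(0L, length(pat), J, dimnames = list(pat, index$label))
    ev <- which(events$period_id == p)
    if (length(ev)) {
      i <- match(events$patient_id[ev], pat)
      if (anyNA(i))
        stop("period ", p, ": event for non-enrolled patient ",
             events$patient_id[ev][which(is.na(i))[1]])
      for (e in seq_along(ev))
        Y[i[e], col[ev[e]]] <- Y[i[e], col[ev[e]]] + as.integer(events$count[ev[e]])
    }
    C <- rep(if (design$is_baseline[k]) baselineExposure else design$n_cycles[k],
             length(pat))
    if ("exposure" %in% names(enrollment)) {
      enr <- enrollment[enrollment$period_id == p, , drop = FALSE]
      ov <- enr$exposure[match(pat, enr$patient_id)]
      C[!is.na(ov)] <- ov[!is.na(ov)]
    }
    names(C) <- pat
    counts[[p]] <- Y
    exposure[[p]] <- C
  }
  new("AECountData", counts = counts, exposure = exposure,
      design = design, typeIndex = index)
}

#' Export the long-format event table of a count container
#'
#' Inverse of [assembleCounts()]: emits one row per nonzero cell, in the
#' CSV dialect read by [readAEEvents()]. Round-trips exactly (up to
#' patients with zero events, which the ingestion filter would drop).
#'
#' @param data an [AECountData-class] object.
#' @return data.frame with columns `patient_id`, `period_id`, `ae_name`,
#'   `severity`, `count`.
#' @export
exportEvents <- function(data) {
  idx <- aeTypeIndex(data)
  out <- lapply(names(aeCounts(data)), function(p) {
    Y <- aeCounts(data)[[p]]
    nz <- which(Y > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return(NULL)
    data.frame(patient_id = rownames(Y)[nz[, 1]], period_id = p,
               ae_name = idx$name[nz[, 2]], severity = idx$severity[nz[, 2]],
               count = Y[nz], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient_id = character(), period_id = character(),
                      ae_name = character(), severity = integer(),
                      count = integer())
  out[order(out$period_id, out$patient_id, out$ae_name, out$severity), ,
      drop = FALSE]
}
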