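#' Export model parameters, hyperparameters and adjacency to JSON
#'
#' Writes a single JSON file holding every parameter matrix with its
#' AE-type column labels and patient-row labels, the hyperparameters
#' and the severity-adjacency sets -- sufficient to recompute the joint
#' log-posterior bit-identically after [readAEParams()]. Doubles are
#' serialized at full precision.
#'
#' @param params an [AEModelParams-class] object.
#' @param hyper an [AEHyperParams-class] object.
#' @param adjacency adjacency structure from [buildAdjacency()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAEParams <- function(params, hyper, adjacency, path) {
  mat2l <- function(A) list(values = unname(A), rows = rownames(A),
                            cols = colnames(A))
  obj <- list(
    hyper = list(K = hyper@K, L = hyper@L, sigmaG = hyper@sigmaG,
                 sigmaM = hyper@sigmaM, sigmaR = hyper@sigmaR,
                 sigmaS = hyper@sigmaS),
    adjacency = list(pairs = unname(adjacency$pairs),
                     anchors = unname(adjacency$anchors),
                     anchor_names = names(adjacency$anchors)),
    M = lapply(params@M, mat2l), R = lapply(params@R, mat2l),
    S = lapply(params@S, mat2l),
    thetaTilde = lapply(params@thetaTilde, mat2l),
    xiTilde = lapply(params@xiTilde, mat2l))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname writeAEParams
#' @return `readAEParams`: list with `params`, `hyper`, `adjacency`.
#' @export
readAEParams <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  l2mat <- function(x) {
    A <- as.matrix(x$values)
    if (!is.null(x$rows) && length(x$rows)) rownames(A) <- x$rows
    if (!is.null(x$cols) && length(x$cols)) colnames(A) <- x$cols
    A
  }
  relist <- function(lst) if (length(lst)) lapply(lst, l2mat) else list()
  prs <- if (length(obj$adjacency$pairs))
    matrix(as.integer(obj$adjacency$pairs), ncol = 2,
           dimnames = list(NULL, c("j", "jprime")))
  else matrix(integer(), 0, 2, dimnames = list(NULL, c("j", "jprime")))
  anchors <- as.integer(obj$adjacency$anchors)
  names(anchors) <- obj$adjacency$anchor_names
  list(
    params = new("AEModelParams",
                 thetaTilde = relist(obj$thetaTilde), M = relist(obj$M),
                 R = relist(obj$R), xiTilde = relist(obj$xiTilde),
                 S = relist(obj$S)),
    hyper = aeHyperParams(K = obj$hyper$K, L = obj$hyper$L,
                          sigmaG = obj$hyper$sigmaG,
                          sigmaM = obj$hyper$sigmaM,
                          sigmaR = obj$hyper$sigmaR,
                          sigmaS = obj$hyper$sigmaS),
    adjacency = list(pairs = prs, anchors = anchors))
}
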