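#' @import methods
#' @importFrom stats runif rnorm quantile median sd setNames rlogis
#' @importFrom utils head
NULL

.SYM_TOL <- 1e-8

#' HeterogeneousNetwork: the drug-disease network triple
#'
#' Container for the three matrices that define a heterogeneous
#' drug-disease network: a drug-drug similarity matrix \code{Mrr}
#' (n x n, entries in [0,1], symmetric, unit diagonal), a
#' disease-disease similarity matrix \code{Mdd} (m x m, same
#' constraints) and a binary drug-disease association matrix
#' \code{Mrd} (n x m, 1 = known association, 0 = unknown). Drugs
#' index rows and diseases index columns of \code{Mrd} throughout
#' the package; every derived adjacency inherits this orientation.
#'
#' @slot drugIds character vector of n unique drug identifiers.
#' @slot diseaseIds character vector of m unique disease identifiers.
#' @slot Mrr n x n numeric drug similarity matrix.
#' @slot Mdd m x m numeric disease similarity matrix.
#' @slot Mrd n x m binary association matrix.
#'
#' @seealso [HeterogeneousNetwork()] for the validating constructor,
#'   [loadNetwork()], [generateSyntheticNetwork()].
#' @export
setClass("HeterogeneousNetwork",
  representation(
    drugIds = "character",
    diseaseIds = "character",
    Mrr = "matrix",
    Mdd = "matrix",
    Mrd = "matrix"
  )
)

.checkSimilarity <- function(S, what, ids) {
  msgs <- character()
  if (nrow(S) != ncol(S)) {
    return(sprintf("%s similarity matrix is not square", what))
  }
  if (nrow(S) != length(ids)) {
    msgs <- c(msgs, sprintf(
      "%s similarity dimension (%d) does not match identifier count (%d)",
      what, nrow(S), length(ids)
    ))
  }
  if (anyNA(S) || any(!is.finite(S))) {
    return(c(msgs, sprintf("%s similarity contains non-finite values", what)))
  }
  dev <- max(abs(S - t(S)))
  if (dev > .SYM_TOL) {
    msgs <- c(msgs, sprintf(
      "%s similarity asymmetric beyond tolerance (max deviation %.3g)",
      what, dev
    ))
  }
  ddev <- max(abs(diag(S) - 1))
  if (ddev > .SYM_TOL) {
    msgs <- c(msgs, sprintf(
      "%s similarity diagonal deviates from 1 (max deviation %.3g)",
      what, ddev
    ))
  }
  msgs
}

setValidity("HeterogeneousNetwork", function(object) {
  msgs <- character()
  n <- length(object@drugIds)
  m <- length(object@diseaseIds)
  if (n < 1L || m < 1L) {
    return("network must contain at least one drug and one disease")
  }
  if (anyDuplicated(object@drugIds)) msgs <- c(msgs, "duplicated drug identifiers")
  if (anyDuplicated(object@diseaseIds)) msgs <- c(msgs, "duplicated disease identifiers")
  msgs <- c(msgs, .checkSimilarity(object@Mrr, "drug", object@drugIds))
  msgs <- c(msgs, .checkSimilarity(object@Mdd, "disease", object@diseaseIds))
  if (!all(dim(object@Mrd) == c(n, m))) {
    msgs <- c(msgs, sprintf(
      "association matrix is %d x %d but identifiers imply %d x %d",
      nrow(object@Mrd), ncol(object@Mrd), n, m
    ))
  } else if (!all(object@Mrd %in% c(0, 1))) {
    msgs <- c(msgs, "non-binary association entries (all entries must be exactly 0 or 1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a validated HeterogeneousNetwork
#'
#' Similarity matrices with asymmetry at or below 1e-8 are repaired by
#' averaging with their transpose; larger asymmetry is an error reported
#' with the maximum deviation.
#'
#' @param drugIds,diseaseIds character identifier vectors.
#' @param Mrr,Mdd,Mrd the drug similarity, disease similarity and binary
#'   association matrices (see [HeterogeneousNetwork-class]).
#' @return A validated `HeterogeneousNetwork` object.
#' @examples
#' net <- HeterogeneousNetwork(
#'   drugIds = c("d1", "d2"), diseaseIds = c("s1", "s2"),
#'   Mrr = diag(2), Mdd = diag(2), Mrd = diag(2)
#' )
#' nDrugs(net)
#' @export
HeterogeneousNetwork <- function(drugIds, diseaseIds, Mrr, Mdd, Mrd) {
  Mrr <- as.matrix(Mrr)
  Mdd <- as.matrix(Mdd)
  Mrd <- as.matrix(Mrd)
  storage.mode(Mrr) <- "double"
  storage.mode(Mdd) <- "double"
  storage.mode(Mrd) <- "double"
  # forced symmetrization is only legal within tolerance; validity re-checks
  if (nrow(Mrr) > 0 && nrow(Mrr) == ncol(Mrr) &&
      max(abs(Mrr - t(Mrr))) <= .SYM_TOL) {
    Mrr <- (Mrr + t(Mrr)) / 2
  }
  if (nrow(Mdd) > 0 && nrow(Mdd) == ncol(Mdd) &&
      max(abs(Mdd - t(Mdd))) <= .SYM_TOL) {
    Mdd <- (Mdd + t(Mdd)) / 2
  }
  dimnames(Mrr) <- list(drugIds, drugIds)
  dimnames(Mdd) <- list(diseaseIds, diseaseIds)
  dimnames(Mrd) <- list(drugIds, diseaseIds)
  new("HeterogeneousNetwork",
    drugIds = as.character(drugIds), diseaseIds = as.character(diseaseIds),
    Mrr = Mrr, Mdd = Mdd, Mrd = Mrd
  )
}

#' @describeIn HeterogeneousNetwork number of drugs
#' @param object,x a `HeterogeneousNetwork`.
#' @export
setGeneric("nDrugs", function(x) standardGeneric("nDrugs"))
#' @export
setGeneric("nDiseases", function(x) standardGeneric("nDiseases"))
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))
#' @export
setGeneric("drugSim", function(x) standardGeneric("drugSim"))
#' @export
setGeneric("diseaseSim", function(x) standardGeneric("diseaseSim"))
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' @rdname HeterogeneousNetwork-class
#' @param x a `HeterogeneousNetwork`.
#' @aliases nDrugs nDiseases drugIds diseaseIds drugSim diseaseSim assocMatrix
#' @export
setMethod("nDrugs", "HeterogeneousNetwork", function(x) length(x@drugIds))
#' @rdname HeterogeneousNetwork-class
#' @export
setMethod("nDiseases", "HeterogeneousNetwork", function(x) length(x@diseaseIds))
#' @rdname HeterogeneousNetwork-class
#' @export
setMethod("drugIds", "HeterogeneousNetwork", function(x) x@drugIds)
#' @rdname HeterogeneousNetwork-class
#' @export
setMethod("diseaseIds", "HeterogeneousNetwork", function(x) x@diseaseIds)
#' @rdname HeterogeneousNetwork-class
#' @export
setMethod("drugSim", "HeterogeneousNetwork", function(x) x@Mrr)
#' @rdname HeterogeneousNetwork-class
#' @export
setMethod("diseaseSim", "HeterogeneousNetwork", function(x) x@Mdd)
#' @rdname HeterogeneousNetwork-class
#' @export
setMethod("assocMatrix", "HeterogeneousNetwork", function(x) x@Mrd)

setMethod("show", "HeterogeneousNetwork", function(object) {
  s <- summarizeNetwork(object)
  cat("HeterogeneousNetwork\n")
  cat(sprintf("  drugs:        %d (%s%s)\n",
    s$n_drugs, paste(head(object@drugIds, 3), collapse = ", "),
    if (s$n_drugs > 3) ", ..." else ""
  ))
  cat(sprintf("  diseases:     %d (%s%s)\n",
    s$n_diseases, paste(head(object@diseaseIds, 3), collapse = ", "),
    if (s$n_diseases > 3) ", ..." else ""
  ))
  cat(sprintf("  associations: %d of %d pairs (sparsity %.4f)\n",
    s$n_associations, s$size, s$sparsity
  ))
  invisible(NULL)
})
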