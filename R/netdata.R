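#' Summarize a drug-disease network
#'
#' Counts drugs, diseases and known associations, and reports sparsity,
#' defined as the proportion of drug-disease pairs without a known
#' association: `1 - n_associations / (n_drugs * n_diseases)`. Sparsity
#' is returned at full precision; round only for display.
#'
#' @param network a [HeterogeneousNetwork-class] object.
#' @return A one-row `data.frame` with columns `n_drugs`, `n_diseases`,
#'   `n_associations`, `size`, `n_non_associations`, `sparsity`.
#' @examples
#' net <- generateSyntheticNetwork(nDrugs = 30, nDiseases = 20, seed = 1)
#' summarizeNetwork(net)
#' @export
summarizeNetwork <- function(network) {
  .assertNetwork(network)
  n <- nDrugs(network)
  m <- nDiseases(network)
  a <- sum(network@Mrd)
  size <- n * m
  data.frame(
    n_drugs = n, n_diseases = m, n_associations = a,
    size = size, n_non_associations = size - a,
    sparsity = 1 - a / size
  )
}

.readMatrixFile <- function(path, sep = "\t") {
  df <- utils::read.table(path,
    header = TRUE, sep = sep, row.names = 1,
    check.names = FALSE, stringsAsFactors = FALSE, comment.char = ""
  )
  as.matrix(df)
}

#' Load a heterogeneous drug-disease network from files
#'
#' Reads three delimited-text matrices: drug-drug similarity,
#' disease-disease similarity, and the binary drug-disease association
#' matrix (drugs in rows, diseases in columns). Each file has a header
#' row of column identifiers and a first column of row identifiers.
#' The association matrix may instead be MatrixMarket coordinate format,
#' in which case `drugIdsFile` and `diseaseIdsFile` (one identifier per
#' line) supply the row and column names.
#'
#' The identifier order of the association matrix is canonical; the
#' similarity matrices are permuted to match it. Identifier-set
#' mismatches, non-binary association entries and asymmetric similarity
#' matrices (beyond 1e-8, reported with the maximum deviation) are
#' errors.
#'
#' @param drugSimFile,diseaseSimFile paths to the similarity matrices.
#' @param assocFile path to the association matrix (delimited text or
#'   `.mtx`).
#' @param sep field separator for delimited text (`"\t"` default, use
#'   `","` for CSV).
#' @param drugIdsFile,diseaseIdsFile identifier lists, required when
#'   `assocFile` is MatrixMarket.
#' @return A validated [HeterogeneousNetwork-class].
#' @seealso [writeNetwork()] for the inverse operation.
#' @export
loadNetwork <- function(drugSimFile, diseaseSimFile, assocFile, sep = "\t",
                        drugIdsFile = NULL, diseaseIdsFile = NULL) {
  if (grepl("\\.mtx$", assocFile, ignore.case = TRUE)) {
    if (is.null(drugIdsFile) || is.null(diseaseIdsFile)) {
      stop("MTX association input requires drugIdsFile and diseaseIdsFile")
    }
    Mrd <- as.matrix(Matrix::readMM(assocFile))
    rownames(Mrd) <- readLines(drugIdsFile)
    colnames(Mrd) <- readLines(diseaseIdsFile)
  } else {
    Mrd <- .readMatrixFile(assocFile, sep)
  }
  if (!all(Mrd %in% c(0, 1))) {
    stop("non-binary association entries in ", assocFile)
  }
  Mrr <- .readMatrixFile(drugSimFile, sep)
  Mdd <- .readMatrixFile(diseaseSimFile, sep)

  drugs <- rownames(Mrd)
  diseases <- colnames(Mrd)
  if (!setequal(rownames(Mrr), drugs)) {
    stop("drug identifiers of similarity and association matrices differ")
  }
  if (!setequal(rownames(Mdd), diseases)) {
    stop("disease identifiers of similarity and association matrices differ")
  }
  Mrr <- Mrr[drugs, drugs, drop = FALSE]
  Mdd <- Mdd[diseases, diseases, drop = FALSE]
  for (nm in c("Mrr", "Mdd")) {
    S <- get(nm)
    dev <- max(abs(S - t(S)))
    if (dev > .SYM_TOL) {
      stop(sprintf(
        "%s similarity matrix asymmetric beyond tolerance (max deviation %.3g)",
        if (nm == "Mrr") "drug" else "disease", dev
      ))
    }
  }
  HeterogeneousNetwork(drugs, diseases, Mrr, Mdd, Mrd)
}

.writeMatrixFile <- function(M, path, sep = "\t", binary = FALSE) {
  df <- as.data.frame(M, check.names = FALSE)
  if (binary) df[] <- lapply(df, function(v) as.integer(round(v)))
  utils::write.table(df, path,
    sep = sep, quote = FALSE,
    row.names = TRUE, col.names = NA
  )
}

#' Write a network to a directory
#'
#' Emits `drug_similarity`, `disease_similarity` and `association`
#' files in the dialect read by [loadNetwork()]: header row of column
#' identifiers, first column of row identifiers, `.` decimal mark.
#' Association entries are written as `0`/`1` tokens. With
#' `format = "mtx"` the association matrix is written as MatrixMarket
#' coordinate plus `drug_ids.txt` / `disease_ids.txt`.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param dir output directory (created if missing).
#' @param sep field separator for the similarity matrices.
#' @param format `"tsv"` (default), `"csv"`, or `"mtx"` for the
#'   association matrix.
#' @return Invisibly, the named vector of file paths written.
#' @export
writeNetwork <- function(network, dir, sep = if (format == "csv") "," else "\t",
                         format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  .assertNetwork(network)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "csv") "csv" else "tsv"
  paths <- c(
    drug_similarity = file.path(dir, paste0("drug_similarity.", ext)),
    disease_similarity = file.path(dir, paste0("disease_similarity.", ext))
  )
  .writeMatrixFile(network@Mrr, paths[["drug_similarity"]], sep)
  .writeMatrixFile(network@Mdd, paths[["disease_similarity"]], sep)
  if (format == "mtx") {
    ap <- file.path(dir, "association.mtx")
    Matrix::writeMM(Matrix::Matrix(network@Mrd, sparse = TRUE), ap)
    writeLines(network@drugIds, file.path(dir, "drug_ids.txt"))
    writeLines(network@diseaseIds, file.path(dir, "disease_ids.txt"))
    paths <- c(paths,
      association = ap,
      drug_ids = file.path(dir, "drug_ids.txt"),
      disease_ids = file.path(dir, "disease_ids.txt")
    )
  } else {
    ap <- file.path(dir, paste0("association.", ext))
    .writeMatrixFile(network@Mrd, ap, sep, binary = TRUE)
    paths <- c(paths, association = ap)
  }
  invisible(paths)
}

#' Generate a synthetic drug-disease network with planted structure
#'
#' Emulates the organising principle of real drug-disease networks --
#' similar drugs tend to target related diseases -- by planting a shared
#' latent cluster structure. Drugs and diseases are assigned to
#' `nClusters` groups; cluster centroids are points in a
#' `latentDim`-dimensional space separated by `signal`; each entity's
#' latent vector is its centroid plus isotropic Gaussian noise of
#' standard deviation `noiseSd`. Similarity between two entities of the
#' same kind is `exp(-||x_i - x_j||^2 / latentDim)` with the diagonal
#' forced to 1. Association propensity of a drug-disease pair is the
#' same kernel on their latent vectors plus logistic noise; the global
#' threshold is set at the `targetSparsity` quantile of the propensities
#' so realized sparsity matches the target (within 1/(n*m) up to ties).
#'
#' @param nDrugs,nDiseases entity counts.
#' @param nClusters number of planted clusters (must not exceed
#'   `min(nDrugs, nDiseases)`).
#' @param latentDim latent-space dimension.
#' @param signal centroid separation scale (>= 0); `signal` much larger
#'   than `noiseSd` yields a learnable planted structure.
#' @param noiseSd within-cluster latent noise standard deviation.
#' @param logisticSd scale of the logistic noise on association
#'   propensities (0 gives a deterministic threshold on the kernel).
#' @param targetSparsity desired fraction of 0 entries in the
#'   association matrix, strictly between 0 and 1.
#' @param seed integer seed; identical seeds give identical networks.
#' @return A validated [HeterogeneousNetwork-class] with attribute
#'   `"clusters"` recording the planted drug and disease labels.
#' @examples
#' net <- generateSyntheticNetwork(
#'   nDrugs = 40, nDiseases = 30,
#'   targetSparsity = 0.95, seed = 7
#' )
#' summarizeNetwork(net)$sparsity
#' @export
generateSyntheticNetwork <- function(nDrugs = 100, nDiseases = 80,
                                     nClusters = 4, latentDim = 8,
                                     signal = 3, noiseSd = 0.5,
                                     logisticSd = 0.1,
                                     targetSparsity = 0.95, seed = 1) {
  stopifnot(
    nDrugs >= 1, nDiseases >= 1, latentDim >= 1,
    signal >= 0, noiseSd >= 0, logisticSd >= 0
  )
  if (nClusters > min(nDrugs, nDiseases)) {
    stop("nClusters must not exceed min(nDrugs, nDiseases)")
  }
  if (targetSparsity <= 0 || targetSparsity >= 1) {
    stop("targetSparsity must lie strictly between 0 and 1")
  }
  withSeed(seed, {
    centroids <- matrix(rnorm(nClusters * latentDim), nClusters) * signal
    drugCl <- rep_len(seq_len(nClusters), nDrugs)
    disCl <- rep_len(seq_len(nClusters), nDiseases)
    X <- centroids[drugCl, , drop = FALSE] +
      matrix(rnorm(nDrugs * latentDim, sd = noiseSd), nDrugs)
    Y <- centroids[disCl, , drop = FALSE] +
      matrix(rnorm(nDiseases * latentDim, sd = noiseSd), nDiseases)

    kernelSim <- function(A, B) {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      d2[d2 < 0] <- 0
      exp(-d2 / latentDim)
    }
    Mrr <- kernelSim(X, X); diag(Mrr) <- 1
    Mdd <- kernelSim(Y, Y); diag(Mdd) <- 1

    prop <- kernelSim(X, Y) +
      matrix(rlogis(nDrugs * nDiseases, scale = logisticSd), nDrugs)
    thr <- quantile(prop, targetSparsity, names = FALSE)
    Mrd <- (prop > thr) * 1
    realized <- 1 - mean(Mrd)
    if (abs(realized - targetSparsity) > 0.01) {
      stop(sprintf(
        "target sparsity %.3f infeasible under the planted structure (realized %.3f); too many tied propensities",
        targetSparsity, realized
      ))
    }
    net <- HeterogeneousNetwork(
      drugIds = sprintf("drug%03d", seq_len(nDrugs)),
      diseaseIds = sprintf("disease%03d", seq_len(nDiseases)),
      Mrr = Mrr, Mdd = Mdd, Mrd = Mrd
    )
    attr(net, "clusters") <- list(drug = drugCl, disease = disCl)
    net
  })
}
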