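#' Composition matrix from taxonomic profiles
#'
#' Builds the samples x categories relative-abundance matrix: the union of
#' viral categories across profiles forms the columns (absent categories are
#' structural zeros), each row is that library's viral category counts
#' divided by its viral read total. "unassigned" is excluded.
#'
#' @param profiles list of [TaxonomicProfile-class] objects with
#'   `viralReads > 0`.
#' @return a [CompositionMatrix-class].
#' @export
toProportions <- function(profiles) {
  vmAssert(length(profiles) >= 1L, "viromassEmptyInputError",
           "no profiles given")
  for (p in profiles)
    vmAssert(p@viralReads > 0, "viromassEmptyInputError",
             sprintf("profile '%s' has no viral reads", p@libraryId))
  cats <- sort(unique(unlist(lapply(profiles, function(p)
    setdiff(names(p@counts), "unassigned")))))
  m <- matrix(0, nrow = length(profiles), ncol = length(cats),
              dimnames = list(vapply(profiles, function(p) p@libraryId,
                                     character(1)), cats))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    viral <- setdiff(names(p@counts), "unassigned")
    m[i, viral] <- p@counts[viral] / p@viralReads
  }
  new("CompositionMatrix", values = m)
}

#' Hellinger transform
#'
#' Square roots of proportions; an optional pre-treatment that damps the
#' influence of dominant categories in the ordination. Off by default in
#' [pcaFit()].
#'
#' @param mat a [CompositionMatrix-class] or plain matrix of row-proportions.
#' @return transformed plain matrix.
#' @export
hellinger <- function(mat) {
  v <- if (is(mat, "CompositionMatrix")) mat@values else mat
  sqrt(v)
}

#' Principal component analysis of composition profiles
#'
#' Column-centers the relative-abundance matrix and extracts principal
#' components (eigenvectors of the sample covariance matrix, ordered by
#' eigenvalue). Explained-variance fractions use the total variance, so they
#' sum to 1 over a full-rank fit. Eigenvector signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param mat a [CompositionMatrix-class] (or plain numeric matrix with
#'   dimnames).
#' @param nComponents number of components, at most
#'   `min(nSamples - 1, nCategories)`.
#' @param transform "none" (the default: proportions enter untransformed) or
#'   "hellinger".
#' @return a [PcaModel-class].
#' @export
pcaFit <- function(mat, nComponents = 2, transform = c("none", "hellinger")) {
  transform <- match.arg(transform)
  v <- if (is(mat, "CompositionMatrix")) mat@values else mat
  vmAssert(nrow(v) >= 2L, "viromassDomainError", "need at least 2 samples")
  maxRank <- min(nrow(v) - 1L, ncol(v))
  vmAssert(nComponents >= 1L && nComponents <= maxRank,
           "viromassRankError",
           sprintf("nComponents must be in [1, %d]", maxRank))
  if (transform == "hellinger") v <- hellinger(v)
  fit <- prcomp(v, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(fit$rotation))
  L <- fit$rotation[, seq_len(k), drop = FALSE]
  S <- fit$x[, seq_len(k), drop = FALSE]
  # sign convention: dominant loading of each component is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  totalVar <- sum(fit$sdev^2)
  ev <- if (totalVar > 0) fit$sdev[seq_len(k)]^2 / totalVar
        else rep(0, k)
  new("PcaModel", loadings = L, scores = S,
      explainedVariance = as.numeric(ev),
      center = fit$center)
}

#' Project new profiles onto a fitted PCA
#'
#' New rows are reconciled with the model's category universe: categories
#' absent from the model are dropped with a warning, categories absent from
#' the new data are zero-filled. Rows are centered with the model's means and
#' projected on its loadings, so projecting the training matrix reproduces
#' the fitted scores.
#'
#' @param model a [PcaModel-class].
#' @param mat a [CompositionMatrix-class] or plain matrix with column names.
#' @return samples x components score matrix.
#' @export
pcaProject <- function(model, mat) {
  v <- if (is(mat, "CompositionMatrix")) mat@values else mat
  modelCats <- names(model@center)
  unknown <- setdiff(colnames(v), modelCats)
  if (length(unknown))
    warning(sprintf("dropping %d category(ies) absent from the model: %s",
                    length(unknown), paste(unknown, collapse = ", ")),
            call. = FALSE)
  aligned <- matrix(0, nrow = nrow(v), ncol = length(modelCats),
                    dimnames = list(rownames(v), modelCats))
  common <- intersect(colnames(v), modelCats)
  aligned[, common] <- v[, common, drop = FALSE]
  sweep(aligned, 2, model@center) %*% model@loadings
}

#' Read / write composition matrices as TSV
#'
#' Samples in rows (first column `sample_id`), categories in columns.
#'
#' @param file TSV path.
#' @return `readComposition` returns a [CompositionMatrix-class].
#' @export
readComposition <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  checkHeader(df, "sample_id", "composition matrix")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  m <- m / rowSums(m)
  new("CompositionMatrix", values = m)
}

#' @rdname readComposition
#' @param mat a [CompositionMatrix-class].
#' @export
writeComposition <- function(mat, file) {
  df <- data.frame(sample_id = rownames(mat@values), mat@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
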