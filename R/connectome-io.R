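#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a region atlas from labels
#'
#' Hemispheres are parsed from name prefixes following the FreeSurfer
#' convention (`lh_` left, `rh_` right); the regexes are configurable for
#' other atlases.
#'
#' @param labels character vector of unique region names.
#' @param size optional per-region voxel counts (positive integers).
#' @param hemisphereRegex named character vector with `left` and `right`
#'   regular expressions matched against each label.
#' @return a [RegionAtlas-class].
#' @examples
#' regionAtlas(c("lh_precentral", "lh_postcentral", "rh_precentral"))
#' @export
regionAtlas <- function(labels, size = NULL,
                        hemisphereRegex = c(left = "^lh_", right = "^rh_")) {
  labels <- as.character(labels)
  left <- grepl(hemisphereRegex[["left"]], labels)
  right <- grepl(hemisphereRegex[["right"]], labels)
  if (any(left & right) || any(!left & !right))
    stop("every region label must match exactly one hemisphere pattern; ",
         "offending labels: ",
         paste(labels[(left & right) | (!left & !right)], collapse = ", "))
  if (is.null(size)) size <- rep(NA_integer_, length(labels))
  new("RegionAtlas", labels = labels,
      hemisphere = ifelse(left, "left", "right"),
      size = as.integer(size))
}

#' Read a labeled connectivity matrix
#'
#' Reads a delimited square table whose first column and header row carry the
#' same set of region names, returning a [ConnectivityMatrix-class].  Values
#' are symmetrised by averaging with the transpose when the maximal asymmetry
#' is below `1e-6`, otherwise an error is raised.  Missing connections may be
#' encoded as blank/`NA`/`NaN` cells (the default) or as zeros
#' (`zeroAsMissing = TRUE`); for `NSTREAMS` matrices a zero streamline count
#' always marks the edge missing, because microstructural averages are
#' undefined on empty tracts.
#'
#' @param path path to the TSV/CSV file.
#' @param modality modality/index tag for the matrix.
#' @param subject subject identifier (defaults to the file name).
#' @param sep field separator (tab by default).
#' @param zeroAsMissing treat exact zeros as missing edges; defaults to
#'   `TRUE` for `NSTREAMS` and `FALSE` otherwise.
#' @param hemisphereRegex passed to [regionAtlas()].
#' @return a [ConnectivityMatrix-class].
#' @seealso [writeConnectome()]
#' @export
readConnectome <- function(path, modality, subject = NULL, sep = "\t",
                           zeroAsMissing = identical(modality, "NSTREAMS"),
                           hemisphereRegex = c(left = "^lh_", right = "^rh_")) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) && is.character(tab[[1L]])) {
    # writer dialect: first column holds region names under its own header
    rn <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
    rownames(tab) <- rn
  }
  if (!setequal(rownames(tab), colnames(tab)))
    stop("row and column name sets differ in ", path)
  tab <- tab[, rownames(tab), drop = FALSE]      # align column order to rows
  v <- as.matrix(tab)
  if (!is.numeric(v))
    stop("non-numeric cell(s) in ", path)
  if (is.null(subject))
    subject <- sub("\\.[^.]*$", "", basename(path))
  connectivityMatrix(v, modality = modality, subject = subject,
                     zeroAsMissing = zeroAsMissing,
                     hemisphereRegex = hemisphereRegex)
}

#' Build a ConnectivityMatrix from a labeled numeric matrix
#'
#' @param values square numeric matrix with identical row and column names.
#' @inheritParams readConnectome
#' @param atlas optional pre-built [RegionAtlas-class]; built from the
#'   dimnames when omitted.
#' @return a [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(values, modality, subject = "subject",
                               zeroAsMissing = identical(modality, "NSTREAMS"),
                               atlas = NULL,
                               hemisphereRegex = c(left = "^lh_",
                                                   right = "^rh_")) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("values must be a square matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry region names as dimnames")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column names must agree")
  if (is.null(atlas))
    atlas <- regionAtlas(rownames(values), hemisphereRegex = hemisphereRegex)
  miss <- !is.finite(values)
  if (zeroAsMissing)
    miss <- miss | (values == 0 & !is.na(values))
  miss <- miss | t(miss)                          # mask is symmetric
  diag(miss) <- FALSE
  vals <- values
  vals[miss] <- NA_real_
  asym <- abs(vals - t(vals))
  if (any(asym > 1e-6, na.rm = TRUE))
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance 1e-6",
                 max(asym, na.rm = TRUE)))
  vals <- (vals + t(vals)) / 2
  new("ConnectivityMatrix", values = vals, atlas = atlas,
      modality = modality, subject = subject, missing = miss)
}

#' Write a labeled connectivity matrix
#'
#' Emits the tab-separated dialect the reader consumes: a header row and a
#' first column of region names.  Missing edges are written as `NA`.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(cm, path, sep = "\t") {
  v <- cm@values
  v[cm@missing] <- NA_real_
  df <- data.frame(region = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate all edges of an atlas
#'
#' All unordered region pairs (i, j) with i < j in row-major upper-triangle
#' order — the canonical edge order used by every panel in the package — each
#' tagged intra-left, intra-right or inter.
#'
#' @param atlas a [RegionAtlas-class].
#' @return an [EdgeIndex-class] with n(n-1)/2 edges.
#' @examples
#' idx <- buildEdgeIndex(regionAtlas(c("lh_A", "lh_B", "rh_A")))
#' edgeLabels(idx)
#' @export
buildEdgeIndex <- function(atlas) {
  stopifnot(is(atlas, "RegionAtlas"))
  n <- length(atlas@labels)
  if (n < 2L) stop("atlas must have at least 2 regions")
  from <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  to <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  hemi <- atlas@hemisphere
  hc <- ifelse(hemi[from] != hemi[to], "inter",
               ifelse(hemi[from] == "left", "intra-left", "intra-right"))
  new("EdgeIndex", from = as.integer(from), to = as.integer(to),
      labels = paste(atlas@labels[from], atlas@labels[to], sep = "--"),
      hemiclass = hc, atlas = atlas)
}

#' Vectorise the upper triangle of a connectivity matrix
#'
#' Returns one value per edge of `idx`, in the canonical edge order, with
#' missing connections as `NA`.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param idx an [EdgeIndex-class] built on the same atlas.
#' @return named numeric vector of length n(n-1)/2.
#' @seealso [devectorizeEdges()]
#' @export
vectorizeUpper <- function(cm, idx) {
  if (!identical(cm@atlas@labels, idx@atlas@labels))
    stop("connectivity matrix and edge index use different atlases")
  v <- cm@values[cbind(idx@from, idx@to)]
  v[cm@missing[cbind(idx@from, idx@to)]] <- NA_real_
  stats::setNames(v, idx@labels)
}

#' Rebuild a connectivity matrix from an edge vector
#'
#' Inverse of [vectorizeUpper()] off the diagonal; the diagonal is set to
#' `NA` (it is ignored by all downstream operations).
#'
#' @param edgeValues numeric vector in the canonical order of `idx` (`NA`
#'   marks missing edges).
#' @param idx an [EdgeIndex-class].
#' @inheritParams connectivityMatrix
#' @return a [ConnectivityMatrix-class].
#' @export
devectorizeEdges <- function(edgeValues, idx, modality = "synthetic",
                             subject = "subject") {
  n <- length(idx@atlas@labels)
  if (length(edgeValues) != length(idx@labels))
    stop("edge vector length does not match the edge index")
  v <- matrix(NA_real_, n, n, dimnames = list(idx@atlas@labels,
                                              idx@atlas@labels))
  v[cbind(idx@from, idx@to)] <- edgeValues
  v[cbind(idx@to, idx@from)] <- edgeValues
  miss <- is.na(v)
  diag(miss) <- FALSE
  new("ConnectivityMatrix", values = v, atlas = idx@atlas,
      modality = modality, subject = subject, missing = miss)
}

#' Edges defined in every subject
#'
#' Connections missing in any subject are excluded from the analysis: a
#' missing microstructural average is undefined, not zero, and sparse CCA has
#' no mechanism for missing cells.
#'
#' @param stack list of [ConnectivityMatrix-class] objects sharing one atlas
#'   and modality.
#' @param idx an [EdgeIndex-class] on the same atlas.
#' @return named logical vector, `TRUE` where the edge is defined in every
#'   subject.
#' @export
commonEdgeMask <- function(stack, idx) {
  if (!length(stack)) stop("empty connectome stack")
  labs <- idx@atlas@labels
  ok <- rep(TRUE, length(idx@labels))
  for (cm in stack) {
    if (!identical(cm@atlas@labels, labs))
      stop("all matrices in the stack must share the atlas")
    ok <- ok & !cm@missing[cbind(idx@from, idx@to)]
  }
  stats::setNames(ok, idx@labels)
}

#' Assemble an edge-by-subject panel
#'
#' Stacks the vectorised upper triangles of a subject stack into a k-by-m
#' panel over the edges retained by `mask`.
#'
#' @param stack list of [ConnectivityMatrix-class] objects (one per subject).
#' @param idx an [EdgeIndex-class] on the shared atlas.
#' @param mask logical edge mask, typically from [commonEdgeMask()].
#' @return an unstandardised [ConnectomePanel-class].
#' @export
assemblePanel <- function(stack, idx, mask = commonEdgeMask(stack, idx)) {
  if (!any(mask)) stop("edge mask excludes all edges")
  vals <- vapply(stack, vectorizeUpper, numeric(length(idx@labels)),
                 idx = idx)
  subj <- vapply(stack, function(cm) cm@subject, character(1L))
  if (anyDuplicated(subj))
    subj <- make.unique(subj)
  vals <- vals[mask, , drop = FALSE]
  if (anyNA(vals))
    stop("retained edges must be defined in every subject; use commonEdgeMask")
  colnames(vals) <- subj
  new("ConnectomePanel", values = vals, hemiclass = idx@hemiclass[mask],
      modality = stack[[1L]]@modality, standardized = FALSE)
}

#' Standardise panel rows
#'
#' Centres each connection across subjects and scales to unit sample standard
#' deviation (denominator m - 1), as sparse CCA assumes.
#'
#' @param panel a [ConnectomePanel-class] with at least 3 subjects.
#' @return the standardised panel.
#' @export
standardizeRows <- function(panel) {
  v <- panel@values
  if (ncol(v) < 3L) stop("standardisation needs at least 3 subjects")
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  if (any(sdv == 0))
    stop("constant connection row(s): ",
         paste(rownames(v)[sdv == 0], collapse = ", "))
  new("ConnectomePanel", values = (v - mu) / sdv, hemiclass = panel@hemiclass,
      modality = panel@modality, standardized = TRUE)
}
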