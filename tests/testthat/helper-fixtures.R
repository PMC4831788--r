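# Shared fixture builders; all data generated in code.

# labeled symmetric matrix with optional missing cells
makeLabeledMatrix <- function(labels, fill = NULL, missing = NULL,
                              seed = 1L) {
  n <- length(labels)
  if (is.null(fill)) {
    set.seed(seed)
    a <- matrix(rnorm(n * n), n, n)
    fill <- (a + t(a)) / 2
  }
  diag(fill) <- 0
  dimnames(fill) <- list(labels, labels)
  if (!is.null(missing)) {
    for (p in missing) {
      fill[p[1L], p[2L]] <- NA_real_
      fill[p[2L], p[1L]] <- NA_real_
    }
  }
  fill
}

# small stack of subject connectomes on one atlas
makeStack <- function(labels, m, modality = "WFA", missing = list(),
                      seed = 1L) {
  lapply(seq_len(m), function(s) {
    miss <- if (s <= length(missing)) missing[[s]] else NULL
    v <- makeLabeledMatrix(labels, missing = miss, seed = seed + s)
    connectivityMatrix(v, modality = modality,
                       subject = sprintf("sub%02d", s))
  })
}

`%||%` <- function(a, b) if (is.null(a) || (is.list(a) && !length(a))) b else a

# standardise a bare matrix by rows, sample SD
rowStandardize <- function(x) {
  t(apply(x, 1L, function(r) (r - mean(r)) / sd(r)))
}
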