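# Locator/loader for the original cohort's deposited connectivity matrices.
#
# The cohort data are not redistributable with the package.  To run the
# cohort-level checks, place the deposited per-subject matrices under
# inst/extdata/s1_data/ (before installation) as TSV files readable by
# readConnectome(), either flat as <INDEX>_<subject>.tsv or in one
# subdirectory per index: s1_data/<INDEX>/<subject>.tsv, with
# INDEX in NSTREAMS, WFA, WMD, WICVF, WISO, WODI, Wkappa.

s1DataDir <- function() {
  installed <- system.file("extdata", "s1_data", package = "sfCCA")
  if (nzchar(installed) && dir.exists(installed)) return(installed)
  local <- file.path("..", "..", "inst", "extdata", "s1_data")
  if (dir.exists(local)) return(local)
  ""
}

s1StructuralStack <- function(index, dir = s1DataDir()) {
  sub <- file.path(dir, index)
  files <- if (dir.exists(sub)) {
    list.files(sub, pattern = "\\.tsv$", full.names = TRUE)
  } else {
    list.files(dir, pattern = paste0("^", index, "[_-].*\\.tsv$"),
               full.names = TRUE)
  }
  lapply(sort(files), readConnectome, modality = index)
}
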