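# internal helpers

# locate a bundled file, falling back to the in-source tree during development
pkg_file <- function(...) {
  path <- system.file(..., package = "rxnscout")
  if (nzchar(path)) return(path)
  file.path("inst", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
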