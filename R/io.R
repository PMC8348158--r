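#' Read a genome-scale metabolic model
#'
#' Supports the two dialects genome-scale models are commonly distributed in:
#' SBML Level 3 with the FBC v2 package, and BiGG-style JSON. GPR strings are
#' retained verbatim and parsed lazily by the functions that need them.
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"sbml"` or `"json"`.
#' @return a [metabolic_model()].
#' @export
read_metabolic_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("model file '%s' does not exist", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     abort(sprintf("cannot infer model format from '%s'", path)))
  }
  switch(format,
    sbml = read_model_sbml(path),
    json = read_model_json(path)
  )
}

#' Write a genome-scale metabolic model
#'
#' @param model a [metabolic_model()].
#' @param path destination file.
#' @param format `"auto"` (by file extension), `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     abort(sprintf("cannot infer model format from '%s'", path)))
  }
  switch(format,
    sbml = write_model_sbml(model, path),
    json = write_model_json(model, path)
  )
}

#' Export the reaction table (with subsystems) as TSV
#'
#' @param model a [metabolic_model()].
#' @param path destination TSV file.
#' @return `path`, invisibly.
#' @export
export_reaction_table <- function(model, path) {
  utils::write.table(tidy(model), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
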