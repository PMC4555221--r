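#' Construct a mutagen spectrum
#'
#' @param name spectrum name.
#' @param substitutions character vector of substitutions in `"X>Y"`
#'   syntax, e.g. `c("C>T", "G>A")`.  May be empty.
#' @return a [MutagenSpectrum-class].
#' @examples
#' mutagenSpectrum("transitions", c("A>G", "G>A", "C>T", "T>C"))
#' @export
mutagenSpectrum <- function(name, substitutions = character()) {
  substitutions <- as.character(substitutions)
  ok <- grepl("^[ACGT]>[ACGT]$", substitutions)
  if (any(!ok))
    stop("malformed substitution(s): ",
         paste(substitutions[!ok], collapse = ", "),
         " (expected \"X>Y\" with X,Y in A/C/G/T)")
  new("MutagenSpectrum", name = as.character(name),
      ref = substr(substitutions, 1L, 1L),
      alt = substr(substitutions, 3L, 3L))
}

#' The default EMS spectrum
#'
#' EMS (ethyl methanesulfonate) induces almost exclusively G:C to A:T
#' transition mutations.  On the coding strand these appear as C>T or G>A,
#' so the default spectrum contains both; no separate strand flag is
#' needed.
#'
#' @return a [MutagenSpectrum-class] named `"EMS"`.
#' @export
emsSpectrum <- function() mutagenSpectrum("EMS", c("C>T", "G>A"))

#' Read mutagen spectra from a YAML/JSON config file
#'
#' The file maps spectrum names to lists of `"X>Y"` substitution strings,
#' e.g.
#' \preformatted{
#' EMS: [ "C>T", "G>A" ]
#' none: []
#' }
#'
#' @param path config file path.
#' @param name optional spectrum name to extract; when `NULL`, all spectra
#'   are returned as a named list.
#' @return a [MutagenSpectrum-class], or a named list of them.
#' @export
readSpectrumConfig <- function(path, name = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("spectrum config must map names to substitution lists")
  specs <- lapply(names(cfg), function(nm)
    mutagenSpectrum(nm, unlist(cfg[[nm]])))
  names(specs) <- names(cfg)
  if (is.null(name)) return(specs)
  if (!name %in% names(specs))
    stop("no spectrum named '", name, "' in ", path)
  specs[[name]]
}

## Resolve a spectrum given by name ("EMS", "none") or object.
.resolveSpectrum <- function(spectrum) {
  if (is(spectrum, "MutagenSpectrum")) return(spectrum)
  if (is.character(spectrum) && length(spectrum) == 1L) {
    if (toupper(spectrum) == "EMS") return(emsSpectrum())
    if (tolower(spectrum) == "none") return(mutagenSpectrum("none"))
    stop("unknown spectrum name '", spectrum,
         "'; pass a MutagenSpectrum object or use readSpectrumConfig()")
  }
  stop("'spectrum' must be a MutagenSpectrum or a spectrum name")
}

#' @rdname spectrumName
#' @export
setMethod("spectrumName", "MutagenSpectrum", function(x) x@name)

#' @rdname substitutions
#' @export
setMethod("substitutions", "MutagenSpectrum",
  function(x) if (length(x@ref)) paste0(x@ref, ">", x@alt) else character(0))

setMethod("show", "MutagenSpectrum", function(object) {
  cat("MutagenSpectrum '", object@name, "': ",
      if (length(object@ref)) paste(substitutions(object), collapse = ", ")
      else "(empty)", "\n", sep = "")
})
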