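#' Build an analysis configuration
#'
#' Constructs an [AnalysisConfig-class] with the published defaults,
#' overriding any named constant. A configuration snapshot is embedded in
#' every JSON result written by [writeResult()], and a flat key-value config
#' file can be read with [readConfig()] (command-line flags override file
#' values, file values override defaults).
#'
#' @param ... named overrides of [AnalysisConfig-class] slots, e.g.
#'   `nSimulations = 199`.
#' @return a validated [AnalysisConfig-class]
#' @examples
#' cfg <- analysisConfig(nSimulations = 99L)
#' cfg
#' @export
analysisConfig <- function(...) {
  over <- list(...)
  obj <- new("AnalysisConfig")
  if (length(over)) {
    bad <- setdiff(names(over), slotNames(obj))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown configuration keys: ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           call. = FALSE)
    for (nm in names(over)) {
      val <- over[[nm]]
      if (is(slot(obj, nm), "integer")) val <- as.integer(val)
      slot(obj, nm) <- val
    }
  }
  validObject(obj)
  obj
}

#' @describeIn analysisConfig Read a flat `key = value` (or `key: value`)
#'   text file into an [AnalysisConfig-class]; keys are slot names, values
#'   are parsed as numbers. Overrides passed in `...` win over file values.
#' @param path path to a flat key-value configuration file
#' @export
readConfig <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z][A-Za-z0-9_.]*)\\s*[=:]\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3]
  if (length(bad))
    stop("malformed config line(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  vals <- lapply(kv, function(m) {
    v <- suppressWarnings(as.numeric(m[3]))
    if (is.na(v)) stop("non-numeric config value for key '", m[2], "'",
                       call. = FALSE)
    v
  })
  names(vals) <- vapply(kv, `[`, character(1), 2)
  over <- list(...)
  vals[names(over)] <- over
  do.call(analysisConfig, vals)
}

# Config as a plain named list (used for provenance snapshots).
configAsList <- function(config) {
  stopifnot(is(config, "AnalysisConfig"))
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}
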