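#' Construct an AxisDefinition
#'
#' @param name process name (e.g. `"oxidation"`).
#' @param parameters character vector of parameter ids.
#' @param kind feature kind per parameter: `"baseline"`, `"mean_over_time"`
#'   or `"both"` (expands to one feature of each kind).  Recycled.
#' @return an [AxisDefinition-class].
#' @examples
#' AxisDefinition("oxidation", c("uric_acid", "vitE"), kind = "both")
#' @export
AxisDefinition <- function(name, parameters, kind = "mean_over_time") {
  kind <- rep_len(as.character(kind), length(parameters))
  bad <- setdiff(unique(kind), c("baseline", "mean_over_time", "both"))
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  expand <- kind == "both"
  features <- data.frame(
    parameter = c(parameters[!expand], rep(parameters[expand], each = 2L)),
    kind = c(kind[!expand], rep(c("baseline", "mean_over_time"),
                                times = sum(expand))),
    stringsAsFactors = FALSE)
  methods::new("AxisDefinition", name = as.character(name), features = features)
}

#' Read / write axis definitions from a JSON or YAML config
#'
#' The document layout is
#' `{"axes": [{"name": ..., "features": [{"parameter": ..., "kind": ...}]}]}`.
#' `kind` may be `"baseline"`, `"mean_over_time"` or the shorthand `"both"`,
#' which expands to the two concrete kinds.  The format is inferred from the
#' extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path file path.
#' @param axes a list of [AxisDefinition-class] objects (for writing).
#' @return `readAxisDefinitions` returns a named list of
#'   [AxisDefinition-class]; `writeAxisDefinitions` returns `path` invisibly.
#' @export
readAxisDefinitions <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$axes)) stop("axis config must contain an 'axes' list")
  axes <- lapply(doc$axes, function(ax) {
    if (is.null(ax$name)) stop("each axis needs a 'name'")
    feats <- ax$features
    if (is.data.frame(feats)) feats <- split(feats, seq_len(nrow(feats)))
    if (!length(feats)) stop("axis '", ax$name, "' has no features")
    params <- vapply(feats, function(f) as.character(f$parameter), "")
    kinds <- vapply(feats, function(f)
      if (is.null(f$kind)) "mean_over_time" else as.character(f$kind), "")
    AxisDefinition(ax$name, params, kinds)
  })
  stats::setNames(axes, vapply(axes, function(a) a@name, ""))
}

#' @rdname readAxisDefinitions
#' @export
writeAxisDefinitions <- function(axes, path) {
  doc <- list(axes = lapply(axes, function(ax) {
    list(name = ax@name,
         features = lapply(seq_len(nrow(ax@features)), function(i)
           list(parameter = ax@features$parameter[i],
                kind = ax@features$kind[i])))
  }))
  names(doc$axes) <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(doc, path)
  else
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
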