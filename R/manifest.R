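#' Run manifest for provenance
#'
#' Builds the provenance record emitted next to every artifact the
#' command-line wrapper writes: tool version, subcommand, resolved
#' parameters, md5 digests of the input files, seed and timestamp. Digests
#' are stable across reruns on identical inputs, so equality of two
#' manifests (ignoring the timestamp) certifies an identical run.
#'
#' @param subcommand name of the operation performed
#' @param params named list of resolved parameter values
#' @param inputs character vector of input file paths to digest
#' @param seed integer seed used for any randomness (NA if none)
#' @return a `RunManifest` list
#' @seealso [writeManifest()]
#' @export
runManifest <- function(subcommand, params = list(), inputs = character(),
                        seed = NA_integer_) {
    digests <- if (length(inputs)) {
        d <- tools::md5sum(inputs)
        stats::setNames(as.character(d), basename(names(d)))
    } else c()
    structure(list(
        tool = "rootMSI",
        version = as.character(utils::packageVersion("rootMSI")),
        subcommand = subcommand,
        params = params,
        input_digests = as.list(digests),
        seed = seed,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        class = "RunManifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [runManifest()]
#' @param path output path (conventionally `<artifact>.manifest.json`)
#' @return `path`, invisibly
#' @export
writeManifest <- function(manifest, path) {
    jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
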