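sigmoid <- function(z) 1 / (1 + exp(-z))

# binary cross-entropy, probabilities clamped away from {0,1}
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seed, package version,
#' timestamp and MD5 checksums of the input files into
#' `<dir>/manifest.json`, so that deterministic stages can be re-run and
#' verified bit-for-bit.
#'
#' @param dir Output directory (created if missing).
#' @param command Subcommand or function name being recorded.
#' @param params Named list: configuration snapshot, including seeds.
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest as a list, invisibly.
#' @export
write_manifest <- function(dir, command, params = list(), inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    params = params,
    version = as.character(utils::packageVersion("footprintCNN")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
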