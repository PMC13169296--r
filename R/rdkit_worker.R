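# Bridge to the bundled RDKit perception worker (inst/python/perceive.py).
# Requests are batched and memoised: repeated perception of the same SMILES
# under the same options never re-launches the interpreter.

.worker_cache <- new.env(parent = emptyenv())

worker_script <- function() {
  p <- system.file("python", "perceive.py", package = "regiots")
  if (!nzchar(p)) stop("bundled perception worker not found")
  p
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' interpreter on PATH (required for molecule perception)")
  p
}

#' Is the molecule-perception backend available?
#'
#' @return `TRUE` if a Python interpreter with RDKit is reachable.
#' @export
perception_available <- function() {
  ok <- tryCatch({
    out <- suppressWarnings(system2(python_bin(), c("-c", "import rdkit"),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status")) || attr(out, "status") == 0
  }, error = function(e) FALSE)
  isTRUE(ok)
}

# Run the worker on a list of records (each list(id=, smiles=)) with the
# given options; returns the parsed per-record list in the same order.
worker_perceive <- function(records, opts) {
  stopifnot(is.list(records))
  req <- c(opts, list(records = records))
  key_full <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA)

  opt_key <- jsonlite::toJSON(opts[order(names(opts))], auto_unbox = TRUE)
  rec_keys <- vapply(records, function(r) paste0(opt_key, "\r", r$smiles), "")
  hit <- vapply(rec_keys, exists, TRUE, envir = .worker_cache)

  res <- vector("list", length(records))
  if (any(hit)) {
    res[hit] <- lapply(rec_keys[hit], get, envir = .worker_cache)
  }
  if (any(!hit)) {
    todo <- which(!hit)
    req$records <- records[todo]
    infile <- tempfile(fileext = ".json")
    on.exit(unlink(infile), add = TRUE)
    writeLines(jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null"),
               infile)
    out <- suppressWarnings(system2(python_bin(), worker_script(),
                                    stdin = infile, stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop("perception worker failed (exit status ", status, ")")
    }
    parsed <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
    if (length(parsed) != length(todo)) stop("perception worker returned wrong record count")
    for (k in seq_along(todo)) {
      res[[todo[k]]] <- parsed[[k]]
      assign(rec_keys[todo[k]], parsed[[k]], envir = .worker_cache)
    }
  }
  res
}

# Default perception options derived from a config list.
worker_opts <- function(config, embed = TRUE, want_fp = FALSE, seed = NULL) {
  list(
    seed = as.integer(if (is.null(seed)) config$embed_seed else seed),
    embed = isTRUE(embed),
    embed_retries = as.integer(config$embed_retries),
    optimize_maxiters = as.integer(config$optimize_maxiters),
    site_smarts = config$site_smarts,
    fp_radius = as.integer(config$fp_radius),
    fp_bits = as.integer(config$fp_bits),
    want_fp = isTRUE(want_fp)
  )
}
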