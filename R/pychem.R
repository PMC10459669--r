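# Bridge to the bundled RDKit helper (inst/python/equivs_chem.py).
#
# All chemistry perception (standardization, ETKDG embedding, MMFF94,
# SDF I/O) runs in one short-lived python process per call; requests and
# responses are exchanged as JSON files so coordinates survive round trips
# at full double precision.

pychem_env <- new.env(parent = emptyenv())

#' Locate the python interpreter used for chemistry perception
#'
#' The interpreter is resolved, in order, from the option `equivs.python`,
#' the environment variable `EQUIVS_PYTHON`, and `python` / `python3` on
#' `PATH`. The first interpreter that can import RDKit is cached for the
#' session.
#'
#' @param force Re-probe even if an interpreter was already cached.
#' @return Path to the python executable (invisibly errors if none found).
#' @export
find_python <- function(force = FALSE) {
  if (!force && !is.null(pychem_env$python)) {
    return(pychem_env$python)
  }
  candidates <- c(
    getOption("equivs.python", ""),
    Sys.getenv("EQUIVS_PYTHON", ""),
    Sys.which("python"),
    Sys.which("python3")
  )
  candidates <- unique(candidates[nzchar(candidates)])
  for (cand in candidates) {
    ok <- tryCatch({
      out <- suppressWarnings(system2(
        cand, c("-c", shQuote("import rdkit")),
        stdout = TRUE, stderr = TRUE
      ))
      is.null(attr(out, "status"))
    }, error = function(e) FALSE)
    if (ok) {
      pychem_env$python <- cand
      return(cand)
    }
  }
  abort(
    paste0(
      "No python interpreter with RDKit found. Set option 'equivs.python' ",
      "or environment variable EQUIVS_PYTHON."
    ),
    class = "equivs_python_error"
  )
}

pychem_script <- function() {
  path <- system.file("python", "equivs_chem.py", package = "equivs")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may be on the source path
    path <- file.path("inst", "python", "equivs_chem.py")
  }
  if (!file.exists(path)) {
    abort("bundled python helper not found", class = "equivs_python_error")
  }
  path
}

# Run one helper command; request is an R list, response a parsed list.
pychem_call <- function(command, request) {
  python <- find_python()
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(request, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  err <- tempfile(fileext = ".log")
  on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(system2(
    python, c(pychem_script(), command, "--in", fin, "--out", fout),
    stdout = FALSE, stderr = err
  ))
  if (!identical(status, 0L) || !file.exists(fout)) {
    msg <- if (file.exists(err)) paste(readLines(err), collapse = "\n") else ""
    abort(
      sprintf("python chemistry helper failed (command '%s'):\n%s",
              command, msg),
      class = "equivs_python_error"
    )
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

# split a result list into ok / failed entries
pychem_partition <- function(results) {
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  list(ok = results[ok], failed = results[!ok])
}

pychem_failure_messages <- function(failed) {
  vapply(failed, function(r) {
    sprintf("%s [%s]: %s", r$id %null% "?", r$error %null% "error",
            r$message %null% "")
  }, character(1))
}
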