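#' @import methods
#' @importFrom jsonlite toJSON fromJSON
NULL

# Singleton connection to the RDKit worker process plus memoisation caches.
# The worker holds no state the R side depends on, so it can be restarted
# transparently if it dies.
.bridge <- new.env(parent = emptyenv())
.bridge$con <- NULL
.bridge$caches <- new.env(parent = emptyenv())

.bridgeAlive <- function() {
  !is.null(.bridge$con) && isTRUE(tryCatch(isOpen(.bridge$con), error = function(e) FALSE))
}

.pythonBin <- function() {
  bin <- Sys.getenv("RETROPLAN_PYTHON", "")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) stop("no python interpreter found on PATH")
  bin
}

.bridgeStart <- function() {
  script <- system.file("python", "rdkit_worker.py", package = "retroplan")
  if (!nzchar(script)) {
    # during development (pkgload) inst/ is not yet flattened
    script <- system.file("inst", "python", "rdkit_worker.py", package = "retroplan")
  }
  if (!nzchar(script)) stop("rdkit_worker.py not found in installed package")
  portfile <- tempfile("retroplan-port-")
  system2(.pythonBin(), c(shQuote(script), shQuote(portfile)),
          wait = FALSE, stdout = FALSE, stderr = FALSE)
  deadline <- Sys.time() + 60
  port <- NA_integer_
  while (Sys.time() < deadline) {
    if (file.exists(portfile)) {
      txt <- tryCatch(readLines(portfile, n = 1L, warn = FALSE), error = function(e) character())
      if (length(txt) && nzchar(txt)) { port <- as.integer(txt); break }
    }
    Sys.sleep(0.05)
  }
  if (is.na(port)) stop("RDKit worker did not start within 60 s (is python+rdkit available?)")
  con <- socketConnection("127.0.0.1", port = port, blocking = TRUE,
                          open = "r+", timeout = 600)
  .bridge$con <- con
  unlink(portfile)
  invisible(con)
}

.bridgeCall <- function(req) {
  if (!.bridgeAlive()) .bridgeStart()
  line <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA)
  writeLines(line, .bridge$con)
  flush(.bridge$con)
  resp <- readLines(.bridge$con, n = 1L)
  if (!length(resp)) {
    # worker died mid-call: restart once and retry
    try(close(.bridge$con), silent = TRUE)
    .bridge$con <- NULL
    .bridgeStart()
    writeLines(line, .bridge$con)
    flush(.bridge$con)
    resp <- readLines(.bridge$con, n = 1L)
    if (!length(resp)) stop("RDKit worker connection lost")
  }
  jsonlite::fromJSON(resp, simplifyVector = FALSE)
}

# memoise a bridge call under cache `name` with key `key`
.bridgeCached <- function(name, key, req) {
  cache <- .bridge$caches[[name]]
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .bridge$caches[[name]] <- cache
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- .bridgeCall(req)
  cache[[key]] <- val
  val
}

#' Shut down the background RDKit worker
#'
#' The worker is started lazily on first use and normally lives for the R
#' session; closing it is only needed to release the process early. A new
#' worker starts automatically on the next chemistry call.
#'
#' @return Invisibly, `TRUE` if a worker was running and was closed.
#' @export
closeChemWorker <- function() {
  was <- .bridgeAlive()
  if (was) try(close(.bridge$con), silent = TRUE)
  .bridge$con <- NULL
  invisible(was)
}
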