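#' Transports: how the pipeline talks to the outside world
#'
#' Every remote interaction goes through a transport object, so the same
#' pipeline runs against the live GBIF/ENA services or against a local
#' fixture directory.  A transport answers two request shapes:
#'
#' * occurrence search: `transport_search(transport, query, offset, limit)`
#'   returning the occurrence-search dialect (`results` list +
#'   `endOfRecords` flag);
#' * resource fetch: `transport_fetch(transport, url)` returning
#'   `list(status, body)` where `body` is a raw vector.
#'
#' Status 200 means success; any other status is treated as a transient
#' failure and retried by the caller.
#'
#' @name transport
NULL

#' @rdname transport
#' @param transport A transport object.
#' @param query A [taxon_query][parse_taxon_query].
#' @param offset,limit Zero-based paging window.
#' @export
transport_search <- function(transport, query, offset, limit) {
  UseMethod("transport_search")
}

#' @rdname transport
#' @param url Resource URL to fetch.
#' @export
transport_fetch <- function(transport, url) {
  UseMethod("transport_fetch")
}

#' Offline transport backed by a fixture directory
#'
#' Serves occurrence pages and sequence resources from a directory written
#' by [generate_fixture()].  The generator's page files are concatenated
#' once at construction and re-sliced to honour any requested
#' `(offset, limit)`, so pagination behaves identically for every page
#' size.  URLs of the form `fixture://<relative/path>` resolve to files
#' beneath the fixture directory.
#'
#' @param fixture_dir Path to a fixture directory.
#' @param truncate_first Character vector of URLs whose first fetch in this
#'   transport's lifetime fails with a truncated-transfer status (used to
#'   exercise retry logic).
#' @return A `fixture_transport` object.
#' @export
fixture_transport <- function(fixture_dir, truncate_first = character(0)) {
  if (!dir.exists(fixture_dir)) {
    stop("fixture directory not found: ", fixture_dir, call. = FALSE)
  }
  page_files <- sort(list.files(file.path(fixture_dir, "pages"),
                                pattern = "\\.json$", full.names = TRUE))
  results <- list()
  for (pf in page_files) {
    page <- jsonlite::read_json(pf)
    results <- c(results, page$results)
  }
  env <- new.env(parent = emptyenv())
  env$attempts <- new.env(parent = emptyenv())
  structure(
    list(
      fixture_dir = normalizePath(fixture_dir),
      results = results,
      truncate_first = truncate_first,
      state = env
    ),
    class = c("fixture_transport", "transport")
  )
}

#' @export
transport_search.fixture_transport <- function(transport, query, offset, limit) {
  n <- length(transport$results)
  if (offset >= n) {
    return(list(results = list(), endOfRecords = TRUE,
                offset = offset, limit = limit, count = n))
  }
  idx <- seq.int(offset + 1L, min(offset + limit, n))
  list(
    results = transport$results[idx],
    endOfRecords = (offset + limit) >= n,
    offset = offset,
    limit = limit,
    count = n
  )
}

#' @export
transport_fetch.fixture_transport <- function(transport, url) {
  att <- transport$state$attempts
  seen <- if (is.null(att[[url]])) 0L else att[[url]]
  att[[url]] <- seen + 1L
  rel <- sub("^fixture://", "", url)
  path <- file.path(transport$fixture_dir, rel)
  if (!file.exists(path)) {
    return(list(status = 404L, body = raw(0)))
  }
  body <- readBin(path, what = "raw", n = file.info(path)$size)
  if (url %in% transport$truncate_first && seen == 0L) {
    # simulate a truncated transfer on the first attempt
    return(list(status = 0L, body = body[seq_len(length(body) %/% 2L)]))
  }
  list(status = 200L, body = body)
}

#' Live HTTP transport
#'
#' Thin adapter over base R connections, talking to the GBIF occurrence
#' search API and fetching resource URLs directly.  It is never exercised
#' in offline test runs; all pipeline logic is shared with the fixture
#' transport.
#'
#' @param api_base Base URL of the occurrence search endpoint.
#' @return An `http_transport` object.
#' @export
http_transport <- function(api_base = "https://api.gbif.org/v1") {
  structure(list(api_base = api_base),
            class = c("http_transport", "transport"))
}

#' @export
transport_search.http_transport <- function(transport, query, offset, limit) {
  url <- sprintf(
    "%s/occurrence/search?scientificName=%s&offset=%d&limit=%d",
    transport$api_base,
    utils::URLencode(paste(query$tokens, collapse = " "), reserved = TRUE),
    offset, limit
  )
  resp <- transport_fetch(transport, url)
  if (resp$status != 200L) {
    stop("occurrence search request failed (status ", resp$status, ")",
         call. = FALSE)
  }
  jsonlite::parse_json(rawToChar(resp$body))
}

#' @export
transport_fetch.http_transport <- function(transport, url) {
  dest <- tempfile()
  on.exit(unlink(dest))
  status <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) -1L,
    warning = function(w) -1L
  )
  if (!identical(status, 0L) || !file.exists(dest)) {
    return(list(status = 0L, body = raw(0)))
  }
  list(status = 200L,
       body = readBin(dest, what = "raw", n = file.info(dest)$size))
}

# retry helper: run fn() up to `attempts` times with exponential backoff,
# treating a NULL return as failure
with_retries <- function(fn, attempts = 3L, backoff = 0.2) {
  for (k in seq_len(attempts)) {
    out <- fn()
    if (!is.null(out)) return(out)
    if (k < attempts) Sys.sleep(backoff * 2^(k - 1L))
  }
  NULL
}
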