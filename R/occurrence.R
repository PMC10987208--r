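#' Occurrence records
#'
#' One occurrence is a documented instance of a taxon at a place and time,
#' identified by a positive integer key and carrying optional locality
#' fields plus zero or more linked sequence-resource URLs.
#'
#' @name occurrence
NULL

#' Parse one occurrence payload into a record
#'
#' Maps the occurrence-search JSON shape onto a flat record.  Missing
#' optional fields become `NA`, never sentinel numbers.  Coordinates are
#' kept only as a valid pair: if either member is absent or out of range
#' (latitude beyond ±90, longitude beyond ±180), both are dropped and a
#' message is logged — a half-valid locality is not mappable.
#'
#' @param payload A named list in the occurrence-search dialect (fields
#'   `key`, `scientificName`, `decimalLatitude`, `decimalLongitude`,
#'   `country`, `basisOfRecord`, `associated_sequence_resources`).
#' @return An `occurrence_record`: a list with fields `occurrence_id`,
#'   `scientific_name`, `decimal_latitude`, `decimal_longitude`, `country`,
#'   `basis_of_record`, `resource_links`.
#' @export
parse_occurrence_payload <- function(payload) {
  key <- payload$key
  if (is.null(key) || is.na(suppressWarnings(as.numeric(key))) ||
      as.numeric(key) <= 0) {
    stop("malformed occurrence: missing or invalid occurrence key",
         call. = FALSE)
  }
  scalar_chr <- function(x) {
    if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x[[1L]])
  }
  scalar_num <- function(x) {
    if (is.null(x) || length(x) == 0L) NA_real_
    else suppressWarnings(as.numeric(x[[1L]]))
  }
  lat <- scalar_num(payload$decimalLatitude)
  lon <- scalar_num(payload$decimalLongitude)
  ok <- !is.na(lat) && !is.na(lon) &&
    lat >= -90 && lat <= 90 && lon >= -180 && lon <= 180
  if (!ok && (!is.na(lat) || !is.na(lon))) {
    occseq_log("occurrence ", key,
               ": dropped incomplete or out-of-range coordinate pair")
  }
  if (!ok) {
    lat <- NA_real_
    lon <- NA_real_
  }
  structure(
    list(
      occurrence_id = as.integer(key),
      scientific_name = scalar_chr(payload$scientificName),
      decimal_latitude = lat,
      decimal_longitude = lon,
      country = scalar_chr(payload$country),
      basis_of_record = scalar_chr(payload$basisOfRecord),
      resource_links = extract_resource_links(payload)
    ),
    class = "occurrence_record"
  )
}

#' Retrieve all occurrences matching a taxon query
#'
#' Issues pages of size `page_size` with increasing offset until the
#' transport signals end-of-results, concatenating in server order;
#' stops early once `max_records` records have been collected.  A page
#' request that keeps failing after the retry budget aborts the search —
#' partial results are never returned silently.
#'
#' @param query A [taxon_query][parse_taxon_query].
#' @param transport A [transport] object.
#' @param page_size Records per page request (default 300, a common
#'   occurrence-API page limit).
#' @param max_records Stop after this many records; `Inf` for all.
#' @param retries Attempts per page before giving up.
#' @return List of [occurrence_record][parse_occurrence_payload]s.
#' @export
search_occurrences <- function(query, transport, page_size = 300L,
                               max_records = Inf, retries = 3L) {
  stopifnot(inherits(query, "taxon_query"), page_size >= 1L,
            max_records >= 1L)
  records <- list()
  offset <- 0L
  warned_large <- FALSE
  repeat {
    page <- with_retries(function() {
      tryCatch(
        transport_search(transport, query, offset, as.integer(page_size)),
        error = function(e) NULL
      )
    }, attempts = retries)
    if (is.null(page)) {
      stop("search failed at offset ", offset, call. = FALSE)
    }
    for (payload in page$results) {
      records[[length(records) + 1L]] <- parse_occurrence_payload(payload)
      if (length(records) >= max_records) break
    }
    if (length(records) > 1e5 && !warned_large) {
      warning("occurrence search exceeded 100000 records; ",
              "consider narrowing the query", call. = FALSE)
      warned_large <- TRUE
    }
    if (length(records) >= max_records) break
    if (isTRUE(page$endOfRecords) || length(page$results) == 0L) break
    offset <- offset + as.integer(page_size)
  }
  records
}

# package-level message logger; quiet unless option occseq.verbose is TRUE
occseq_log <- function(...) {
  if (isTRUE(getOption("occseq.verbose", FALSE))) {
    message("[occseq] ", ...)
  }
  invisible(NULL)
}
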