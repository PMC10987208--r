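#' Sequence-resource links and cached fetching
#'
#' Each occurrence may link to sequence resources: FASTA/FASTQ files of
#' SSU reads and MAPseq taxonomy-assignment files, optionally gzipped.
#' Links are classified from their URL suffix and fetched into a local
#' per-occurrence cache with retry and atomic writes.
#'
#' @name resource
NULL

#' Classify a resource URL by suffix
#'
#' Case-insensitive: `.fasta`/`.fa` are FASTA, `.fastq`/`.fq` FASTQ,
#' `.mseq`/`.mapseq` MAPseq; a trailing `.gz` marks gzip compression and
#' is stripped before kind matching.  Anything else is `other`.
#'
#' @param url Non-empty URL string.
#' @return List with `kind` (one of `"fasta"`, `"fastq"`, `"mapseq"`,
#'   `"other"`) and `compression` (`"none"` or `"gzip"`).
#' @examples
#' classify_url("http://x/ERZ1_FASTQ_SSU.fasta.gz")  # fasta, gzip
#' classify_url("http://x/ERZ1.mseq")                # mapseq, none
#' @export
classify_url <- function(url) {
  stopifnot(is.character(url), length(url) == 1L, nzchar(url))
  lower <- tolower(url)
  compression <- "none"
  if (endsWith(lower, ".gz")) {
    compression <- "gzip"
    lower <- sub("\\.gz$", "", lower)
  }
  kind <- if (grepl("\\.(fasta|fa)$", lower)) "fasta"
    else if (grepl("\\.(fastq|fq)$", lower)) "fastq"
    else if (grepl("\\.(mseq|mapseq)$", lower)) "mapseq"
    else "other"
  list(kind = kind, compression = compression)
}

#' Extract classified resource links from an occurrence payload
#'
#' Reads the payload's link-bearing field (`associated_sequence_resources`,
#' a list of URL strings), classifies each URL, preserves order, and drops
#' duplicates keeping the first.
#'
#' @param payload A named list in the occurrence-search dialect.
#' @return List of `resource_link` objects (`url`, `kind`, `compression`,
#'   `accession`); empty when the payload has no links.
#' @export
extract_resource_links <- function(payload) {
  urls <- unlist(payload$associated_sequence_resources, use.names = FALSE)
  if (is.null(urls) || length(urls) == 0L) return(list())
  urls <- as.character(urls)
  urls <- urls[!duplicated(urls)]
  lapply(urls, function(u) {
    cls <- classify_url(u)
    accession <- sub("\\..*$", "", basename(u))
    structure(
      list(url = u, kind = cls$kind, compression = cls$compression,
           accession = if (nzchar(accession)) accession else NA_character_),
      class = "resource_link"
    )
  })
}

# stable digest of a URL using base tools::md5sum (hash of the bytes)
url_digest <- function(url) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(url), f)
  unname(tools::md5sum(f))
}

#' Fetch one resource into a local cache
#'
#' The cache key is a stable digest of the URL (plus the original file
#' name for readability); a complete cached file short-circuits the
#' download.  Bytes are written to a temporary file and renamed into
#' place, so a failed run never leaves a partial file under its final
#' name.
#'
#' @param link A `resource_link` (or bare URL string).
#' @param cache_dir Writable directory for this occurrence's downloads.
#' @param transport A [transport] object.
#' @param retries Download attempts before giving up.
#' @param use_cache Set `FALSE` to force a re-download.
#' @return A `fetched_resource`: list with `link`, `local_path`,
#'   `byte_size`, `from_cache`.
#' @export
fetch_resource <- function(link, cache_dir, transport, retries = 3L,
                           use_cache = TRUE) {
  if (is.character(link)) {
    cls <- classify_url(link)
    link <- structure(list(url = link, kind = cls$kind,
                           compression = cls$compression,
                           accession = NA_character_),
                      class = "resource_link")
  }
  if (!dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  dest <- file.path(cache_dir,
                    paste0(url_digest(link$url), "_", basename(link$url)))
  if (use_cache && file.exists(dest) && file.info(dest)$size > 0) {
    return(structure(
      list(link = link, local_path = dest,
           byte_size = file.info(dest)$size, from_cache = TRUE),
      class = "fetched_resource"
    ))
  }
  resp <- with_retries(function() {
    r <- tryCatch(transport_fetch(transport, link$url),
                  error = function(e) NULL)
    if (is.null(r) || r$status != 200L) NULL else r
  }, attempts = retries)
  if (is.null(resp)) {
    stop("fetch failed: ", link$url, call. = FALSE)
  }
  if (length(resp$body) == 0L) {
    stop("empty resource: ", link$url, call. = FALSE)
  }
  tmp <- tempfile(tmpdir = cache_dir, fileext = ".part")
  writeBin(resp$body, tmp)
  if (!file.rename(tmp, dest)) {
    unlink(tmp)
    stop("fetch failed: could not move downloaded file into place for ",
         link$url, call. = FALSE)
  }
  structure(
    list(link = link, local_path = dest,
         byte_size = length(resp$body), from_cache = FALSE),
    class = "fetched_resource"
  )
}
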