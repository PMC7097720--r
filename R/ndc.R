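#' Normalize National Drug Codes to the 11-digit 5-4-2 form
#'
#' US National Drug Codes are printed in several 10-digit hyphenated
#' dialects (4-4-2, 5-3-2, 5-4-1) depending on how the labeler, product and
#' package segments were assigned. Terminology lookups require the uniform
#' 11-digit 5-4-2 form, obtained by zero-padding the short segment of the
#' dialect. `normalize_ndc()` validates a vector of raw code strings and
#' returns one row per input with the parsed segments and the normalized
#' code.
#'
#' Accepted inputs are hyphenated three-segment codes with segment lengths
#' 5-4-2 (already normalized), 4-4-2, 5-3-2 or 5-4-1, and unhyphenated
#' 11-digit codes. Unhyphenated 10-digit codes are rejected: without
#' hyphens the dialect is ambiguous and padding would have to guess which
#' segment is short. Leading/trailing whitespace is trimmed; any other
#' non-digit content, internal whitespace, or segment pattern is invalid.
#'
#' Normalization is idempotent: re-normalizing either the `normalized` or
#' the `hyphenated` output reproduces the same code.
#'
#' @param raw character vector of NDC strings as received.
#' @param strict if `TRUE` (default) any invalid code raises a
#'   `rxmatch_validation_error`; if `FALSE` invalid codes yield a row with
#'   `valid = FALSE` and an `error_code`, so a pipeline can route them to
#'   the missing-concept stream instead of halting.
#'
#' @return A tibble with columns `raw`, `labeler` (5 digits), `product`
#'   (4 digits), `package` (2 digits), `normalized` (11 digits),
#'   `hyphenated` (`LLLLL-PPPP-KK`), `valid` (logical) and `error_code`
#'   (`NA`, `"non_digit"`, `"ambiguous_10_digit"`, `"bad_segments"`,
#'   `"bad_length"`, or `"empty"`).
#'
#' @examples
#' normalize_ndc("00008-0841-81")$normalized   # already 5-4-2
#' normalize_ndc("0008-0841-81")$normalized    # 4-4-2, labeler padded
#' normalize_ndc("12345-678-90")$normalized    # 5-3-2, product padded
#' normalize_ndc("0000-20002-02", strict = FALSE)$error_code
#' @export
normalize_ndc <- function(raw, strict = TRUE) {
  stopifnot(is.character(raw))
  out <- purrr::map(raw, ndc_parse_one)
  res <- dplyr::bind_rows(out)
  if (strict && any(!res$valid)) {
    bad <- res$raw[!res$valid][1L]
    code <- res$error_code[!res$valid][1L]
    rx_abort(
      "rxmatch_validation_error",
      sprintf("invalid NDC %s (%s)", encodeString(bad, quote = "\""), code),
      ndc = bad, error_code = code
    )
  }
  res
}

ndc_parse_one <- function(x) {
  row <- tibble::tibble(
    raw = if (is.na(x)) NA_character_ else x,
    labeler = NA_character_, product = NA_character_, package = NA_character_,
    normalized = NA_character_, hyphenated = NA_character_,
    valid = FALSE, error_code = NA_character_
  )
  fail <- function(code) { row$error_code <- code; row }

  if (is.na(x)) return(fail("empty"))
  x <- trimws(x)
  if (!nzchar(x)) return(fail("empty"))
  if (grepl("[^0-9-]", x)) return(fail("non_digit"))

  if (!grepl("-", x, fixed = TRUE)) {
    if (nchar(x) == 11L) {
      segs <- c(substr(x, 1, 5), substr(x, 6, 9), substr(x, 10, 11))
    } else if (nchar(x) == 10L) {
      return(fail("ambiguous_10_digit"))
    } else {
      return(fail("bad_length"))
    }
  } else {
    segs <- strsplit(x, "-", fixed = TRUE)[[1L]]
    if (length(segs) != 3L || any(!nzchar(segs))) return(fail("bad_segments"))
    lens <- nchar(segs)
    known <- list(c(5L, 4L, 2L), c(4L, 4L, 2L), c(5L, 3L, 2L), c(5L, 4L, 1L))
    if (!any(vapply(known, function(k) identical(lens, k), logical(1)))) {
      return(fail("bad_segments"))
    }
    segs <- sprintf(c("%05s", "%04s", "%02s"), segs)
    segs <- gsub(" ", "0", segs, fixed = TRUE)
  }

  row$labeler <- segs[1L]
  row$product <- segs[2L]
  row$package <- segs[3L]
  row$normalized <- paste0(segs, collapse = "")
  row$hyphenated <- paste(segs, collapse = "-")
  row$valid <- TRUE
  row$error_code <- NA_character_
  row
}
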