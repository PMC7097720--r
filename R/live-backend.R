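#' Live RxNorm REST API backend
#'
#' A terminology backend over the public RxNorm REST API. NDC lookups use
#' the `ndcstatus` endpoint (which resolves both current and retired NDCs),
#' term types come from `rxcui/{rxcui}/properties`, and branded or pack
#' concepts are expanded with `rxcui/{rxcui}/related?tty=SCD`. Attribute
#' lookups combine `related?tty=IN` (ingredients), `related?tty=DF` (dose
#' form) and the `AVAILABLE_STRENGTH` property; multi-ingredient strength
#' strings are assigned positionally to the sorted ingredient names, and a
#' pack quantity is recovered from the concept-name pattern
#' `"N (...) pack"`. Qualifier tags are not recoverable from the REST
#' properties and are returned empty; mismatch classification is therefore
#' highest-fidelity on fixture snapshots that carry explicit qualifiers.
#'
#' Every response is cached on disk keyed by (endpoint, argument), so
#' re-runs are deterministic and place no repeat load on the public API.
#' Requests are rate-limited and retried with exponential backoff;
#' exhausted retries signal `rxmatch_backend_unavailable`, which is
#' distinct from an NDC simply being unknown (a `NULL` data outcome).
#'
#' @param base_url root of the REST service (default the NLM RxNav host).
#' @param cache_dir directory for the persistent response cache; `NULL`
#'   disables caching.
#' @param rate_limit maximum requests per second.
#' @param transport function `(url) -> character(1)` returning the raw
#'   response body. The default fetches over HTTP; tests inject a
#'   transport that serves recorded or fixture-derived responses, so the
#'   backend contract can be exercised without a network.
#' @param retries transport attempts before giving up.
#' @return A backend of class `rx_live_backend`.
#' @export
rxnorm_live_backend <- function(base_url = "https://rxnav.nlm.nih.gov/REST",
                                cache_dir = NULL,
                                rate_limit = 10,
                                transport = NULL,
                                retries = 3L) {
  if (is.null(transport)) {
    transport <- function(url) paste(readLines(url, warn = FALSE),
                                     collapse = "\n")
  }
  if (!is.null(cache_dir))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  structure(
    list(base_url = sub("/$", "", base_url), cache_dir = cache_dir,
         rate_limit = rate_limit, transport = transport,
         retries = as.integer(retries),
         state = new.env(parent = emptyenv())),
    class = c("rx_live_backend", "rx_backend")
  )
}

#' @export
print.rx_live_backend <- function(x, ...) {
  cat("<rx_live_backend>", x$base_url,
      if (!is.null(x$cache_dir)) sprintf("(cache: %s)", x$cache_dir) else
        "(no cache)", "\n")
  invisible(x)
}

cache_key_path <- function(backend, path_q) {
  safe <- gsub("[^A-Za-z0-9._-]", "_", path_q)
  file.path(backend$cache_dir, sprintf("%s_%d.json", safe, nchar(path_q)))
}

live_get <- function(backend, path_q) {
  if (!is.null(backend$cache_dir)) {
    cp <- cache_key_path(backend, path_q)
    if (file.exists(cp)) {
      return(jsonlite::fromJSON(readChar(cp, file.size(cp)),
                                simplifyVector = FALSE))
    }
  }
  url <- paste0(backend$base_url, "/", path_q)
  # polite pacing against the public API
  last <- backend$state$last_request
  if (!is.null(last)) {
    wait <- 1 / backend$rate_limit - (as.numeric(Sys.time()) - last)
    if (wait > 0) Sys.sleep(wait)
  }
  txt <- NULL
  for (attempt in seq_len(backend$retries)) {
    backend$state$last_request <- as.numeric(Sys.time())
    txt <- tryCatch(backend$transport(url), error = function(e) NULL)
    if (!is.null(txt)) break
    Sys.sleep(0.5 * 2^(attempt - 1L))
  }
  if (is.null(txt))
    rx_abort("rxmatch_backend_unavailable",
             sprintf("terminology service unreachable after %d attempts: %s",
                     backend$retries, url))
  if (!is.null(backend$cache_dir)) writeLines(txt, cache_key_path(backend, path_q))
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

json_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)

#' @export
ndc_to_concept.rx_live_backend <- function(backend, ndc) {
  stopifnot(length(ndc) == 1L)
  st <- live_get(backend, sprintf("ndcstatus.json?ndc=%s", ndc))$ndcStatus
  status <- toupper(json_chr(st$status))
  rxcui <- json_chr(st$rxcui)
  if (is.na(status) || status %in% c("UNKNOWN", "NORXCUI") ||
      is.na(rxcui) || !nzchar(rxcui)) {
    return(NULL)
  }
  live_concept(backend, rxcui)
}

live_concept <- function(backend, rxcui) {
  pr <- live_get(backend,
                 sprintf("rxcui/%s/properties.json", rxcui))$properties
  if (is.null(pr)) return(NULL)
  tty <- json_chr(pr$tty)
  if (!tty %in% c("SCD", "SBD", "GPCK", "BPCK")) tty <- "OTHER"
  tibble::tibble(
    rxcui = json_chr(pr$rxcui),
    tty = tty,
    name = json_chr(pr$name),
    status = "active",
    curated = !identical(toupper(json_chr(pr$suppress)), "Y")
  )
}

related_by_tty <- function(backend, rxcui, tty) {
  rel <- live_get(backend,
                  sprintf("rxcui/%s/related.json?tty=%s", rxcui, tty))
  groups <- rel$relatedGroup$conceptGroup
  out <- character()
  nms <- character()
  for (g in groups) {
    for (cp in g$conceptProperties) {
      out <- c(out, json_chr(cp$rxcui))
      nms <- c(nms, json_chr(cp$name))
    }
  }
  names(out) <- nms
  out
}

#' @export
resolve_to_scds.rx_live_backend <- function(backend, rxcui) {
  if (is.data.frame(rxcui)) {
    row <- rxcui
  } else {
    row <- live_concept(backend, rxcui)
    if (is.null(row))
      rx_abort("rxmatch_unknown_concept",
               sprintf("concept %s not known to service", rxcui))
  }
  if (row$tty %in% c("SCD", "GPCK") || !isTRUE(row$curated)) {
    return(row$rxcui)
  }
  scds <- unname(related_by_tty(backend, row$rxcui, "SCD"))
  if (row$tty == "BPCK") {
    scds <- c(scds, unname(related_by_tty(backend, row$rxcui, "GPCK")))
  }
  scds <- scds[!is.na(scds) & nzchar(scds)]
  if (!length(scds))
    rx_abort("rxmatch_resolution_error",
             sprintf("%s concept %s has no related clinical drug",
                     row$tty, row$rxcui))
  sort(unique(scds))
}

#' @export
get_scd_attributes.rx_live_backend <- function(backend, rxcui) {
  row <- live_concept(backend, rxcui)
  if (is.null(row))
    rx_abort("rxmatch_unknown_concept",
             sprintf("concept %s not known to service", rxcui))
  if (!isTRUE(row$curated)) {
    return(new_scd_attributes(row$rxcui, curated = FALSE))
  }
  ingredients <- sort(unique(names(related_by_tty(backend, row$rxcui, "IN"))))
  forms <- names(related_by_tty(backend, row$rxcui, "DF"))
  dose_form <- if (length(forms)) tolower(forms[[1L]]) else NA_character_

  props <- live_get(backend,
                    sprintf("rxcui/%s/allProperties.json?prop=ATTRIBUTES",
                            row$rxcui))
  strength_str <- NA_character_
  for (p in props$propConceptGroup$propConcept) {
    if (identical(json_chr(p$propName), "AVAILABLE_STRENGTH"))
      strength_str <- json_chr(p$propValue)
  }
  strengths <- list()
  if (!is.na(strength_str) && length(ingredients)) {
    parts <- trimws(strsplit(strength_str, "/", fixed = TRUE)[[1L]])
    for (k in seq_along(ingredients)) {
      if (k > length(parts)) break
      m <- regmatches(parts[k],
                      regexec("^([0-9.]+)\\s*(.*)$", parts[k]))[[1L]]
      if (length(m) == 3L) {
        strengths[[ingredients[k]]] <-
          list(value = as.numeric(m[2L]), unit = canonical_unit(m[3L]))
      }
    }
  }
  pack_quantity <- NA_integer_
  pm <- regmatches(row$name, regexec("^\\s*([0-9]+)\\s*\\(", row$name))[[1L]]
  if (length(pm) == 2L && grepl("pack", row$name, ignore.case = TRUE))
    pack_quantity <- as.integer(pm[2L])

  new_scd_attributes(
    row$rxcui, curated = TRUE, ingredients = ingredients,
    strengths = strengths, dose_form = dose_form,
    pack_quantity = pack_quantity, qualifiers = character()
  )
}
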