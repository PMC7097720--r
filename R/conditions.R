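# Classed conditions used across the package. Every failure mode the
# pipeline distinguishes gets its own condition class so callers (and the
# CLI exit-code mapping) can branch on class rather than on message text.

rx_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "rxmatch_error"), ...)
}

#' @rdname rxmatch-conditions
#' @name rxmatch-conditions
#' @title Condition classes signalled by rxmatch
#' @description
#' All errors signalled by the package carry class `rxmatch_error` plus one
#' of the specific classes below, so callers can use `tryCatch()` on the
#' failure mode they care about:
#'
#' * `rxmatch_validation_error` — an NDC string that cannot be normalized
#'   (non-digit content, wrong segment lengths, ambiguous 10-digit form).
#' * `rxmatch_format_error` — a record-pair file missing required columns.
#' * `rxmatch_backend_unavailable` — live terminology transport failure
#'   after retries (distinct from an NDC simply being absent, which is a
#'   data outcome, not an error).
#' * `rxmatch_resolution_error` — a branded or pack concept with no related
#'   clinical-drug concept in the snapshot.
#' * `rxmatch_unknown_concept` — an attribute lookup for an identifier the
#'   snapshot does not contain.
#' * `rxmatch_attribute_unavailable` — a curated concept that should carry
#'   attributes but does not (data-integrity failure in the snapshot).
#' * `rxmatch_config_error` — an invalid synthetic-generator configuration.
#' * `rxmatch_generation_error` — a generator request the terminology cannot
#'   satisfy (e.g. a pack-quantity mismatch with no pack concepts).
NULL
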