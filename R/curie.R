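#' Canonicalize a compact identifier (CURIE)
#'
#' Builds the canonical `namespace:code` rendering of an identifier. The
#' namespace is lowercased and mapped through the registry synonym table
#' (e.g. `"RxNorm"` -> `"rxcui"`); the code is whitespace-trimmed with case
#' preserved. Codes containing `":"` are rejected so that the rendered form
#' splits unambiguously at its single separator.
#'
#' @param namespace_raw Raw namespace string.
#' @param code_raw Raw code string.
#' @param registry A [default_registry()] object.
#' @return A length-1 character CURIE, e.g. `"rxcui:282388"`.
#' @examples
#' canonicalize_curie("RxNorm", " 282388 ")
#' canonicalize_curie("drugbank", "DB00619")
#' @export
canonicalize_curie <- function(namespace_raw, code_raw,
                               registry = default_registry()) {
  ns_in <- trimws(namespace_raw)
  code <- trimws(code_raw)
  if (!nzchar(ns_in) || !nzchar(code))
    tn_stop("namespace and code must be nonempty after trimming",
            "theranorm_curie_error")
  if (grepl(":", code, fixed = TRUE))
    tn_stop(sprintf("code %s contains ':'; colons are reserved for the namespace separator",
                    dQuote(code)),
            "theranorm_curie_error")
  ns <- resolve_namespace(registry, ns_in)
  if (is.na(ns))
    tn_stop(sprintf("unknown namespace %s: not a registered source or external namespace",
                    dQuote(ns_in)),
            "theranorm_unknown_namespace")
  paste0(ns, ":", code)
}

#' Split a rendered CURIE into namespace and code
#'
#' @param x Character vector of rendered CURIEs (`namespace:code`).
#' @return For `curie_namespace`/`curie_code`, a character vector.
#' @examples
#' curie_namespace("rxcui:282388")
#' curie_code("drugbank:DB00619")
#' @export
curie_namespace <- function(x) sub(":.*$", "", x)

#' @rdname curie_namespace
#' @export
curie_code <- function(x) sub("^[^:]*:", "", x)

#' Parse and canonicalize a rendered CURIE
#'
#' Accepts `"namespace:code"` (namespace in any case or synonym form,
#' optional whitespace around the code) and returns the canonical
#' rendering. Errors if the string does not contain exactly one colon or
#' the namespace is unknown.
#'
#' @param x Length-1 character string.
#' @inheritParams canonicalize_curie
#' @return Canonical CURIE string.
#' @export
parse_curie <- function(x, registry = default_registry()) {
  x <- trimws(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    tn_stop(sprintf("malformed CURIE %s: expected exactly one ':'", dQuote(x)),
            "theranorm_curie_error")
  canonicalize_curie(parts[[1]], parts[[2]], registry)
}
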