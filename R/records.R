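#' Construct a source record
#'
#' One therapeutic entry from one source vocabulary: its CURIE identifier,
#' display label, alias and trade-name sets, outgoing cross-references
#' ("has reference to" edges toward equivalent records in other sources),
#' free-form association annotations, and an optional regulatory-approval
#' annotation. String fields are NFC-normalized on construction so that
#' multi-language labels survive round-trips byte-identically.
#'
#' @param id CURIE identifier (`namespace:code`), canonical form.
#' @param label Display label; may be empty.
#' @param aliases Character vector of aliases (whitespace-only entries are
#'   invalid).
#' @param trade_names Character vector of marketed brand names.
#' @param xrefs Character vector of CURIEs this record references.
#' @param associations Character vector of tagged annotation strings
#'   (e.g. `"indication:chronic myeloid leukemia"`).
#' @param approval Optional list with elements `status` (character) and
#'   `application_codes` (character vector), or `NULL`.
#' @return An object of class `source_record`.
#' @examples
#' source_record("rxcui:282388", label = "imatinib mesylate",
#'               xrefs = "drugbank:DB00619")
#' @export
source_record <- function(id, label = "", aliases = character(),
                          trade_names = character(), xrefs = character(),
                          associations = character(), approval = NULL) {
  nfc <- function(x) stringi::stri_trans_nfc(enc2utf8(as.character(x)))
  structure(
    list(
      id = nfc(id),
      label = if (length(label)) nfc(label) else "",
      aliases = nfc(aliases),
      trade_names = nfc(trade_names),
      xrefs = nfc(xrefs),
      associations = nfc(associations),
      approval = if (!is.null(approval))
        list(status = nfc(approval$status %||% character()),
             application_codes = nfc(approval$application_codes %||% character()))
    ),
    class = "source_record"
  )
}

#' Validate a source record against its schema invariants
#'
#' Checks: the id parses as a CURIE whose namespace is a registered source;
#' no alias or trade name is empty after whitespace trimming; no xref
#' equals the record's own id; every xref namespace is registered (source
#' or external). Violations are returned as data, not raised.
#'
#' @param record A [source_record()].
#' @param registry A [default_registry()] object.
#' @return A data frame with columns `field`, `rule`, `message`; zero rows
#'   iff the record is valid.
#' @export
validate_record <- function(record, registry = default_registry()) {
  v <- list()
  add <- function(field, rule, message)
    v[[length(v) + 1L]] <<- data.frame(field = field, rule = rule,
                                       message = message)
  ns <- curie_namespace(record$id)
  if (!grepl("^[^:]+:[^:]+$", record$id))
    add("id", "curie-form", sprintf("id %s is not of the form namespace:code",
                                    dQuote(record$id)))
  else if (!is_source_namespace(registry, ns))
    add("id", "source-namespace",
        sprintf("id namespace %s is not a registered source", dQuote(ns)))
  for (f in c("aliases", "trade_names")) {
    bad <- !nzchar(trimws(record[[f]]))
    if (any(bad))
      add(f, "empty-term",
          sprintf("%d %s entr%s empty after whitespace trimming",
                  sum(bad), sub("_", " ", f), if (sum(bad) == 1L) "y is" else "ies are"))
  }
  if (record$id %in% record$xrefs)
    add("xrefs", "self-xref", "record references its own id")
  xns <- unique(curie_namespace(record$xrefs))
  unknown <- xns[vapply(xns, function(n) is.na(resolve_namespace(registry, n)), TRUE)]
  if (length(unknown))
    add("xrefs", "unknown-namespace",
        sprintf("xref namespace(s) not registered: %s",
                paste(unknown, collapse = ", ")))
  if (length(v)) do.call(rbind, v)
  else data.frame(field = character(), rule = character(), message = character())
}

#' Parse line-delimited JSON therapeutic records
#'
#' Reads the record interchange format: one JSON object per line with
#' fields `id`, `label`, `aliases`, `trade_names`, `xrefs`, `associations`,
#' `approval` (absent arrays are treated as empty). Every record is
#' validated, its id namespace must match the declaring source's, and
#' duplicate ids within one stream are an error.
#'
#' @param lines Character vector, one JSON record per element.
#' @param meta A [source_meta()] for the declaring source, or `NULL` to
#'   skip the namespace-match check (mixed-source streams).
#' @param registry A [default_registry()] object.
#' @return List of [source_record()] in input order.
#' @examples
#' rec <- parse_source_records(
#'   '{"id": "rxcui:282388", "label": "imatinib mesylate", "xrefs": ["drugbank:DB00619"]}',
#'   meta = source_meta("rxcui", 1))
#' rec[[1]]$xrefs
#' @export
parse_source_records <- function(lines, meta = NULL,
                                 registry = default_registry()) {
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      tn_stop(sprintf("line %d: malformed record JSON (%s)",
                                      i, conditionMessage(e)),
                              "theranorm_parse_error"))
    if (is.null(obj$id))
      tn_stop(sprintf("line %d: record has no id", i), "theranorm_parse_error")
    id <- parse_curie(obj$id, registry)
    xrefs <- vapply(as.character(obj$xrefs %||% character()),
                    parse_curie, "", registry = registry, USE.NAMES = FALSE)
    rec <- source_record(
      id = id,
      label = as.character(obj$label %||% ""),
      aliases = as.character(obj$aliases %||% character()),
      trade_names = as.character(obj$trade_names %||% character()),
      xrefs = xrefs,
      associations = as.character(obj$associations %||% character()),
      approval = obj$approval
    )
    viol <- validate_record(rec, registry)
    if (nrow(viol))
      tn_stop(sprintf("line %d: invalid record %s: %s", i, rec$id,
                      paste(viol$message, collapse = "; ")),
              "theranorm_parse_error")
    if (!is.null(meta) && curie_namespace(rec$id) != meta$name)
      tn_stop(sprintf("line %d: record %s does not belong to declared source %s",
                      i, rec$id, dQuote(meta$name)),
              "theranorm_source_mismatch")
    records[[i]] <- rec
  }
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    tn_stop(sprintf("duplicate record id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "theranorm_duplicate_record")
  records
}

#' Serialize source records to interchange lines
#'
#' Inverse of [parse_source_records()]: emits one JSON object per record
#' with a fixed field order, omitting empty arrays and absent approval so
#' that parse-serialize round-trips are field-by-field identities.
#'
#' @param records List of [source_record()].
#' @return Character vector of JSON lines.
#' @export
serialize_source_records <- function(records) {
  vapply(records, function(r) {
    obj <- list(id = r$id)
    if (nzchar(r$label)) obj$label <- r$label
    for (f in c("aliases", "trade_names", "xrefs", "associations"))
      if (length(r[[f]])) obj[[f]] <- as.list(r[[f]])
    if (!is.null(r$approval))
      obj$approval <- list(status = as.list(r$approval$status),
                           application_codes = as.list(r$approval$application_codes))
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, "")
}

#' Read / write record interchange files
#'
#' @param path File path (UTF-8, one JSON record per line).
#' @inheritParams parse_source_records
#' @return `read_source_records`: list of [source_record()];
#'   `write_source_records`: the path, invisibly.
#' @export
read_source_records <- function(path, meta = NULL,
                                registry = default_registry()) {
  if (!file.exists(path))
    tn_stop(sprintf("no such file: %s", path), "theranorm_io_error")
  parse_source_records(readLines(path, encoding = "UTF-8"), meta, registry)
}

#' @rdname read_source_records
#' @param records List of [source_record()].
#' @export
write_source_records <- function(records, path) {
  writeLines(serialize_source_records(records), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.source_record <- function(x, ...) {
  cat("<source_record> ", x$id, "\n", sep = "")
  if (nzchar(x$label)) cat("  label:       ", x$label, "\n", sep = "")
  if (length(x$aliases))
    cat("  aliases:     ", paste(x$aliases, collapse = ", "), "\n", sep = "")
  if (length(x$trade_names))
    cat("  trade names: ", paste(x$trade_names, collapse = ", "), "\n", sep = "")
  if (length(x$xrefs))
    cat("  xrefs:       ", paste(x$xrefs, collapse = ", "), "\n", sep = "")
  invisible(x)
}
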