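# Registry persistence: delimited text (TSV default, CSV selectable) and a
# mirrored JSON export. write -> read is the identity on canonical
# registries; read refuses files whose rows fail the checksum or whose
# content violates any registry invariant.

.registry_columns <- c("identifier", "code", "source_ref", "domain",
                       "label_fr", "label_en", "label_es", "label_pt",
                       "operational")

.dialect_sep <- function(dialect) {
  dialect <- match.arg(dialect, c("tsv", "csv"))
  if (dialect == "tsv") "\t" else ","
}

#' Write a registry to delimited text
#'
#' @param registry An `unhs_registry`.
#' @param path Output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, dialect = "tsv") {
  stopifnot(inherits(registry, "unhs_registry"))
  cc <- registry$concepts[, .registry_columns, drop = FALSE]
  cc$identifier <- format(cc$identifier, scientific = FALSE, trim = TRUE)
  cc$operational <- ifelse(cc$operational, "true", "false")
  utils::write.table(cc, path, sep = .dialect_sep(dialect), quote = TRUE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a registry from delimited text
#'
#' Every row's code is checksum-validated (failures are reported with their
#' line numbers) and the full set of registry invariants is audited before
#' the registry is returned; a file violating any of them is rejected.
#'
#' @param path Input file path with header columns identifier, code,
#'   source_ref, domain, label_fr, label_en, label_es, label_pt,
#'   operational.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param classifications Classification table used to validate source
#'   references; defaults to [default_classifications()].
#' @return An `unhs_registry`.
#' @export
read_registry <- function(path, dialect = "tsv",
                          classifications = default_classifications()) {
  raw <- utils::read.table(path, sep = .dialect_sep(dialect), header = TRUE,
                           quote = "\"", colClasses = "character",
                           na.strings = "", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE, comment.char = "")
  missing_cols <- setdiff(.registry_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("registry file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, .registry_columns]

  identifier <- suppressWarnings(as.numeric(raw$identifier))
  bad_id <- which(is.na(identifier) | identifier < 1 |
                  identifier != floor(identifier))
  if (length(bad_id) > 0L) {
    stop("malformed identifier at line ", bad_id[1] + 1L, " of ", path,
         ": ", sQuote(raw$identifier[bad_id[1]]), call. = FALSE)
  }
  op_raw <- tolower(trimws(raw$operational))
  if (!all(op_raw %in% c("true", "false"))) {
    bad <- which(!op_raw %in% c("true", "false"))[1]
    stop("malformed operational flag at line ", bad + 1L, " of ", path,
         call. = FALSE)
  }

  for (i in seq_len(nrow(raw))) {
    v <- validate_code(raw$code[i])
    if (!v$valid) {
      stop("invalid code at line ", i + 1L, " of ", path, ": ", v$reason,
           call. = FALSE)
    }
  }

  registry <- unhs_registry(classifications)
  registry$concepts <- data.frame(
    identifier = identifier,
    code = toupper(raw$code),
    source_ref = raw$source_ref,
    domain = canonical_domain(raw$domain),
    label_fr = raw$label_fr, label_en = raw$label_en,
    label_es = raw$label_es, label_pt = raw$label_pt,
    operational = op_raw == "true",
    stringsAsFactors = FALSE
  )
  registry$next_identifier <- max(identifier) + 1

  problems <- registry_audit(registry)
  if (length(problems) > 0L) {
    stop("registry file ", path, " violates registry invariants:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  registry
}

#' Export a registry as JSON
#'
#' Mirrors the delimited schema: an array of concept objects plus the
#' classification table and the allocation counter.
#'
#' @param registry An `unhs_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_registry_json <- function(registry, path) {
  stopifnot(inherits(registry, "unhs_registry"))
  payload <- list(
    classifications = data.frame(
      name = registry$classifications$name,
      prefix = registry$classifications$prefix,
      domains = vapply(registry$classifications$domains,
                       paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    ),
    concepts = registry$concepts[, .registry_columns, drop = FALSE],
    next_identifier = registry$next_identifier
  )
  jsonlite::write_json(payload, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
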