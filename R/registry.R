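# Concept registry: sequential identifier allocation, source-classification
# prefixes, multilingual labels, national extensions and operational codes.

#' The twelve health-service domain acronyms
#'
#' Hospital procedures (PROC), evaluation and management (EVAL), medications
#' (MED), prosthetics (PROT), consumables and devices (CONS), transportation
#' (TRANS), hospital accommodation (LOG), laboratory (LAB), medical imaging
#' (IMG), radiotherapy (RXT), physical rehabilitation (PHY) and mental
#' health (MENT).
#' @export
unhs_domains <- c("PROC", "EVAL", "MED", "PROT", "CONS", "TRANS",
                  "LOG", "LAB", "IMG", "RXT", "PHY", "MENT")

# Legacy spellings accepted on input, mapped to the canonical acronym.
.domain_aliases <- c(TRAN = "TRANS")

.languages <- c("fr", "en", "es", "pt")

canonical_domain <- function(domain) {
  domain <- toupper(trimws(domain))
  hit <- match(domain, names(.domain_aliases))
  domain[!is.na(hit)] <- .domain_aliases[hit[!is.na(hit)]]
  bad <- !domain %in% unhs_domains
  if (any(bad)) {
    stop("unknown domain acronym: ", paste(unique(domain[bad]), collapse = ", "),
         " (expected one of ", paste(unhs_domains, collapse = ", "), ")",
         call. = FALSE)
  }
  domain
}

#' Default source-classification table
#'
#' The six international classifications with their one-letter prefixes and
#' the domains each one serves: ICD-10-PCS (I: MENT, PHY, PROC, IMG, RXT),
#' CPT (C: EVAL), HCPCS (H: CONS, PROT, TRANS), LOINC (L: LAB),
#' RxNorm (R: MED), UB04 (U: LOG).
#'
#' @return A data frame with columns `name`, `prefix` and `domains`
#'   (a list column of domain acronyms).
#' @export
default_classifications <- function() {
  data.frame(
    name = c("ICD-10-PCS", "CPT", "HCPCS", "LOINC", "RxNorm", "UB04"),
    prefix = c("I", "C", "H", "L", "R", "U"),
    domains = I(list(
      c("MENT", "PHY", "PROC", "IMG", "RXT"),
      "EVAL",
      c("CONS", "PROT", "TRANS"),
      "LAB",
      "MED",
      "LOG"
    )),
    stringsAsFactors = FALSE
  )
}

.empty_concepts <- function() {
  data.frame(
    identifier = numeric(0), code = character(0),
    source_ref = character(0), domain = character(0),
    label_fr = character(0), label_en = character(0),
    label_es = character(0), label_pt = character(0),
    operational = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Create an empty concept registry
#'
#' @param classifications A classification table as returned by
#'   [default_classifications()]; prefixes must be unique single letters.
#' @return An object of class `"unhs_registry"` holding the concept table,
#'   the classification table and the next free identifier.
#' @export
unhs_registry <- function(classifications = default_classifications()) {
  stopifnot(is.data.frame(classifications),
            all(c("name", "prefix", "domains") %in% names(classifications)))
  if (anyDuplicated(classifications$prefix) ||
      any(nchar(classifications$prefix) != 1L)) {
    stop("classification prefixes must be unique single letters",
         call. = FALSE)
  }
  structure(
    list(concepts = .empty_concepts(),
         classifications = classifications,
         next_identifier = 1),
    class = "unhs_registry"
  )
}

#' @export
print.unhs_registry <- function(x, ...) {
  ext <- grepl(".", x$concepts$code, fixed = TRUE)
  cat("<unhs_registry> ", nrow(x$concepts), " concepts (",
      sum(ext), " extensions, ", sum(x$concepts$operational),
      " operational), next identifier ",
      format(x$next_identifier, scientific = FALSE), "\n", sep = "")
  invisible(x)
}

.label_row <- function(labels) {
  labels <- as.list(labels)
  if (length(labels) == 0L || is.null(names(labels)) ||
      !all(names(labels) %in% .languages)) {
    stop("labels must be a named list/vector over languages ",
         paste(.languages, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(rep(NA_character_, length(.languages)),
                         paste0("label_", .languages))
  for (lang in names(labels)) {
    val <- trimws(as.character(labels[[lang]]))
    if (!is.na(val) && nzchar(val)) out[paste0("label_", lang)] <- val
  }
  if (all(is.na(out))) {
    stop("at least one non-empty label is required", call. = FALSE)
  }
  out
}

.find_classification <- function(registry, classification) {
  i <- match(classification, registry$classifications$name)
  if (is.na(i)) {
    stop("unknown classification ", sQuote(classification),
         "; registered: ",
         paste(registry$classifications$name, collapse = ", "), call. = FALSE)
  }
  i
}

.append_concept <- function(registry, identifier, code, source_ref, domain,
                            labels, operational) {
  row <- data.frame(
    identifier = identifier, code = code,
    source_ref = source_ref, domain = domain,
    t(.label_row(labels)),
    operational = operational,
    stringsAsFactors = FALSE
  )
  registry$concepts <- rbind(registry$concepts, row)
  rownames(registry$concepts) <- NULL
  attr(registry, "last_code") <- code
  registry
}

#' Register a concept from an international source classification
#'
#' Allocates the next sequential identifier, derives the canonical code from
#' it, and binds it to `<prefix>-<source_code>` in the given domain. The
#' same (classification, source code, domain) triple cannot be registered
#' twice.
#'
#' @param registry An `unhs_registry`.
#' @param source_code The code in the source classification (e.g. "A0428").
#' @param classification Name of a registered classification (e.g. "HCPCS").
#' @param domain Domain acronym; must belong to the classification's domain
#'   set ("TRAN" is accepted as an alias of "TRANS").
#' @param labels Named character vector/list over languages fr, en, es, pt;
#'   at least one non-empty label.
#' @return The updated registry. The code just created is available as
#'   `attr(registry, "last_code")` and through [lookup_code()].
#' @examples
#' reg <- unhs_registry()
#' reg <- register_concept(reg, "A0428", "HCPCS", "TRANS",
#'                         c(en = "Ambulance service"))
#' attr(reg, "last_code")  # "AY" (identifier 1)
#' @export
register_concept <- function(registry, source_code, classification, domain,
                             labels) {
  stopifnot(inherits(registry, "unhs_registry"))
  domain <- canonical_domain(domain)
  source_code <- trimws(as.character(source_code))
  if (!nzchar(source_code)) stop("source_code must be non-empty", call. = FALSE)
  i <- .find_classification(registry, classification)
  allowed <- registry$classifications$domains[[i]]
  if (!domain %in% allowed) {
    stop("domain ", domain, " is not served by ", classification,
         " (its domains: ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  }
  prefix <- registry$classifications$prefix[i]
  source_ref <- paste0(prefix, "-", source_code)
  dup <- registry$concepts$source_ref == source_ref &
         registry$concepts$domain == domain &
         !grepl(".", registry$concepts$code, fixed = TRUE)
  if (any(dup, na.rm = TRUE)) {
    stop("already registered: ", source_ref, " in domain ", domain,
         call. = FALSE)
  }
  n <- registry$next_identifier
  registry$next_identifier <- n + 1
  .append_concept(registry, n, make_code(n), source_ref, domain, labels,
                  operational = FALSE)
}

#' Add a national extension under a parent code
#'
#' Extension codes append `".k"` to the parent's code, with `k` the next
#' free suffix (1, 2, 3, ... dense from 1). The extension inherits the
#' parent's domain and source reference and records its hierarchical
#' dependence in the code itself. Extensions of extensions are not allowed
#' (the hierarchy is single-level). The extension row still receives its own
#' sequential identifier for bookkeeping; that identifier is not encoded in
#' the extension's code.
#'
#' @param registry An `unhs_registry`.
#' @param parent_code Canonical code of an existing non-extension concept.
#' @param labels Named labels as in [register_concept()].
#' @return The updated registry.
#' @examples
#' reg <- unhs_registry()
#' reg <- register_concept(reg, "BW0CZZZ", "ICD-10-PCS", "IMG",
#'                         c(en = "Plain radiography of lower extremity"))
#' reg <- add_extension(reg, attr(reg, "last_code"),
#'                      c(en = "Plain radiography of lower extremity - front view"))
#' @export
add_extension <- function(registry, parent_code, labels) {
  stopifnot(inherits(registry, "unhs_registry"))
  parent_code <- toupper(trimws(parent_code))
  if (grepl(".", parent_code, fixed = TRUE)) {
    stop("cannot extend ", sQuote(parent_code),
         ": extensions of extensions are not allowed", call. = FALSE)
  }
  j <- match(parent_code, registry$concepts$code)
  if (is.na(j)) {
    stop("unknown parent code ", sQuote(parent_code), call. = FALSE)
  }
  pattern <- paste0("^", parent_code, "\\.([0-9]+)$")
  existing <- grep(pattern, registry$concepts$code, value = TRUE)
  k <- if (length(existing) == 0L) 1L
       else max(as.integer(sub(pattern, "\\1", existing))) + 1L
  n <- registry$next_identifier
  registry$next_identifier <- n + 1
  .append_concept(registry, n, paste0(parent_code, ".", k),
                  registry$concepts$source_ref[j],
                  registry$concepts$domain[j],
                  labels, operational = registry$concepts$operational[j])
}

#' Add an operational code (no international equivalent)
#'
#' Operational codes serve local needs — brand management, research,
#' services with no counterpart in any source classification. They carry no
#' source reference.
#'
#' @param registry An `unhs_registry`.
#' @param domain Domain acronym.
#' @param labels Named labels as in [register_concept()].
#' @return The updated registry.
#' @export
add_operational <- function(registry, domain, labels) {
  stopifnot(inherits(registry, "unhs_registry"))
  domain <- canonical_domain(domain)
  n <- registry$next_identifier
  registry$next_identifier <- n + 1
  .append_concept(registry, n, make_code(n), NA_character_, domain, labels,
                  operational = TRUE)
}

#' Look up a concept by code
#'
#' @param registry An `unhs_registry`.
#' @param code A code string (uppercased before matching).
#' @return A list with `status` — `"found"`, `"not_found"` or
#'   `"checksum_invalid"` — and, when found, `concept` (a one-row data
#'   frame). Checksum failures are reported distinctly from mere absence.
#' @export
lookup_code <- function(registry, code) {
  stopifnot(inherits(registry, "unhs_registry"))
  v <- validate_code(code)
  if (!v$valid) {
    return(list(status = "checksum_invalid", concept = NULL,
                reason = v$reason))
  }
  canonical <- parse_code(code)$canonical
  j <- match(canonical, registry$concepts$code)
  if (is.na(j)) return(list(status = "not_found", concept = NULL,
                            reason = NA_character_))
  list(status = "found", concept = registry$concepts[j, , drop = FALSE],
       reason = NA_character_)
}

#' Audit a registry against all structural invariants
#'
#' Checks identifier and code uniqueness, per-row checksums, the
#' identifier-to-code relation for non-extension rows, parent existence and
#' dense suffix numbering for extensions, the operational/source-reference
#' exclusion, prefix/domain consistency, label presence, and the allocation
#' counter.
#'
#' @param registry An `unhs_registry`.
#' @return Character vector of violation messages; empty when the registry
#'   is sound.
#' @export
registry_audit <- function(registry) {
  stopifnot(inherits(registry, "unhs_registry"))
  cc <- registry$concepts
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  if (nrow(cc) == 0L) return(problems)

  if (anyDuplicated(cc$identifier))
    note("duplicate identifiers: ",
         paste(unique(cc$identifier[duplicated(cc$identifier)]), collapse = ", "))
  if (anyDuplicated(cc$code))
    note("duplicate codes: ",
         paste(unique(cc$code[duplicated(cc$code)]), collapse = ", "))
  if (registry$next_identifier <= max(cc$identifier))
    note("next_identifier (", registry$next_identifier,
         ") must exceed every allocated identifier")

  is_ext <- grepl(".", cc$code, fixed = TRUE)
  for (i in seq_len(nrow(cc))) {
    v <- validate_code(cc$code[i])
    if (!v$valid) note("row ", i, " (", cc$code[i], "): ", v$reason)
  }
  plain <- which(!is_ext)
  bad_map <- plain[cc$code[plain] != make_code(cc$identifier[plain])]
  for (i in bad_map)
    note("row ", i, ": code ", cc$code[i],
         " does not derive from identifier ",
         format(cc$identifier[i], scientific = FALSE),
         " (expected ", make_code(cc$identifier[i]), ")")

  if (any(is_ext)) {
    parents <- sub("\\..*$", "", cc$code[is_ext])
    missing <- !parents %in% cc$code[!is_ext]
    for (p in unique(parents[missing]))
      note("extension parent ", p, " is not in the registry")
    for (p in unique(parents)) {
      suf <- sort(as.integer(sub("^.*\\.", "",
                                 cc$code[is_ext][parents == p])))
      if (!identical(suf, seq_along(suf)))
        note("extension suffixes under ", p,
             " are not dense from 1: ", paste(suf, collapse = ", "))
    }
  }

  bad_op <- which(cc$operational & !is.na(cc$source_ref))
  for (i in bad_op)
    note("row ", i, " (", cc$code[i],
         "): operational concepts must not carry a source_ref")

  labels <- as.matrix(cc[, paste0("label_", .languages)])
  no_label <- which(apply(labels, 1L, function(r) all(is.na(r) | !nzchar(r))))
  for (i in no_label)
    note("row ", i, " (", cc$code[i], "): no label in any language")

  with_ref <- which(!is.na(cc$source_ref) & !is_ext)
  for (i in with_ref) {
    prefix <- sub("-.*$", "", cc$source_ref[i])
    j <- match(prefix, registry$classifications$prefix)
    if (is.na(j)) {
      note("row ", i, " (", cc$code[i], "): source_ref prefix ",
           sQuote(prefix), " matches no registered classification")
    } else if (!cc$domain[i] %in% registry$classifications$domains[[j]]) {
      note("row ", i, " (", cc$code[i], "): domain ", cc$domain[i],
           " is outside the ", registry$classifications$name[j],
           " domain set")
    }
  }
  problems
}
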