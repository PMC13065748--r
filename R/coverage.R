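# Coverage analysis: classify each catalog item against a registry and roll
# the per-item statuses up into per-domain and overall coverage rates.

.coverage_statuses <- c("direct", "extension_required", "operational_only",
                        "header_mapped", "unmatched")

#' Classify catalog items against a registry
#'
#' Each item receives exactly one status:
#' \describe{
#'   \item{direct}{an exact concept match — via a mapping hint or
#'     normalized-label equality with a registry label in any language.}
#'   \item{extension_required}{the item matches a parent concept but needs a
#'     new dot-suffix to be billable at its granularity (e.g. an imaging
#'     view qualifier).}
#'   \item{operational_only}{the mapping marks the item as having no
#'     international equivalent.}
#'   \item{header_mapped}{assigned to a more generic header code.}
#'   \item{unmatched}{nothing in the registry accounts for the item.}
#' }
#'
#' @param catalog A catalog data frame (facility_id, local_code, label,
#'   optional price and domain).
#' @param registry A validated `unhs_registry`.
#' @param mapping Optional expert hints: a data frame with columns `item`
#'   (row index into the catalog), `relation` (one of "direct",
#'   "extension", "header", "operational") and `code` (the target registry
#'   code; ignored for "operational"). Hint codes failing their checksum or
#'   absent from the registry are rejected. Items without a hint fall back
#'   to normalized-label matching.
#' @param fuzzy Enable fuzzy label matching for unhinted items (off by
#'   default; the conservative default mirrors a manual-review workflow).
#' @param max_dist Maximum edit distance between normalized labels for a
#'   fuzzy match.
#' @return A data frame with one row per item: `item`, `facility_id`,
#'   `local_code`, `label`, `domain`, `status`, `matched_code`, `fuzzy`.
#'   The domain comes from the matched concept when there is one, else from
#'   the catalog's own `domain` column.
#' @export
match_catalog_to_registry <- function(catalog, registry, mapping = NULL,
                                      fuzzy = FALSE, max_dist = 2) {
  catalog <- as_catalog(catalog)
  stopifnot(inherits(registry, "unhs_registry"))
  n <- nrow(catalog)
  status <- rep(NA_character_, n)
  matched_code <- rep(NA_character_, n)
  fuzzy_flag <- rep(FALSE, n)
  domain <- if ("domain" %in% names(catalog)) {
    as.character(catalog$domain)
  } else {
    rep(NA_character_, n)
  }

  cc <- registry$concepts

  if (!is.null(mapping)) {
    stopifnot(is.data.frame(mapping),
              all(c("item", "relation") %in% names(mapping)))
    if (!"code" %in% names(mapping)) mapping$code <- NA_character_
    bad_item <- mapping$item < 1 | mapping$item > n |
      mapping$item != floor(mapping$item)
    if (any(bad_item)) {
      stop("mapping references unknown item(s): ",
           paste(mapping$item[bad_item], collapse = ", "), call. = FALSE)
    }
    rel <- as.character(mapping$relation)
    bad_rel <- !rel %in% c("direct", "extension", "header", "operational")
    if (any(bad_rel)) {
      stop("unknown mapping relation(s): ",
           paste(unique(rel[bad_rel]), collapse = ", "),
           " (expected direct, extension, header or operational)",
           call. = FALSE)
    }
    for (k in seq_len(nrow(mapping))) {
      i <- mapping$item[k]
      if (rel[k] == "operational") {
        status[i] <- "operational_only"
        next
      }
      code <- toupper(trimws(mapping$code[k]))
      v <- validate_code(code)
      if (!v$valid) {
        stop("mapping hint for item ", i, " fails validation: ", v$reason,
             call. = FALSE)
      }
      j <- match(parse_code(code)$canonical, cc$code)
      if (is.na(j)) {
        stop("mapping hint for item ", i, " names code ", code,
             " which is not in the registry", call. = FALSE)
      }
      status[i] <- switch(rel[k],
                          direct = "direct",
                          extension = "extension_required",
                          header = "header_mapped")
      matched_code[i] <- cc$code[j]
      domain[i] <- cc$domain[j]
    }
  }

  todo <- which(is.na(status))
  if (length(todo) > 0L && nrow(cc) > 0L) {
    label_cols <- paste0("label_", .languages)
    reg_labels <- normalize_label(unlist(cc[, label_cols], use.names = FALSE))
    reg_codes <- rep(cc$code, times = length(label_cols))
    reg_domains <- rep(cc$domain, times = length(label_cols))
    keep <- !is.na(reg_labels) & nzchar(reg_labels)
    reg_labels <- reg_labels[keep]
    reg_codes <- reg_codes[keep]
    reg_domains <- reg_domains[keep]

    keys <- normalize_label(catalog$label[todo])
    hit <- match(keys, reg_labels)
    found <- !is.na(hit)
    status[todo[found]] <- "direct"
    matched_code[todo[found]] <- reg_codes[hit[found]]
    domain[todo[found]] <- reg_domains[hit[found]]

    if (fuzzy && any(!found)) {
      rest <- todo[!found]
      dm <- utils::adist(normalize_label(catalog$label[rest]), reg_labels)
      best <- apply(dm, 1L, which.min)
      bestd <- dm[cbind(seq_along(rest), best)]
      ok <- bestd <= max_dist
      status[rest[ok]] <- "direct"
      matched_code[rest[ok]] <- reg_codes[best[ok]]
      domain[rest[ok]] <- reg_domains[best[ok]]
      fuzzy_flag[rest[ok]] <- TRUE
    }
  }
  status[is.na(status)] <- "unmatched"

  data.frame(
    item = seq_len(n),
    facility_id = catalog$facility_id,
    local_code = catalog$local_code,
    label = catalog$label,
    domain = domain,
    status = factor(status, levels = .coverage_statuses),
    matched_code = matched_code,
    fuzzy = fuzzy_flag,
    stringsAsFactors = FALSE
  )
}

#' Roll per-item statuses up into a coverage report
#'
#' For every domain (and an Overall row) reports, as percentages of that
#' row's items, rounded half-up to one decimal:
#' \describe{
#'   \item{international_coverage_pct}{items matched directly to a source
#'     concept.}
#'   \item{national_extension_pct}{items requiring any national addition —
#'     a new extension suffix, a header mapping, or an operational code.}
#'   \item{operational_only_pct}{the subset with no international
#'     equivalent at all.}
#'   \item{overall_coverage_pct}{items the nomenclature accounts for
#'     through an internationally anchored code: direct + extension +
#'     header. Operational-only items are excluded from this numerator (and
#'     all raw shares are reported so any alternative roll-up can be
#'     recomputed).}
#' }
#'
#' @param statuses A data frame with columns `domain` and `status` (one row
#'   per item), as produced by [match_catalog_to_registry()]. Every item
#'   must carry a known domain acronym.
#' @return An object of class `"unhs_coverage"`: a data frame with one row
#'   per domain plus an `"Overall"` row, columns `domain`, `n_items`, the
#'   four percentages above, and raw per-status counts.
#' @export
coverage_report <- function(statuses) {
  stopifnot(is.data.frame(statuses),
            all(c("domain", "status") %in% names(statuses)))
  domain <- canonical_domain(statuses$domain)  # rejects unknown acronyms
  status <- as.character(statuses$status)
  bad <- !status %in% .coverage_statuses
  if (any(bad)) {
    stop("unknown status value(s): ", paste(unique(status[bad]), collapse = ", "),
         call. = FALSE)
  }

  one_row <- function(dom, idx) {
    counts <- table(factor(status[idx], levels = .coverage_statuses))
    n <- length(idx)
    direct <- counts[["direct"]]
    ext <- counts[["extension_required"]]
    oper <- counts[["operational_only"]]
    header <- counts[["header_mapped"]]
    data.frame(
      domain = dom,
      n_items = n,
      international_coverage_pct = round_half_up(pct(direct, n), 1),
      national_extension_pct = round_half_up(pct(ext + header + oper, n), 1),
      operational_only_pct = round_half_up(pct(oper, n), 1),
      overall_coverage_pct = round_half_up(pct(direct + ext + header, n), 1),
      n_direct = direct, n_extension_required = ext,
      n_operational_only = oper, n_header_mapped = header,
      n_unmatched = counts[["unmatched"]],
      stringsAsFactors = FALSE
    )
  }

  rows <- lapply(sort(unique(domain)), function(d)
    one_row(d, which(domain == d)))
  rows <- c(rows, list(one_row("Overall", seq_along(domain))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("unhs_coverage", "data.frame")
  out
}

#' @export
print.unhs_coverage <- function(x, ...) {
  cat("Coverage of local service codes (percent of items per row)\n")
  print.data.frame(x[, c("domain", "n_items", "international_coverage_pct",
                         "national_extension_pct", "operational_only_pct",
                         "overall_coverage_pct")], row.names = FALSE)
  invisible(x)
}
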