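# Multi-facility billing-catalog assessment: label normalization, item
# alignment across facilities, and the four coding-consistency metrics.
#
# A catalog is a plain data frame with columns facility_id, local_code,
# label and optionally price (non-negative) and domain. Several facilities
# can be stacked in one table; facility_id keeps them apart.

.catalog_columns <- c("facility_id", "local_code", "label")

as_catalog <- function(x) {
  if (inherits(x, "list") && !is.data.frame(x)) x <- do.call(rbind, x)
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.catalog_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("catalog lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"price" %in% names(x)) x$price <- rep(NA_real_, nrow(x))
  x$facility_id <- as.character(x$facility_id)
  x$local_code <- as.character(x$local_code)
  x$label <- as.character(x$label)
  if (any(!nzchar(x$facility_id))) {
    stop("facility_id must be non-empty", call. = FALSE)
  }
  if (any(!is.na(x$price) & x$price < 0)) {
    stop("price must be non-negative", call. = FALSE)
  }
  x
}

#' Normalize a billing label for alignment
#'
#' Uppercases, strips accents (ASCII transliteration), replaces punctuation
#' with spaces, and collapses whitespace. Deterministic and idempotent —
#' the default key under which items from different facilities are treated
#' as the same service.
#'
#' @param text Character vector of labels.
#' @return Character vector of canonical labels.
#' @examples
#' normalize_label("Aciclovir—200 mg tablet")
#' # "ACICLOVIR 200 MG TABLET"
#' @export
normalize_label <- function(text) {
  out <- toupper(as.character(text))
  ascii <- iconv(out, from = "UTF-8", to = "ASCII//TRANSLIT")
  out <- ifelse(is.na(ascii), out, ascii)
  # transliteration renders accents as combining marks ("E, ^O): drop them
  out <- gsub("['`^\"~]", "", out)
  out <- gsub("[^A-Z0-9]+", " ", out)
  trimws(gsub(" +", " ", out))
}

#' Align catalog items into cross-facility clusters
#'
#' Groups items by an explicit concept key where one is supplied and by
#' normalized label otherwise; the explicit key always wins. Every item
#' lands in exactly one cluster.
#'
#' @param catalogs A catalog data frame (facilities stacked, see package
#'   docs) or a list of per-facility catalogs.
#' @param concept_key Optional character vector, one entry per item row;
#'   `NA` entries fall back to the normalized label. A key of the wrong
#'   length (referencing unknown items) is rejected.
#' @return The catalog with two added columns: `cluster_key` (the grouping
#'   key) and `cluster_id` (integer, dense from 1 in order of first
#'   appearance).
#' @export
cluster_items <- function(catalogs, concept_key = NULL) {
  items <- as_catalog(catalogs)
  key <- normalize_label(items$label)
  if (!is.null(concept_key)) {
    concept_key <- as.character(concept_key)
    if (length(concept_key) != nrow(items)) {
      stop("concept_key has ", length(concept_key), " entries for ",
           nrow(items), " items; keys must reference existing items",
           call. = FALSE)
    }
    use <- !is.na(concept_key) & nzchar(concept_key)
    key[use] <- concept_key[use]
  }
  items$cluster_key <- key
  items$cluster_id <- match(key, unique(key))
  items
}

#' Coding-consistency metrics across facilities
#'
#' Computes the four harmonization statistics over clustered catalog items:
#' \describe{
#'   \item{consistent}{share of clusters present in every facility whose raw
#'     labels agree verbatim across all their items.}
#'   \item{duplicate-within}{share of items whose local code is carried by
#'     at least one other item of the same facility.}
#'   \item{multiple-across}{share of clusters, among those present in two or
#'     more facilities, realized with at least two distinct (code, label)
#'     pairs in different facilities.}
#'   \item{code reuse}{share of items whose local code is also attached, in
#'     the same facility, to an item of a different cluster — the same code
#'     naming different services. Reuse items are necessarily also
#'     duplicate-within items.}
#' }
#' Each percentage is reported with its denominator; definitions are the
#' toolkit's own (denominators for such audits are rarely stated in the
#' wild) and are documented here and in the output.
#'
#' @param items A clustered catalog as returned by [cluster_items()]. For
#'   convenience an unclustered catalog is clustered with the default key.
#' @return An object of class `"unhs_consistency"`: a list with
#'   `pct_consistent_across_facilities`, `pct_duplicate_within_facility`,
#'   `pct_multiple_codes_across_facilities`,
#'   `pct_code_reuse_for_different_services`, and `denominators`.
#' @export
consistency_metrics <- function(items) {
  if (!"cluster_id" %in% names(items)) items <- cluster_items(items)
  facilities <- unique(items$facility_id)
  n_fac <- length(facilities)

  by_cluster <- split(seq_len(nrow(items)), items$cluster_id)

  span <- vapply(by_cluster, function(i)
    length(unique(items$facility_id[i])), integer(1))
  everywhere <- names(by_cluster)[span == n_fac]
  consistent <- vapply(by_cluster[everywhere], function(i)
    length(unique(items$label[i])) == 1L, logical(1))

  shared <- names(by_cluster)[span >= 2L]
  # For a cluster spanning >=2 facilities, any two distinct (code, label)
  # realizations guarantee a differing pair in different facilities.
  multi <- vapply(by_cluster[shared], function(i) {
    real <- paste(items$local_code[i], items$label[i], sep = "\r")
    length(unique(real)) >= 2L
  }, logical(1))

  fac_code <- paste(items$facility_id, items$local_code, sep = "\r")
  code_count <- table(fac_code)
  dup_item <- code_count[fac_code] >= 2L
  reuse_item <- vapply(seq_len(nrow(items)), function(i) {
    same <- fac_code == fac_code[i]
    any(items$cluster_id[same] != items$cluster_id[i])
  }, logical(1))

  structure(list(
    pct_consistent_across_facilities = pct(sum(consistent), length(everywhere)),
    pct_duplicate_within_facility = pct(sum(dup_item), nrow(items)),
    pct_multiple_codes_across_facilities = pct(sum(multi), length(shared)),
    pct_code_reuse_for_different_services = pct(sum(reuse_item), nrow(items)),
    denominators = list(
      clusters_in_all_facilities = length(everywhere),
      items = nrow(items),
      clusters_in_two_or_more_facilities = length(shared),
      facilities = n_fac,
      clusters = length(by_cluster)
    )
  ), class = "unhs_consistency")
}

#' @export
print.unhs_consistency <- function(x, ...) {
  d <- x$denominators
  fmt <- function(p) ifelse(is.na(p), "  n/a", sprintf("%5.1f%%", round_half_up(p, 1)))
  cat("Coding-consistency assessment (", d$items, " items, ",
      d$clusters, " services, ", d$facilities, " facilities)\n", sep = "")
  cat("  Consistent nomenclature across facilities : ",
      fmt(x$pct_consistent_across_facilities),
      "  (of ", d$clusters_in_all_facilities, " clusters in all facilities)\n",
      sep = "")
  cat("  Duplicate codes in the same facility      : ",
      fmt(x$pct_duplicate_within_facility),
      "  (of ", d$items, " items)\n", sep = "")
  cat("  Multiple codes across different facilities: ",
      fmt(x$pct_multiple_codes_across_facilities),
      "  (of ", d$clusters_in_two_or_more_facilities,
      " clusters in >=2 facilities)\n", sep = "")
  cat("  Same code for different services          : ",
      fmt(x$pct_code_reuse_for_different_services),
      "  (of ", d$items, " items)\n", sep = "")
  invisible(x)
}

#' Consistency report as a data frame
#'
#' @param x An `unhs_consistency` object.
#' @return A data frame with metric, percentage (half-up, one decimal) and
#'   denominator columns, suitable for CSV output.
#' @export
consistency_as_table <- function(x) {
  stopifnot(inherits(x, "unhs_consistency"))
  d <- x$denominators
  data.frame(
    metric = c("consistent_across_facilities", "duplicate_within_facility",
               "multiple_codes_across_facilities",
               "code_reuse_for_different_services"),
    percent = round_half_up(c(x$pct_consistent_across_facilities,
                              x$pct_duplicate_within_facility,
                              x$pct_multiple_codes_across_facilities,
                              x$pct_code_reuse_for_different_services), 1),
    denominator = c(d$clusters_in_all_facilities, d$items,
                    d$clusters_in_two_or_more_facilities, d$items),
    stringsAsFactors = FALSE
  )
}

#' Read facility catalogs from delimited text
#'
#' @param paths One or more CSV/TSV files with header facility_id,
#'   local_code, label and optionally price, domain.
#' @param dialect `"csv"` (default for catalogs) or `"tsv"`.
#' @return One stacked catalog data frame.
#' @export
read_catalogs <- function(paths, dialect = "csv") {
  sep <- .dialect_sep(dialect)
  parts <- lapply(paths, function(p) {
    df <- utils::read.table(p, sep = sep, header = TRUE, quote = "\"",
                            na.strings = "", fileEncoding = "UTF-8",
                            stringsAsFactors = FALSE, comment.char = "")
    df
  })
  all_cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(df) {
    for (col in setdiff(all_cols, names(df))) df[[col]] <- NA
    df[, all_cols, drop = FALSE]
  })
  as_catalog(do.call(rbind, parts))
}

#' Write a catalog to delimited text
#'
#' @param catalog A catalog data frame.
#' @param path Output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, dialect = "csv") {
  catalog <- as_catalog(catalog)
  utils::write.table(catalog, path, sep = .dialect_sep(dialect),
                     quote = TRUE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}
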