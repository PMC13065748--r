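# Seeded synthetic fixtures: mock source classifications, registries and
# multi-facility billing catalogs with controlled disharmony. Everything is
# generated from a FixtureConfig so the assessment machinery can be tested
# closed-loop without licensed terminologies: the generator plants exact
# counts and emits the ground truth needed to recover them.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.coverage_split_names <- c("direct", "extension_required", "operational_only",
                           "header_mapped", "unmatched")

#' Build a fixture configuration
#'
#' Controls every knob of the synthetic generators. Rates are fractions in
#' \[0, 1\]; the same seed always yields byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_concepts_per_domain Concepts to mock per domain (single count or
#'   a named vector over domain acronyms).
#' @param n_facilities Number of facilities whose catalogs are emulated.
#' @param n_services Number of distinct billable services (cross-facility
#'   item clusters) in the catalogs.
#' @param rate_consistent Fraction of services whose raw labels agree
#'   verbatim in every facility.
#' @param rate_duplicate_within Fraction of items sharing a local code with
#'   another item of the same facility. Must be at least
#'   `rate_code_reuse` (a reused code makes its carriers duplicates).
#' @param rate_multi_coded Fraction of services realized with at least two
#'   distinct (code, label) pairs across facilities. Must be at least
#'   `1 - rate_consistent`: a service whose labels diverge is necessarily
#'   multi-coded.
#' @param rate_code_reuse Fraction of items whose local code also names a
#'   different service in the same facility.
#' @param coverage_split Named fractions over direct, extension_required,
#'   operational_only, header_mapped, unmatched; must sum to 1. Planted as
#'   each item's intended coverage status.
#' @return A list of class `"unhs_fixture_config"`.
#' @export
fixture_config <- function(seed = 1L,
                           n_concepts_per_domain = 10L,
                           n_facilities = 5L,
                           n_services = 100L,
                           rate_consistent = 0.33,
                           rate_duplicate_within = 0.11,
                           rate_multi_coded = 1.0,
                           rate_code_reuse = 0.09,
                           coverage_split = c(direct = 0.91,
                                              extension_required = 0.067,
                                              operational_only = 0.023,
                                              header_mapped = 0,
                                              unmatched = 0)) {
  if (length(n_concepts_per_domain) == 1L && is.null(names(n_concepts_per_domain))) {
    n_concepts_per_domain <- stats::setNames(
      rep(as.integer(n_concepts_per_domain), length(unhs_domains)), unhs_domains)
  }
  stopifnot(all(names(n_concepts_per_domain) %in% unhs_domains),
            all(n_concepts_per_domain >= 0),
            n_facilities >= 1, n_services >= 1)
  rates <- c(rate_consistent, rate_duplicate_within, rate_multi_coded,
             rate_code_reuse)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(coverage_split))) {
    if (length(coverage_split) != 5L) {
      stop("an unnamed coverage_split must have exactly 5 entries, in the ",
           "order ", paste(.coverage_split_names, collapse = ", "),
           call. = FALSE)
    }
    names(coverage_split) <- .coverage_split_names
  }
  split <- coverage_split[.coverage_split_names]
  split[is.na(split)] <- 0
  names(split) <- .coverage_split_names
  if (any(split < 0) || abs(sum(split) - 1) > 1e-8) {
    stop("coverage_split must be non-negative fractions over ",
         paste(.coverage_split_names, collapse = ", "),
         " summing to 1 (got sum ", sum(split), ")", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_concepts_per_domain = n_concepts_per_domain,
    n_facilities = as.integer(n_facilities),
    n_services = as.integer(n_services),
    rate_consistent = rate_consistent,
    rate_duplicate_within = rate_duplicate_within,
    rate_multi_coded = rate_multi_coded,
    rate_code_reuse = rate_code_reuse,
    coverage_split = split
  ), class = "unhs_fixture_config")
}

# Mock source codes imitating each classification's surface shape, without
# any real codes; uniqueness is guaranteed by an index suffix.
.mock_source_code <- function(classification, i) {
  switch(classification,
    "ICD-10-PCS" = paste0(paste(sample(LETTERS, 3, replace = TRUE),
                                collapse = ""), sprintf("%04d", i)),
    "CPT" = sprintf("%05d", 10000 + i),
    "HCPCS" = paste0(sample(LETTERS, 1), sprintf("%04d", i)),
    "LOINC" = paste0(10000 + i, "-", i %% 10),
    "RxNorm" = sprintf("%06d", 100000 + i),
    "UB04" = sprintf("%04d", 100 + i),
    sprintf("X%05d", i)
  )
}

.mock_labels <- function(domain, j) {
  c(fr = paste("Service", tolower(domain), "simule", j),
    en = paste("Mock", domain, "service", j),
    es = paste("Servicio", tolower(domain), "simulado", j),
    pt = paste("Servico", tolower(domain), "simulado", j))
}

#' Generate a mock concept registry
#'
#' Builds, per domain, the configured number of concepts under the matching
#' source classification (default prefixes I/C/H/L/R/U), adds a couple of
#' extension families in the imaging domain and a handful of operational
#' codes, and returns a registry that passes the full audit. Deterministic
#' given the config seed.
#'
#' @param config An [fixture_config()] object.
#' @param classifications Classification table; default
#'   [default_classifications()].
#' @return An `unhs_registry`.
#' @export
generate_mock_registry <- function(config,
                                   classifications = default_classifications()) {
  stopifnot(inherits(config, "unhs_fixture_config"))
  with_seed(config$seed, {
    npd <- config$n_concepts_per_domain
    rows <- list()
    n <- 0
    counters <- stats::setNames(rep(0L, nrow(classifications)),
                                classifications$name)
    for (ci in seq_len(nrow(classifications))) {
      cname <- classifications$name[ci]
      prefix <- classifications$prefix[ci]
      for (dom in classifications$domains[[ci]]) {
        k <- npd[dom]
        if (is.na(k) || k == 0L) next
        for (j in seq_len(k)) {
          counters[cname] <- counters[cname] + 1L
          n <- n + 1
          labs <- .mock_labels(dom, counters[cname])
          rows[[length(rows) + 1L]] <- data.frame(
            identifier = n, code = NA_character_,
            source_ref = paste0(prefix, "-",
                                .mock_source_code(cname, counters[cname])),
            domain = dom,
            label_fr = labs[["fr"]], label_en = labs[["en"]],
            label_es = labs[["es"]], label_pt = labs[["pt"]],
            operational = FALSE, stringsAsFactors = FALSE
          )
        }
      }
    }
    cc <- do.call(rbind, rows)
    cc$code <- make_code(cc$identifier)

    # a few operational codes (no international equivalent)
    op_domains <- intersect(c("PROC", "LAB"), names(npd)[npd > 0])
    for (dom in op_domains) {
      n <- n + 1
      labs <- .mock_labels(dom, paste0("operational ", n))
      cc <- rbind(cc, data.frame(
        identifier = n, code = make_code(n), source_ref = NA_character_,
        domain = dom,
        label_fr = labs[["fr"]], label_en = labs[["en"]],
        label_es = labs[["es"]], label_pt = labs[["pt"]],
        operational = TRUE, stringsAsFactors = FALSE
      ))
    }

    # extension families under the first two imaging concepts (or, lacking
    # imaging, the first domain present)
    fam_idx <- which(cc$domain == "IMG" & !cc$operational)
    if (length(fam_idx) == 0L) fam_idx <- which(!cc$operational)
    fam_idx <- utils::head(fam_idx, 2L)
    for (j in fam_idx) {
      for (k in seq_len(2L + (j %% 3L))) {
        n <- n + 1
        cc <- rbind(cc, data.frame(
          identifier = n, code = paste0(cc$code[j], ".", k),
          source_ref = cc$source_ref[j], domain = cc$domain[j],
          label_fr = paste(cc$label_fr[j], "variante", k),
          label_en = paste(cc$label_en[j], "variant", k),
          label_es = paste(cc$label_es[j], "variante", k),
          label_pt = paste(cc$label_pt[j], "variante", k),
          operational = FALSE, stringsAsFactors = FALSE
        ))
      }
    }

    rownames(cc) <- NULL
    registry <- unhs_registry(classifications)
    registry$concepts <- cc
    registry$next_identifier <- n + 1
    problems <- registry_audit(registry)
    if (length(problems) > 0L) {
      stop("internal error: generated registry fails audit:\n  ",
           paste(problems, collapse = "\n  "), call. = FALSE)
    }
    registry
  })
}

# Deterministic, seeded label corruptions: realistic disagreement between
# facilities, reproducible under the config seed.
.corrupt_label <- function(label, style) {
  words <- strsplit(label, " ", fixed = TRUE)[[1]]
  switch(style,
    lowercase = tolower(label),
    punct = paste0(gsub(" ", " - ", label, fixed = TRUE), "."),
    synonym = {
      swaps <- c("service" = "svc", "mock" = "test", "tablet" = "tab",
                 "radiography" = "xray", "examination" = "exam")
      out <- words
      for (w in names(swaps)) out[out == w] <- swaps[[w]]
      paste(out, collapse = " ")
    },
    shuffle = paste(rev(words), collapse = " "),
    abbrev = paste(substr(words, 1L, 4L), collapse = " "),
    label
  )
}

.largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  counts <- floor(raw)
  short <- total - sum(counts)
  if (short > 0) {
    order_idx <- order(raw - counts, decreasing = TRUE)
    counts[order_idx[seq_len(short)]] <- counts[order_idx[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Generate multi-facility billing catalogs with planted disharmony
#'
#' Emulates the rate lists of several facilities describing the same set of
#' services. Each service appears once per facility; the configured rates
#' are realized by exact counts (to the nearest item):
#' label-consistent services keep one verbatim label everywhere, label-
#' divergent services get a deterministic corruption (case/punctuation
#' change, synonym swap, word-order shuffle or abbreviation) in at least one
#' facility; multi-coded services carry facility-specific codes; code reuse
#' is planted by giving two different services the same code in one
#' facility; duplicate listings are planted as verbatim repeated items.
#' Every item also gets an intended coverage status drawn from
#' `coverage_split`, with mapping hints pointing at registry concepts.
#'
#' @param config An [fixture_config()] object.
#' @param registry A registry supplying concepts to map services onto
#'   (e.g. from [generate_mock_registry()]).
#' @return A list with elements `catalog` (stacked item table), `key`
#'   (ground truth per item: concept key, planted coverage status, target
#'   code), `mapping` (expert hints for [match_catalog_to_registry()]),
#'   `planted` (the achieved rates, percent), and `config`.
#' @export
generate_catalogs <- function(config, registry) {
  stopifnot(inherits(config, "unhs_fixture_config"),
            inherits(registry, "unhs_registry"))
  K <- config$n_services
  nf <- config$n_facilities

  if (config$rate_multi_coded < 1 - config$rate_consistent - 1e-9 - 1 / K) {
    stop("infeasible rates: a service whose labels diverge across ",
         "facilities is necessarily multi-coded, so rate_multi_coded must ",
         "be at least 1 - rate_consistent (",
         format(1 - config$rate_consistent), ")", call. = FALSE)
  }
  if (config$rate_duplicate_within < config$rate_code_reuse - 1e-9) {
    stop("infeasible rates: items carrying a reused code are duplicates by ",
         "definition, so rate_duplicate_within must be at least ",
         "rate_code_reuse", call. = FALSE)
  }

  base_pool <- registry$concepts[!grepl(".", registry$concepts$code, fixed = TRUE) &
                                 !registry$concepts$operational, , drop = FALSE]
  if (nrow(base_pool) == 0L) {
    stop("registry has no non-extension, non-operational concepts to draw on",
         call. = FALSE)
  }

  with_seed(config$seed + 1L, {
    concept_idx <- sample(nrow(base_pool), K, replace = K > nrow(base_pool))
    facilities <- sprintf("FAC%02d", seq_len(nf))

    # approximate final size to convert item rates into plantable counts
    approx_extra <- round((config$rate_duplicate_within -
                           config$rate_code_reuse) / 2 /
                          max(1e-12, 1 - (config$rate_duplicate_within -
                                          config$rate_code_reuse) / 2) * K * nf)
    n_base <- K * nf
    n_total_est <- n_base + approx_extra
    n_reuse_pairs <- round(config$rate_code_reuse * n_total_est / 2)
    n_copies <- approx_extra

    n_cons <- round(config$rate_consistent * K)
    n_multi <- round(config$rate_multi_coded * K)
    n_multi <- max(n_multi, K - n_cons)  # forced by label divergence
    consistent <- seq_len(K) <= n_cons
    multi <- rep(FALSE, K)
    if (n_multi > 0) {
      # all inconsistent clusters are multi; top up from the consistent ones
      multi[which(!consistent)] <- TRUE
      need <- n_multi - sum(multi)
      if (need > 0) multi[utils::head(which(consistent), need)] <- TRUE
    }
    if (n_reuse_pairs * 2 > sum(multi)) {
      stop("infeasible rates: planting ", n_reuse_pairs, " reused codes ",
           "needs ", 2 * n_reuse_pairs, " multi-coded services but only ",
           sum(multi), " are available at rate_multi_coded = ",
           config$rate_multi_coded, call. = FALSE)
    }

    base_label <- paste(base_pool$label_en[concept_idx], "item", seq_len(K))
    styles <- c("lowercase", "punct", "synonym", "shuffle", "abbrev")

    # one item per service per facility
    items <- expand.grid(service = seq_len(K), facility = seq_len(nf),
                         KEEP.OUT.ATTRS = FALSE)
    items <- items[order(items$facility, items$service), , drop = FALSE]
    n_items <- nrow(items)

    label <- base_label[items$service]
    corrupt_style <- sample(styles, K, replace = TRUE)
    corrupt_fac <- sample.int(nf, K, replace = TRUE)
    divergent <- !consistent[items$service] &
      items$facility == corrupt_fac[items$service]
    if (nf == 1L) divergent <- rep(FALSE, n_items)
    label[divergent] <- vapply(which(divergent), function(i) {
      .corrupt_label(label[i], corrupt_style[items$service[i]])
    }, character(1))

    # local codes: shared across facilities unless the service is planted
    # multi-coded, in which case each facility uses its own code
    shared_code <- sprintf("S%05d", sample(99999, K))
    code <- shared_code[items$service]
    is_multi_item <- multi[items$service]
    code[is_multi_item] <- sprintf("F%d-%05d", items$facility[is_multi_item],
                                   seq_len(sum(is_multi_item)))

    catalog <- data.frame(
      facility_id = facilities[items$facility],
      local_code = code,
      label = label,
      price = round(stats::runif(n_items, 1, 500), 2),
      domain = base_pool$domain[concept_idx[items$service]],
      stringsAsFactors = FALSE
    )
    service_of <- items$service

    # plant code reuse: two multi-coded services share one code in facility 1
    reuse_services <- utils::head(which(multi), 2 * n_reuse_pairs)
    if (n_reuse_pairs > 0) {
      for (p in seq_len(n_reuse_pairs)) {
        a <- reuse_services[2 * p - 1]
        b <- reuse_services[2 * p]
        ia <- which(service_of == a & catalog$facility_id == facilities[1])
        ib <- which(service_of == b & catalog$facility_id == facilities[1])
        catalog$local_code[ib] <- catalog$local_code[ia]
      }
    }

    # plant duplicate listings: verbatim copies of untouched items
    if (n_copies > 0) {
      touched <- service_of %in% reuse_services &
        catalog$facility_id == facilities[1]
      candidates <- which(!touched)
      if (n_copies > length(candidates)) {
        stop("infeasible rates: not enough items to plant ", n_copies,
             " duplicate listings", call. = FALSE)
      }
      picks <- sample(candidates, n_copies)
      catalog <- rbind(catalog, catalog[picks, , drop = FALSE])
      service_of <- c(service_of, service_of[picks])
    }
    # keep items grouped by facility so that per-facility files concatenate
    # back to this exact row order (item indices in the ground truth and
    # the mapping stay meaningful after a write/read cycle)
    ord <- order(catalog$facility_id)
    catalog <- catalog[ord, , drop = FALSE]
    service_of <- service_of[ord]
    rownames(catalog) <- NULL
    n_final <- nrow(catalog)

    # planted coverage statuses, by exact counts over the final item set
    counts <- .largest_remainder(config$coverage_split, n_final)
    status <- rep(names(config$coverage_split), counts)
    status <- sample(status, n_final)  # seeded shuffle across items
    target_code <- base_pool$code[concept_idx[service_of]]
    target_code[status %in% c("operational_only", "unmatched")] <- NA_character_

    key <- data.frame(
      item = seq_len(n_final),
      facility_id = catalog$facility_id,
      local_code = catalog$local_code,
      concept_key = paste0("SVC", service_of),
      status = status,
      target_code = target_code,
      stringsAsFactors = FALSE
    )

    hinted <- which(status != "unmatched")
    mapping <- data.frame(
      item = hinted,
      relation = c(direct = "direct", extension_required = "extension",
                   operational_only = "operational",
                   header_mapped = "header")[status[hinted]],
      code = target_code[hinted],
      stringsAsFactors = FALSE
    )
    rownames(mapping) <- NULL

    planted <- list(
      pct_consistent = if (nf == 1L) 100 else 100 * n_cons / K,
      pct_duplicate_within = 100 * (2 * n_reuse_pairs + 2 * n_copies) / n_final,
      pct_multi_coded = 100 * sum(multi) / K,
      pct_code_reuse = 100 * 2 * n_reuse_pairs / n_final,
      coverage_counts = stats::setNames(counts, names(config$coverage_split)),
      n_items = n_final, n_services = K, n_facilities = F
    )

    list(catalog = catalog, key = key, mapping = mapping,
         planted = planted, config = config)
  })
}

#' Write a generated fixture set to disk
#'
#' Emits the registry (TSV), one catalog CSV per facility, and the
#' ground-truth key CSV, as a CLI-friendly bundle.
#'
#' @param registry The mock registry.
#' @param fixture Output of [generate_catalogs()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(registry, fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "registry.tsv")
  write_registry(registry, p)
  paths <- c(paths, p)
  for (fac in unique(fixture$catalog$facility_id)) {
    p <- file.path(dir, paste0("catalog_", fac, ".csv"))
    write_catalog(fixture$catalog[fixture$catalog$facility_id == fac, ,
                                  drop = FALSE], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ground_truth.csv")
  utils::write.table(fixture$key, p, sep = ",", quote = TRUE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  paths <- c(paths, p)
  p <- file.path(dir, "mapping.csv")
  utils::write.table(fixture$mapping, p, sep = ",", quote = TRUE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  paths <- c(paths, p)
  invisible(paths)
}
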