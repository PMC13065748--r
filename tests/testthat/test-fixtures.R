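# Seeded fixture generators: determinism, audit, planted-rate recovery.

test_that("config validation enforces fractions and feasibility", {
  expect_error(fixture_config(rate_consistent = 1.2), "rates")
  expect_error(fixture_config(coverage_split = c(direct = 0.5,
                                                 unmatched = 0.1)),
               "summing to 1")
  reg <- generate_mock_registry(fixture_config())
  # divergent labels force multi-coding, so a low multi rate cannot be
  # combined with a low consistency rate
  expect_error(generate_catalogs(
    fixture_config(n_services = 100, rate_consistent = 0.5,
                   rate_multi_coded = 0.1), reg),
    "necessarily multi-coded")
  expect_error(generate_catalogs(
    fixture_config(rate_duplicate_within = 0.02, rate_code_reuse = 0.08),
    reg),
    "duplicates by definition")
})

test_that("the mock registry is audit-clean and fully decodable", {
  cfg <- fixture_config(seed = 1, n_concepts_per_domain = 10)
  reg <- generate_mock_registry(cfg)
  expect_gte(nrow(reg$concepts), 120L)
  expect_length(registry_audit(reg), 0)
  expect_true(all(validate_codes(reg$concepts$code)$valid))
  # non-extension codes decode back to their own identifiers
  plain <- !grepl(".", reg$concepts$code, fixed = TRUE)
  decoded <- vapply(reg$concepts$code[plain],
                    function(cd) validate_code(cd)$identifier, numeric(1),
                    USE.NAMES = FALSE)
  expect_identical(decoded, reg$concepts$identifier[plain])
  # it contains extension families and operational codes
  expect_gt(sum(!plain), 0)
  expect_gt(sum(reg$concepts$operational), 0)
})

test_that("the same seed reproduces byte-identical fixture files", {
  cfg <- fixture_config(seed = 21, n_services = 30, n_facilities = 3)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  for (d in c(d1, d2)) {
    reg <- generate_mock_registry(cfg)
    fx <- generate_catalogs(cfg, reg)
    write_fixtures(reg, fx, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed does not
  cfg2 <- fixture_config(seed = 22, n_services = 30, n_facilities = 3)
  fx2 <- generate_catalogs(cfg2, generate_mock_registry(cfg2))
  fx1 <- generate_catalogs(cfg, generate_mock_registry(cfg))
  expect_false(identical(fx1$catalog, fx2$catalog))
})

test_that("fully harmonized catalogs close the loop at 100/0/0/0", {
  cfg <- fixture_config(seed = 2, n_services = 50, n_facilities = 4,
                        rate_consistent = 1, rate_multi_coded = 0,
                        rate_duplicate_within = 0, rate_code_reuse = 0)
  reg <- generate_mock_registry(cfg)
  fx <- generate_catalogs(cfg, reg)
  m <- consistency_metrics(cluster_items(fx$catalog, fx$key$concept_key))
  expect_equal(m$pct_consistent_across_facilities, 100)
  expect_equal(m$pct_duplicate_within_facility, 0)
  expect_equal(m$pct_multiple_codes_across_facilities, 0)
  expect_equal(m$pct_code_reuse_for_different_services, 0)
})

test_that("planted disharmony rates are recovered through the metrics", {
  cfg <- fixture_config(seed = 9, n_services = 200, n_facilities = 5,
                        rate_consistent = 0.33, rate_duplicate_within = 0.11,
                        rate_multi_coded = 1, rate_code_reuse = 0.09)
  reg <- generate_mock_registry(cfg)
  fx <- generate_catalogs(cfg, reg)
  m <- consistency_metrics(cluster_items(fx$catalog, fx$key$concept_key))
  # the metrics reproduce the generator's achieved counts exactly
  expect_equal(m$pct_consistent_across_facilities, fx$planted$pct_consistent)
  expect_equal(m$pct_duplicate_within_facility,
               fx$planted$pct_duplicate_within)
  expect_equal(m$pct_multiple_codes_across_facilities,
               fx$planted$pct_multi_coded)
  expect_equal(m$pct_code_reuse_for_different_services,
               fx$planted$pct_code_reuse)
  # and the achieved counts sit within one planting unit of the request
  one_cluster <- 100 / fx$planted$n_services
  one_pair <- 2 * 100 / fx$planted$n_items
  expect_lt(abs(m$pct_consistent_across_facilities - 33), one_cluster)
  expect_lt(abs(m$pct_duplicate_within_facility - 11), one_pair)
  expect_equal(m$pct_multiple_codes_across_facilities, 100)
  expect_lt(abs(m$pct_code_reuse_for_different_services - 9), one_pair)
})

test_that("planted coverage statuses are recovered item for item", {
  cfg <- fixture_config(seed = 4, n_services = 60, n_facilities = 3,
                        rate_duplicate_within = 0, rate_code_reuse = 0,
                        coverage_split = c(direct = 0.8,
                                           extension_required = 0.1,
                                           operational_only = 0.05,
                                           header_mapped = 0.025,
                                           unmatched = 0.025))
  reg <- generate_mock_registry(cfg)
  fx <- generate_catalogs(cfg, reg)
  st <- match_catalog_to_registry(fx$catalog, reg, fx$mapping)
  expect_identical(as.character(st$status), fx$key$status)
  counts <- table(factor(fx$key$status, names(fx$planted$coverage_counts)))
  expect_equal(as.integer(counts), as.integer(fx$planted$coverage_counts))
})

test_that("generated fixtures round-trip losslessly through their files", {
  cfg <- fixture_config(seed = 13, n_services = 25, n_facilities = 2)
  reg <- generate_mock_registry(cfg)
  fx <- generate_catalogs(cfg, reg)
  dir <- file.path(tempdir(), "fx_rt")
  write_fixtures(reg, fx, dir)
  back_reg <- read_registry(file.path(dir, "registry.tsv"))
  expect_identical(back_reg$concepts, reg$concepts)
  cat_files <- list.files(dir, pattern = "^catalog_", full.names = TRUE)
  back_cat <- read_catalogs(cat_files)
  expect_identical(nrow(back_cat), nrow(fx$catalog))
  expect_setequal(back_cat$label, fx$catalog$label)
})
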