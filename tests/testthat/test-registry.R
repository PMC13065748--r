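# Registry semantics: allocation, extensions, operational codes, audit, IO.

test_that("registration allocates sequential identifiers and prefixed refs", {
  reg <- unhs_registry()
  reg <- register_concept(reg, "A0428", "HCPCS", "TRANS",
                          c(en = "Ambulance service, basic life support, non-emergency transport"))
  expect_identical(attr(reg, "last_code"), "AY")  # identifier 1
  row <- reg$concepts[1, ]
  expect_identical(row$identifier, 1)
  expect_identical(row$source_ref, "H-A0428")
  expect_identical(row$domain, "TRANS")
  reg <- register_concept(reg, "99213", "CPT", "EVAL", c(en = "Office visit"))
  expect_identical(reg$concepts$identifier, c(1, 2))
  expect_identical(reg$next_identifier, 3)
})

test_that("TRAN is accepted as an alias of the canonical TRANS acronym", {
  reg <- unhs_registry()
  reg <- register_concept(reg, "A0428", "HCPCS", "TRAN", c(en = "Ambulance"))
  expect_identical(reg$concepts$domain, "TRANS")
})

test_that("re-registration and domain/classification mismatches are rejected", {
  reg <- unhs_registry()
  reg <- register_concept(reg, "A0428", "HCPCS", "TRANS", c(en = "Ambulance"))
  expect_error(register_concept(reg, "A0428", "HCPCS", "TRANS",
                                c(en = "Ambulance again")),
               "already registered")
  expect_error(register_concept(reg, "15074-8", "LOINC", "MED",
                                c(en = "Glucose")),
               "not served by")
  expect_error(register_concept(reg, "X", "NotASystem", "MED", c(en = "x")),
               "unknown classification")
  expect_error(register_concept(reg, "Y1", "CPT", "EVAL", list()),
               "label")
})

test_that("extensions are dense dot-suffixes under a single-level parent", {
  reg <- unhs_registry()
  reg <- register_concept(reg, "BW0CZZZ", "ICD-10-PCS", "IMG",
                          c(en = "Plain radiography of lower extremity"))
  parent <- attr(reg, "last_code")
  views <- c("front view", "front and profile views", "profile view",
             "other view")
  for (v in views) {
    reg <- add_extension(reg, parent,
                         c(en = paste0("Plain radiography of lower extremity - ", v)))
  }
  ext <- grep(".", reg$concepts$code, fixed = TRUE, value = TRUE)
  expect_identical(ext, paste0(parent, ".", 1:4))
  # extensions inherit domain and source_ref, get their own identifiers
  ext_rows <- reg$concepts[grepl(".", reg$concepts$code, fixed = TRUE), ]
  expect_true(all(ext_rows$domain == "IMG"))
  expect_true(all(ext_rows$source_ref == "I-BW0CZZZ"))
  expect_identical(ext_rows$identifier, c(2, 3, 4, 5))
  expect_error(add_extension(reg, paste0(parent, ".1"), c(en = "nested")),
               "extensions of extensions")
  expect_error(add_extension(reg, "ZZZZA", c(en = "orphan")),
               "unknown parent")
  expect_length(registry_audit(reg), 0)
})

test_that("operational codes carry no source reference and valid checksums", {
  reg <- unhs_registry()
  reg <- add_operational(reg, "PROC", c(en = "Services related to the neck"))
  reg <- add_operational(reg, "LAB", c(en = "Mock panel"))
  expect_true(all(is.na(reg$concepts$source_ref)))
  expect_true(all(reg$concepts$operational))
  expect_true(all(validate_codes(reg$concepts$code)$valid))
  expect_identical(reg$concepts$identifier, c(1, 2))  # strictly increasing
  expect_length(registry_audit(reg), 0)
})

test_that("lookup distinguishes found, absent and checksum-invalid codes", {
  reg <- unhs_registry()
  reg <- register_concept(reg, "BW0CZZZ", "ICD-10-PCS", "IMG",
                          c(en = "Plain radiography"))
  parent <- attr(reg, "last_code")
  reg <- add_extension(reg, parent, c(en = "front view"))
  reg <- add_extension(reg, parent, c(en = "front and profile views"))
  hit <- lookup_code(reg, paste0(parent, ".2"))
  expect_identical(hit$status, "found")
  expect_identical(hit$concept$label_en, "front and profile views")
  expect_identical(lookup_code(reg, tolower(parent))$status, "found")
  expect_identical(lookup_code(reg, "RSCF")$status, "not_found")
  expect_identical(lookup_code(reg, "RSCG")$status, "checksum_invalid")
})

test_that("the audit flags each class of invariant violation", {
  reg <- tiny_registry()
  expect_length(registry_audit(reg), 0)

  broken <- reg
  broken$concepts$identifier[2] <- 1
  expect_match(registry_audit(broken), "duplicate identifiers", all = FALSE)

  broken <- reg
  broken$concepts$code[3] <- "RSCG"
  expect_match(registry_audit(broken), "checksum", all = FALSE)

  broken <- reg
  broken$next_identifier <- 3
  expect_match(registry_audit(broken), "next_identifier", all = FALSE)

  broken <- reg
  broken$concepts$operational[1] <- TRUE
  expect_match(registry_audit(broken), "operational", all = FALSE)

  broken <- reg
  broken$concepts$domain[5] <- "LAB"  # RxNorm concept outside its domain set
  expect_match(registry_audit(broken), "domain set", all = FALSE)

  # sparse extension suffixes (".2" without ".1")
  broken <- reg
  r <- broken$concepts[1, ]
  r$identifier <- 99
  r$code <- paste0(broken$concepts$code[1], ".2")
  broken$concepts <- rbind(broken$concepts, r)
  broken$next_identifier <- 100
  expect_match(registry_audit(broken), "dense from 1", all = FALSE)
})

test_that("write/read round-trips registries in both dialects", {
  reg <- tiny_registry()
  reg <- add_extension(reg, reg$concepts$code[1], c(en = "variant one"))
  reg <- add_operational(reg, "PROC", c(en = "local-only service",
                                        fr = "service local"))
  for (dialect in c("tsv", "csv")) {
    path <- tempfile(fileext = paste0(".", dialect))
    write_registry(reg, path, dialect)
    back <- read_registry(path, dialect)
    expect_identical(back$concepts, reg$concepts)
    expect_identical(back$next_identifier, reg$next_identifier)
  }
})

test_that("a row with a broken checksum is rejected with its line number", {
  reg <- tiny_registry()
  path <- tempfile(fileext = ".tsv")
  write_registry(reg, path)
  lines <- readLines(path)
  lines[4] <- sub("\"([A-Z]+)\"", "\"RSCG\"", lines[4])  # row 3 of the data
  writeLines(lines, path)
  expect_error(read_registry(path), "line 4")
})

test_that("an invariant-violating file is rejected with the invariant named", {
  reg <- tiny_registry()
  path <- tempfile(fileext = ".tsv")
  reg$concepts$identifier[2] <- 1  # duplicate identifier
  write_registry(reg, path)
  expect_error(read_registry(path), "duplicate identifiers")
})

test_that("a file reproducing the seven published sample rows loads", {
  # the two rows whose printed check letters are inconsistent with the
  # stated algorithm are corrected to their recomputed codes
  rows <- data.frame(
    identifier = c(73559, 2099, 2354, 54414, 61936, 66841, 68059),
    code = c("AYAXU", "AX8G", "A6IL", "AINXD", "AOSUV", "ASSZE", "ATSSI"),
    source_ref = c("H-A0428", "I-GZHZZZZ", "I-BW28ZZZ", "I-0W9G3ZZ",
                   "H-A4207", "L-15074-8", "R-315280"),
    domain = c("TRAN", "MENT", "IMG", "PROC", "CONS", "LAB", "MED"),
    label_fr = NA, label_en = c(
      "Ambulance service, basic life support, non-emergency transport",
      "Group psychotherapy", "CT scan of head",
      "Drainage of peritoneal cavity, percutaneous approach",
      "Sterile 2 cc syringe with needle",
      "Glucose [Moles/volume] in Blood", "Aciclovir-200 mg tablet"),
    label_es = NA, label_pt = NA, operational = "false",
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rows, path, sep = "\t", quote = TRUE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  reg <- read_registry(path)
  expect_identical(nrow(reg$concepts), 7L)
  expect_identical(reg$concepts$domain[1], "TRANS")  # alias canonicalized
  expect_length(registry_audit(reg), 0)
})

test_that("JSON export mirrors the delimited schema", {
  reg <- tiny_registry()
  path <- tempfile(fileext = ".json")
  export_registry_json(reg, path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(nrow(payload$concepts), nrow(reg$concepts))
  expect_identical(payload$concepts$code, reg$concepts$code)
  expect_equal(payload$next_identifier, reg$next_identifier,
               ignore_attr = TRUE)
  expect_identical(payload$classifications$prefix,
                   default_classifications()$prefix)
})
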