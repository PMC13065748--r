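# Shared test helpers.

# Independent decoding oracle: Horner evaluation over symbol values, kept
# deliberately separate from the package's positional-sum implementation.
oracle_alphabet <- c(LETTERS, as.character(1:9))

oracle_decode <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], oracle_alphabet)
  Reduce(function(acc, d) acc * 35 + d, v, accumulate = FALSE)
}

# All code cores of length <= `len` over the alphabet.
all_cores_upto <- function(len) {
  out <- oracle_alphabet
  prev <- oracle_alphabet
  for (l in seq_len(len - 1)) {
    prev <- as.vector(outer(prev, oracle_alphabet, paste0))
    out <- c(out, prev)
  }
  out
}

# A small registry with one concept per classification, built through the
# public API.
tiny_registry <- function() {
  reg <- unhs_registry()
  reg <- register_concept(reg, "0W9G3ZZ", "ICD-10-PCS", "PROC",
                          c(en = "Drainage of peritoneal cavity"))
  reg <- register_concept(reg, "99213", "CPT", "EVAL",
                          c(en = "Office visit, established patient"))
  reg <- register_concept(reg, "A0428", "HCPCS", "TRANS",
                          c(en = "Ambulance service, basic life support"))
  reg <- register_concept(reg, "15074-8", "LOINC", "LAB",
                          c(en = "Glucose [Moles/volume] in Blood"))
  reg <- register_concept(reg, "315280", "RxNorm", "MED",
                          c(en = "Aciclovir 200 mg tablet"))
  reg <- register_concept(reg, "0120", "UB04", "LOG",
                          c(en = "Room and board, semi-private"))
  reg
}
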