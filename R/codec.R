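# Bijective base-35 codec for UNHS service codes.
#
# The code alphabet is A-Z then 1-9 (35 symbols, no zero). Symbol values run
# 1..35, so encoding is bijective numeration: every positive integer has
# exactly one representation and there is no representation of zero. A final
# check letter, 26 - (n mod 26) mapped onto A..Z, is appended to the encoded
# core. National extensions append ".k" (k >= 1, no leading zeros) to a
# finished code and never participate in the checksum.

#' The 35-symbol UNHS code alphabet
#'
#' Uppercase letters A--Z (values 1--26) followed by digits 1--9 (values
#' 27--35). The character "0" is deliberately absent: the encoding is
#' bijective (no zero digit), which is what makes every positive identifier
#' representable exactly once.
#'
#' @format A character vector of length 35; position i holds the symbol with
#'   value i.
#' @export
unhs_alphabet <- c(LETTERS, as.character(1:9))

.BASE <- 35L

#' Value of a single code symbol
#'
#' @param c A single character (or vector of single characters). Lowercase
#'   letters are accepted and uppercased; "0" and anything outside the
#'   alphabet is an error.
#' @return Integer value(s) in 1..35.
#' @examples
#' symbol_value("R")  # 18
#' symbol_value("9")  # 35
#' @export
symbol_value <- function(c) {
  c <- toupper(as.character(c))
  bad <- nchar(c) != 1L
  if (any(bad)) {
    stop("symbol_value() expects single characters; got ",
         paste(sQuote(c[bad]), collapse = ", "), call. = FALSE)
  }
  v <- match(c, unhs_alphabet)
  if (anyNA(v)) {
    stop("not a UNHS alphabet symbol: ",
         paste(sQuote(unique(c[is.na(v)])), collapse = ", "),
         " (alphabet is A-Z, 1-9; there is no \"0\")", call. = FALSE)
  }
  v
}

#' Symbol for a value in 1..35
#' @param v Integer value(s) in 1..35.
#' @return Character symbol(s).
#' @export
value_symbol <- function(v) {
  v <- as.integer(v)
  if (anyNA(v) || any(v < 1L | v > .BASE)) {
    stop("symbol values must lie in 1..35", call. = FALSE)
  }
  unhs_alphabet[v]
}

.check_identifier <- function(n, what = "identifier") {
  if (length(n) == 0L) return(integer(0))
  n <- suppressWarnings(as.numeric(n))
  if (anyNA(n) || any(n < 1) || any(n != floor(n))) {
    stop(what, " must be a positive integer (>= 1); ",
         "bijective numeration has no representation of 0", call. = FALSE)
  }
  if (any(n > 2^53)) {
    stop(what, " exceeds the exactly-representable integer range",
         call. = FALSE)
  }
  n
}

#' Bijective base-35 digits of an identifier
#'
#' Returns the digit values (each in 1..35) of `n` under bijective base-35
#' numeration, most significant first. `encode_identifier()` is these digits
#' mapped through the alphabet.
#'
#' @param n A single positive integer.
#' @return Integer vector of digit values, most significant first.
#' @examples
#' base35_digits(22718)  # 18 19 3  (R, S, C)
#' @export
base35_digits <- function(n) {
  n <- .check_identifier(n)
  if (length(n) != 1L) stop("base35_digits() takes a single identifier",
                            call. = FALSE)
  digits <- integer(0)
  while (n > 0) {
    d <- ((n - 1) %% .BASE) + 1
    digits <- c(as.integer(d), digits)
    n <- (n - d) / .BASE
  }
  digits
}

#' Encode identifiers as base-35 cores
#'
#' Bijective base-35 encoding: repeatedly take `d = ((n - 1) mod 35) + 1` as
#' the next least-significant digit and continue with `(n - d) / 35` until
#' nothing remains. Vectorised over `n`.
#'
#' @param n Positive integer identifier(s).
#' @return Character vector of code cores over the 35-symbol alphabet.
#' @examples
#' encode_identifier(22718)  # "RSC"
#' encode_identifier(c(1, 36))  # "A" "AA"
#' @export
encode_identifier <- function(n) {
  n <- .check_identifier(n)
  out <- character(length(n))
  active <- n > 0
  while (any(active)) {
    d <- ((n[active] - 1) %% .BASE) + 1
    out[active] <- paste0(unhs_alphabet[d], out[active])
    n[active] <- (n[active] - d) / .BASE
    active[active] <- n[active] > 0
  }
  out
}

#' Decode a base-35 core back to its identifier
#'
#' Exact inverse of [encode_identifier()]: the positional sum of symbol
#' values times powers of 35. Vectorised.
#'
#' @param core Non-empty string(s) over the alphabet (lowercase accepted).
#' @return Numeric identifier(s), each >= 1.
#' @examples
#' decode_core("RSC")  # 22718
#' @export
decode_core <- function(core) {
  core <- toupper(as.character(core))
  if (any(is.na(core) | nchar(core) == 0L)) {
    stop("code core must be a non-empty string", call. = FALSE)
  }
  vapply(strsplit(core, "", fixed = TRUE), function(ch) {
    v <- match(ch, unhs_alphabet)
    if (anyNA(v)) {
      stop("invalid symbol ", sQuote(ch[which(is.na(v))[1]]),
           " at position ", which(is.na(v))[1], call. = FALSE)
    }
    sum(v * .BASE^rev(seq_along(v) - 1))
  }, numeric(1))
}

#' Numeric check value of an identifier
#'
#' The checksum rule subtracts the identifier's residue mod 26 from 26,
#' giving a value in 1..26 that [check_digit()] maps onto A..Z (a multiple
#' of 26 yields 26, i.e. "Z").
#'
#' @param n Positive integer identifier(s).
#' @return Integer check value(s) in 1..26.
#' @examples
#' check_value(22718)  # 6
#' @export
check_value <- function(n) {
  n <- .check_identifier(n)
  as.integer(26 - (n %% 26))
}

#' Check letter of an identifier
#' @inheritParams check_value
#' @return Uppercase letter(s) A--Z.
#' @examples
#' check_digit(22718)  # "F"
#' check_digit(26)     # "Z"
#' @export
check_digit <- function(n) {
  LETTERS[check_value(n)]
}

#' Build the canonical code for an identifier
#'
#' Concatenates the base-35 core and the check letter. The result carries no
#' extension suffix; extensions are registry-level children of a finished
#' code (see [add_extension()]).
#'
#' @inheritParams check_value
#' @return Canonical code string(s), e.g. `make_code(22718)` is `"RSCF"`.
#' @export
make_code <- function(n) {
  paste0(encode_identifier(n), check_digit(n))
}

#' Parse a code string into core, check letter and extension
#'
#' Splits `text` into the base-35 core (all but the last pre-dot character),
#' the check letter (the last pre-dot character, necessarily A--Z) and an
#' optional extension suffix (a dot followed by an integer >= 1 with no
#' leading zeros). Parsing is purely syntactic: the checksum is NOT verified
#' here — use [validate_code()] for that.
#'
#' @param text A single code string; uppercased before parsing.
#' @return A list of class `"unhs_code"` with elements `core`, `check`,
#'   `extension` (integer or `NA`), and `canonical` (the normalised text).
#' @examples
#' parse_code("AROEM.1")
#' @export
parse_code <- function(text) {
  if (length(text) != 1L || is.na(text)) {
    stop("parse_code() takes a single code string", call. = FALSE)
  }
  text <- toupper(trimws(as.character(text)))
  if (nchar(text) == 0L) stop("empty code string", call. = FALSE)

  dot <- regexpr(".", text, fixed = TRUE)
  main <- if (dot > 0) substr(text, 1L, dot - 1L) else text
  suffix <- if (dot > 0) substr(text, dot + 1L, nchar(text)) else NA_character_

  if (nchar(main) < 2L) {
    stop("code ", sQuote(text), " is too short: need a core plus a check ",
         "letter (error at position 1)", call. = FALSE)
  }
  chars <- strsplit(main, "", fixed = TRUE)[[1]]
  ok <- chars %in% unhs_alphabet
  if (!all(ok)) {
    p <- which(!ok)[1]
    stop("illegal character ", sQuote(chars[p]), " at position ", p,
         " in ", sQuote(text), call. = FALSE)
  }
  core <- substr(main, 1L, nchar(main) - 1L)
  check <- substr(main, nchar(main), nchar(main))
  if (!check %in% LETTERS) {
    stop("check character ", sQuote(check), " at position ", nchar(main),
         " must be a letter A-Z", call. = FALSE)
  }

  extension <- NA_integer_
  if (!is.na(suffix)) {
    if (!grepl("^[1-9][0-9]*$", suffix)) {
      stop("malformed extension suffix ", sQuote(suffix), " at position ",
           dot + 1L, ": must be an integer >= 1 with no leading zeros ",
           "and no nested dots", call. = FALSE)
    }
    extension <- as.integer(suffix)
  }

  structure(
    list(core = core, check = check, extension = extension,
         canonical = if (is.na(extension)) main
                     else paste0(main, ".", extension)),
    class = "unhs_code"
  )
}

#' @export
print.unhs_code <- function(x, ...) {
  cat("<unhs_code> ", x$canonical, "  (core ", x$core, ", check ", x$check,
      if (!is.na(x$extension)) paste0(", extension ", x$extension) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Validate a code string (total, never throws)
#'
#' A code is valid iff it parses and the check letter equals the check digit
#' of the decoded core. The extension suffix is ignored by the checksum (it
#' is appended after the check letter is computed). All failures are
#' reported in-band so batch audits can collect every problem in one pass.
#'
#' @param text A single code string.
#' @return A list with `valid` (logical), `identifier` (the recovered
#'   identifier, or `NA`), `extension` (integer or `NA`) and `reason`
#'   (`NA` when valid).
#' @examples
#' validate_code("RSCF")$identifier  # 22718
#' validate_code("RSCG")$valid      # FALSE: checksum mismatch
#' @export
validate_code <- function(text) {
  parsed <- tryCatch(parse_code(text), error = function(e) e)
  if (inherits(parsed, "error")) {
    return(list(valid = FALSE, identifier = NA_real_,
                extension = NA_integer_,
                reason = conditionMessage(parsed)))
  }
  n <- decode_core(parsed$core)
  expected <- check_digit(n)
  if (expected != parsed$check) {
    return(list(valid = FALSE, identifier = NA_real_,
                extension = parsed$extension,
                reason = paste0("checksum mismatch: expected ", expected,
                                " for identifier ", format(n, scientific = FALSE),
                                ", found ", parsed$check)))
  }
  list(valid = TRUE, identifier = n, extension = parsed$extension,
       reason = NA_character_)
}

#' Validate many codes at once
#'
#' @param texts Character vector of code strings.
#' @return A data frame with one row per input: `code`, `valid`,
#'   `identifier`, `extension`, `reason`.
#' @export
validate_codes <- function(texts) {
  texts <- as.character(texts)
  rows <- lapply(texts, validate_code)
  data.frame(
    code = texts,
    valid = vapply(rows, `[[`, logical(1), "valid"),
    identifier = vapply(rows, `[[`, numeric(1), "identifier"),
    extension = vapply(rows, `[[`, integer(1), "extension"),
    reason = vapply(rows, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
}
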