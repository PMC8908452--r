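# Parsing, validation and canonical formatting of the ISCN-2020 subset used
# in peripheral-blood biomonitoring karyotypes.
#
# Supported aberration terms:
#   +N / -N / +mar                         numerical gain, loss, marker gain
#   del, t, add, der, inv, dic, dup, i, r  structural rearrangements
#   fra, chtb, chrb                        fragile sites and breaks
#   1qh+, 9qh+, 16qh+, pericentric inv(9)  heterochromatic variants (CVs)
#
# Not supported (rejected with an error): mosaicism slashes, stemline
# shorthand (idem/sl/sdl), uncertainty marks except "?" as the band of an
# add(), and chromosome labels outside 1-22, X, Y.

# Category sets used by downstream classification.
CAT_NCA    <- c("loss", "gain", "marker_gain")
CAT_SCA    <- c("del", "t", "add", "der", "inv", "dic", "dup", "iso", "ring")
CAT_BREAK  <- c("chtb", "chrb")
CAT_FRA    <- "fra"
CAT_CV     <- c("cv_1qh_plus", "cv_9qh_plus", "cv_16qh_plus", "cv_inv9")

# Structural prefixes as written in karyotype strings (longest first so the
# alternation never matches a prefix of a longer keyword).
ISCN_PREFIXES <- c(chtb = "chtb", chrb = "chrb", fra = "fra", del = "del",
                   dup = "dup", dic = "dic", der = "der", add = "add",
                   inv = "inv", t = "t", iso = "i", ring = "r")

new_aberration_event <- function(raw_token, category, chromosomes,
                                 breakpoints = character(0)) {
  structure(
    list(raw_token = raw_token, category = category,
         chromosomes = chromosomes, breakpoints = breakpoints),
    class = "aberration_event"
  )
}

#' @export
print.aberration_event <- function(x, ...) {
  cat(sprintf("<aberration_event> %s [%s] chrom: %s%s\n",
              x$raw_token, x$category,
              paste(x$chromosomes, collapse = ";"),
              if (length(x$breakpoints))
                paste0(" bands: ", paste(x$breakpoints, collapse = ";"))
              else ""))
  invisible(x)
}

validate_chromosome <- function(lab, token) {
  lab <- trimws(lab)
  if (toupper(lab) %in% c("X", "Y")) return(toupper(lab))
  if (grepl("^(1[0-9]|2[0-2]|[1-9])$", lab)) return(lab)
  stop_parse(token, sprintf("bad chromosome label '%s'", lab))
}

# One cytogenetic band: arm letter + region/band digits, optional sub-band.
BAND_RE <- "[pq][0-9]+(\\.[0-9]+)?"

# Split a concatenated band field such as "p21q22" or "q21q31".
split_bands <- function(s, token) {
  m <- gregexpr(BAND_RE, s, perl = TRUE)[[1]]
  if (m[1] == -1L)
    stop_parse(token, sprintf("bad band designation '%s'", s))
  bands <- regmatches(s, gregexpr(BAND_RE, s, perl = TRUE))[[1]]
  if (paste(bands, collapse = "") != s)
    stop_parse(token, sprintf("bad band designation '%s'", s))
  bands
}

# Extract "(...)(...)" groups; errors on anything not inside balanced
# parentheses (the subset has no nested parentheses).
paren_groups <- function(rest, token) {
  groups <- regmatches(rest, gregexpr("\\(([^()]*)\\)", rest))[[1]]
  if (paste(groups, collapse = "") != rest)
    stop_parse(token, sprintf("unbalanced or stray text in '%s'", rest))
  substr(groups, 2L, nchar(groups) - 1L)
}

#' Parse one ISCN aberration term
#'
#' Accepts a single aberration token from the supported subset and returns a
#' structured event with its category, the chromosomes cited, and any
#' breakpoints. A pericentric inversion of chromosome 9 (one breakpoint on
#' each arm) is classified as the common heterochromatic variant
#' (`cv_inv9`) rather than as a structural inversion; all other inversions
#' are structural.
#'
#' @param token a single aberration term, e.g. `"del(6)(q25)"`,
#'   `"t(7;14)(p22;q12)"`, `"+mar"`, `"-20"`, `"1qh+"`.
#' @return an `aberration_event`: list with `raw_token`, `category`,
#'   `chromosomes` (character), `breakpoints` (character, possibly empty).
#' @export
#' @examples
#' parse_aberration("del(6)(q25)")
#' parse_aberration("t(7;14)(p22;q12)")
#' parse_aberration("1qh+")
parse_aberration <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- gsub("−", "-", trimws(token))  # normalize unicode minus
  if (!nzchar(tok)) stop_parse(token, "empty token")

  if (tok == "+mar")
    return(new_aberration_event(tok, "marker_gain", character(0)))

  if (grepl("^[+-]", tok)) {
    chrom <- validate_chromosome(substring(tok, 2L), tok)
    cat <- if (substring(tok, 1L, 1L) == "+") "gain" else "loss"
    return(new_aberration_event(paste0(substring(tok, 1L, 1L), chrom),
                                cat, chrom))
  }

  m <- regmatches(tok, regexec("^(1|9|16)qh\\+$", tok))[[1]]
  if (length(m)) {
    return(new_aberration_event(tok, paste0("cv_", m[2], "qh_plus"), m[2]))
  }

  m <- regmatches(tok, regexec("^(chtb|chrb|fra|del|dup|dic|der|add|inv|t|i|r)(\\(.*)$",
                               tok))[[1]]
  if (!length(m)) stop_parse(tok, "unknown prefix")
  prefix <- m[2]
  category <- names(ISCN_PREFIXES)[match(prefix, ISCN_PREFIXES)]

  # Derivative chromosomes: record the category and every cited chromosome;
  # internal structure (an appended rearrangement such as
  # "der(9)t(9;12)(q34;p13)") is kept only in raw_token.
  if (category == "der") {
    rest <- m[3]
    raw_groups <- regmatches(rest, gregexpr("\\(([^()]*)\\)", rest))[[1]]
    leftover <- gsub("\\(([^()]*)\\)", "", rest)
    if (!length(raw_groups) || !grepl("^[a-z]*$", leftover))
      stop_parse(tok, sprintf("unbalanced or stray text in '%s'", rest))
    groups <- substr(raw_groups, 2L, nchar(raw_groups) - 1L)
    chroms <- vapply(strsplit(groups[1], ";", fixed = TRUE)[[1]],
                     validate_chromosome, character(1), token = tok,
                     USE.NAMES = FALSE)
    if (!length(chroms)) stop_parse(tok, "missing chromosome designation")
    extra <- if (length(groups) > 1L)
      unlist(regmatches(groups[-1],
                        gregexpr("(?<![0-9.pq])(1[0-9]|2[0-2]|[1-9]|[XYxy])(?![0-9])",
                                 groups[-1], perl = TRUE)))
    else character(0)
    extra <- vapply(unique(extra), validate_chromosome, character(1),
                    token = tok, USE.NAMES = FALSE)
    return(new_aberration_event(tok, "der", unique(c(chroms, extra))))
  }

  groups <- paren_groups(m[3], tok)
  if (!length(groups)) stop_parse(tok, "missing chromosome designation")

  chroms <- vapply(strsplit(groups[1], ";", fixed = TRUE)[[1]],
                   validate_chromosome, character(1), token = tok,
                   USE.NAMES = FALSE)
  if (!length(chroms)) stop_parse(tok, "missing chromosome designation")

  if (category == "ring") {
    if (length(groups) != 1L || length(chroms) != 1L)
      stop_parse(tok, "ring takes a single chromosome and no band group")
    return(new_aberration_event(tok, "ring", chroms))
  }

  # All remaining categories are band-level: a band group is required.
  if (length(groups) != 2L)
    stop_parse(tok, "expected exactly one chromosome group and one band group")
  band_field <- groups[2]

  if (length(chroms) > 1L) {
    if (!category %in% c("t", "dic"))
      stop_parse(tok, sprintf("'%s' takes a single chromosome", category))
    fields <- strsplit(band_field, ";", fixed = TRUE)[[1]]
    if (length(fields) != length(chroms))
      stop_parse(tok, "band count does not match chromosome count")
    bands <- vapply(fields, function(f) {
      b <- split_bands(f, tok)
      if (length(b) != 1L) stop_parse(tok, "one band expected per chromosome")
      b
    }, character(1), USE.NAMES = FALSE)
    return(new_aberration_event(tok, category, chroms, bands))
  }

  if (category %in% c("t", "dic"))
    stop_parse(tok, sprintf("'%s' requires two or more chromosomes", category))

  # "?" as the band of an add() denotes material of unknown origin.
  if (category == "add" && band_field == "?")
    return(new_aberration_event(tok, "add", chroms, "?"))

  bands <- split_bands(band_field, tok)
  n_ok <- switch(category,
                 del = 1:2, dup = 2L, inv = 2L, iso = 1L,
                 fra = 1L, chtb = 1L, chrb = 1L, add = 1L)
  if (!length(bands) %in% n_ok)
    stop_parse(tok, sprintf("'%s' takes %s breakpoint(s), found %d",
                            category, paste(n_ok, collapse = " or "),
                            length(bands)))

  # Pericentric inversion of chromosome 9 = heterochromatic variant.
  if (category == "inv" && chroms == "9" &&
      length(unique(substr(bands, 1L, 1L))) == 2L)
    category <- "cv_inv9"

  new_aberration_event(tok, category, chroms, bands)
}

new_metaphase_record <- function(individual_id, metaphase_id,
                                 chromosome_count, sex_complement, events) {
  structure(
    list(individual_id = individual_id, metaphase_id = metaphase_id,
         chromosome_count = chromosome_count,
         sex_complement = sex_complement, events = events),
    class = "metaphase_record"
  )
}

#' @export
print.metaphase_record <- function(x, ...) {
  cat(sprintf("<metaphase_record> %s (%s/%s): %d event(s)\n",
              format_karyotype(x), x$individual_id, x$metaphase_id,
              length(x$events)))
  invisible(x)
}

#' Parse a full ISCN karyotype string
#'
#' A karyotype string is `"count,sexComplement[,term]*"`, e.g.
#' `"46,XX,inv(9)(p21q22)"`. Each trailing term is run through
#' [parse_aberration()].
#'
#' @param s karyotype string.
#' @param individual_id,metaphase_id identifiers carried on the record.
#' @return a `metaphase_record`: list with `individual_id`, `metaphase_id`,
#'   `chromosome_count`, `sex_complement` and `events`.
#' @export
#' @examples
#' parse_karyotype("46,XX,inv(9)(p21q22)")
#' parse_karyotype("47,XX,+22")
parse_karyotype <- function(s, individual_id = "", metaphase_id = "") {
  stopifnot(is.character(s), length(s) == 1L)
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  if (length(parts) < 2L)
    stop(sprintf("karyotype '%s' must be 'count,sexComplement[,term]*'", s),
         call. = FALSE)
  if (!grepl("^[0-9]+$", parts[1]))
    stop(sprintf("karyotype '%s': chromosome count '%s' is not an integer",
                 s, parts[1]), call. = FALSE)
  count <- as.integer(parts[1])
  if (count < 1L)
    stop(sprintf("karyotype '%s': chromosome count must be >= 1", s),
         call. = FALSE)
  comp <- toupper(parts[2])
  if (!grepl("^[XY]{1,4}$", comp))
    stop(sprintf("karyotype '%s': bad sex complement '%s'", s, parts[2]),
         call. = FALSE)
  events <- lapply(parts[-(1:2)], parse_aberration)
  new_metaphase_record(individual_id, metaphase_id, count, comp, events)
}

#' Canonical string for one aberration event
#'
#' @param e an `aberration_event`.
#' @return the canonical token text.
#' @export
format_aberration <- function(e) {
  stopifnot(inherits(e, "aberration_event"))
  switch(e$category,
    gain        = paste0("+", e$chromosomes),
    loss        = paste0("-", e$chromosomes),
    marker_gain = "+mar",
    cv_1qh_plus = "1qh+", cv_9qh_plus = "9qh+", cv_16qh_plus = "16qh+",
    der         = e$raw_token,
    ring        = paste0("r(", e$chromosomes, ")"),
    {
      prefix <- if (e$category == "cv_inv9") "inv"
                else unname(ISCN_PREFIXES[e$category])
      bands <- if (length(e$chromosomes) > 1L)
        paste(e$breakpoints, collapse = ";")
      else paste(e$breakpoints, collapse = "")
      paste0(prefix, "(", paste(e$chromosomes, collapse = ";"), ")",
             "(", bands, ")")
    })
}

#' Canonical karyotype string for a metaphase record
#'
#' Round trip: `parse_karyotype(format_karyotype(r))` reproduces `r`'s
#' count, sex complement and events.
#'
#' @param r a `metaphase_record`.
#' @return the canonical ISCN string.
#' @export
#' @examples
#' format_karyotype(parse_karyotype("47,XX,+22"))
format_karyotype <- function(r) {
  stopifnot(inherits(r, "metaphase_record"))
  paste(c(r$chromosome_count, r$sex_complement,
          vapply(r$events, format_aberration, character(1))),
        collapse = ",")
}

#' Is a metaphase record cytogenetically normal?
#'
#' Normal means 46 chromosomes, an XX or XY complement, and no aberration
#' terms.
#'
#' @param r a `metaphase_record`.
#' @return logical.
#' @export
is_normal_karyotype <- function(r) {
  stopifnot(inherits(r, "metaphase_record"))
  r$chromosome_count == 46L && r$sex_complement %in% c("XX", "XY") &&
    length(r$events) == 0L
}

#' Read a karyotype table
#'
#' Expects a UTF-8 TSV with a header row and columns `individual_id`,
#' `metaphase_id`, `karyotype`. Every karyotype string is parsed; a parse
#' failure is reported with its row number.
#'
#' @param path path to the TSV file.
#' @return a tibble with the three input columns plus a list-column
#'   `record` of parsed `metaphase_record`s.
#' @export
read_karyotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8")
  req <- c("individual_id", "metaphase_id", "karyotype")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("karyotype file '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    records[[i]] <- tryCatch(
      parse_karyotype(df$karyotype[i], df$individual_id[i], df$metaphase_id[i]),
      error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  tibble::tibble(individual_id = df$individual_id,
                 metaphase_id = df$metaphase_id,
                 karyotype = df$karyotype,
                 record = records)
}
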