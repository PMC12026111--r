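# Oligonucleotide sequence handling and salt-adjusted melting temperatures.
#
# Adaptive PCR instruments add fluorophore/quencher end-labelled L-DNA
# duplexes ("anneal" and "melt" sensors) to the reaction. L-DNA is the
# mirror-image stereoisomer of natural D-DNA: it hybridizes with identical
# thermodynamics but is invisible to polymerases, so its fluorescence reports
# the hybridization state of the reaction without participating in it.
# Sensor sequences are chosen so their melting temperatures bracket those of
# the primers and the double-stranded target; the Tm calculator here is the
# salt-adjusted formula used for that design comparison.

valid_bases <- c("A", "C", "G", "T")

#' Construct a validated oligonucleotide record
#'
#' Builds a one-row tibble describing an oligonucleotide. Bases are
#' uppercased and validated against the DNA alphabet ACGT; fluorophore and
#' quencher labels and the chirality flag are carried as metadata only and
#' never affect any computation (L-DNA base pairs with the same energetics
#' as D-DNA).
#'
#' @param bases Single string of bases over A, C, G, T (case-insensitive).
#' @param name Optional display name.
#' @param label5,label3 Optional 5'/3' modification names (e.g. "FAM",
#'   "BHQ2"). Metadata only.
#' @param chirality `"D"` (natural) or `"L"` (mirror-image). Metadata only.
#' @return A one-row tibble with columns `name`, `bases`, `length`,
#'   `label5`, `label3`, `chirality`.
#' @examples
#' oligo("ACTGGGTTTTACAAACCTGTGA", name = "anneal sensor", label5 = "TEX",
#'       chirality = "L")
#' @export
oligo <- function(bases, name = NA_character_, label5 = NA_character_,
                  label3 = NA_character_, chirality = c("D", "L")) {
  chirality <- match.arg(chirality)
  bases <- check_bases(bases)
  tibble(
    name = as.character(name), bases = bases, length = nchar(bases),
    label5 = as.character(label5), label3 = as.character(label3),
    chirality = chirality
  )
}

# Uppercase and validate a single base string; errors name the first
# offending position so a mistyped fixture is easy to locate.
check_bases <- function(bases) {
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    abort("`bases` must be a single non-missing string.", class = "adaptivepcr_validation_error")
  }
  bases <- toupper(bases)
  if (nchar(bases) < 1L) {
    abort("sequence must contain at least one base.", class = "adaptivepcr_validation_error")
  }
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% valid_bases)
  if (length(bad) > 0L) {
    abort(
      sprintf("invalid base '%s' at position %d (alphabet is ACGT).",
              chars[bad[1]], bad[1]),
      class = "adaptivepcr_validation_error"
    )
  }
  bases
}

# Accept either a character vector of sequences or a data frame with a
# `bases` column; return a tibble with name/bases columns.
as_oligo_tbl <- function(x) {
  if (is.data.frame(x)) {
    if (!"bases" %in% names(x)) {
      abort("data-frame input must have a `bases` column.", class = "adaptivepcr_validation_error")
    }
    out <- tibble(
      name = if ("name" %in% names(x)) as.character(x$name) else NA_character_,
      bases = vapply(x$bases, check_bases, character(1), USE.NAMES = FALSE)
    )
  } else {
    nm <- names(x) %||% rep(NA_character_, length(x))
    out <- tibble(
      name = as.character(nm),
      bases = vapply(x, check_bases, character(1), USE.NAMES = FALSE)
    )
  }
  out
}

#' Count G+C bases
#'
#' @param x Character vector of sequences, or a data frame with a `bases`
#'   column (e.g. the output of [oligo()] or [ldna_oligos()]).
#' @return Integer vector of G+C counts, one per sequence.
#' @examples
#' gc_count("GCCATTGAAGCGGTTACTTTG")  # 10
#' @export
gc_count <- function(x) {
  tbl <- as_oligo_tbl(x)
  vapply(strsplit(tbl$bases, "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C")), integer(1))
}

#' Salt-adjusted oligonucleotide melting temperature
#'
#' Computes the salt-adjusted Tm used to compare sensor and primer/target
#' melting temperatures. Two formula branches are used depending on length
#' N (threshold 13, the convention of web Tm calculators):
#'
#' \deqn{N > 13:\quad T_m = 100.5 + 41\,GC/N - 820/N + 16.6\log_{10}[Na^+]}
#' \deqn{N \le 13:\quad T_m = 2(A{+}T) + 4(G{+}C) - 16.6\log_{10}(0.05) + 16.6\log_{10}[Na^+]}
#'
#' The default 50 mM monovalent salt reproduces the design values for the
#' short sensor/primer sequences exactly; master-mix salt content is usually
#' proprietary, so the concentration is a parameter, not a constant.
#'
#' @param x Character vector of sequences (optionally named), or a data
#'   frame with `bases` (and optionally `name`) columns.
#' @param na_molar Monovalent cation concentration in mol/L; must be > 0.
#' @return A tibble with one row per sequence: `name`, `bases`, `length`,
#'   `gc_count`, `na_molar`, `formula` (`"salt_adjusted_long"` or
#'   `"salt_adjusted_short"`), `tm_celsius` (full precision) and
#'   `tm_display` (rounded to 1 decimal, the conventional reporting
#'   precision).
#' @examples
#' salt_adjusted_tm(c(anneal = "ACTGGGTTTTACAAACCTGTGA",
#'                    fwd    = "GCCATTGAAGCGGTTACTTTG"))
#' @export
salt_adjusted_tm <- function(x, na_molar = 0.05) {
  if (!is.numeric(na_molar) || length(na_molar) != 1L || is.na(na_molar) ||
      na_molar <= 0) {
    abort("`na_molar` must be a single positive number (mol/L).",
          class = "adaptivepcr_domain_error")
  }
  tbl <- as_oligo_tbl(x)
  chars <- strsplit(tbl$bases, "", fixed = TRUE)
  n <- nchar(tbl$bases)
  gc <- vapply(chars, function(ch) sum(ch %in% c("G", "C")), integer(1))
  at <- n - gc
  long <- n > 13L
  tm <- ifelse(
    long,
    100.5 + 41 * gc / n - 820 / n + 16.6 * log10(na_molar),
    2 * at + 4 * gc - 16.6 * log10(0.05) + 16.6 * log10(na_molar)
  )
  tibble(
    name = tbl$name, bases = tbl$bases, length = as.integer(n),
    gc_count = gc, na_molar = na_molar,
    formula = ifelse(long, "salt_adjusted_long", "salt_adjusted_short"),
    tm_celsius = tm, tm_display = round(tm, 1)
  )
}

#' Reverse complement of a DNA sequence
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    s <- check_bases(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Two-state duplex melt model
#'
#' A logistic two-state surrogate for the melt/anneal transition of a
#' sensor duplex: the single-stranded fraction at temperature T is
#' \deqn{f_{ss}(T) = 1/(1 + e^{-(T - T_m)/w})}
#' so that half the strands are separated at Tm and `width_celsius` sets the
#' steepness of the transition (about 90% melted at Tm + 2.2 w).
#'
#' @param tm_celsius Midpoint temperature in deg C.
#' @param width_celsius Transition width w in deg C; must be > 0.
#' @return An object of class `melt_model`.
#' @examples
#' m <- melt_model(58.4, 2.5)
#' ss_fraction(58.4, m)  # 0.5
#' @export
melt_model <- function(tm_celsius, width_celsius = 2.5) {
  if (!is.numeric(tm_celsius) || length(tm_celsius) != 1L || is.na(tm_celsius)) {
    abort("`tm_celsius` must be a single number.", class = "adaptivepcr_validation_error")
  }
  if (!is.numeric(width_celsius) || length(width_celsius) != 1L ||
      is.na(width_celsius) || width_celsius <= 0) {
    abort("`width_celsius` must be a single positive number.",
          class = "adaptivepcr_validation_error")
  }
  structure(list(tm_celsius = tm_celsius, width_celsius = width_celsius),
            class = "melt_model")
}

#' @export
print.melt_model <- function(x, ...) {
  cat(sprintf("<melt_model> Tm = %.2f degC, width = %.2f degC\n",
              x$tm_celsius, x$width_celsius))
  invisible(x)
}

#' Single-stranded fraction at a temperature
#'
#' @param t Temperature(s) in deg C; vectorized.
#' @param model A [melt_model()].
#' @return Numeric vector of single-stranded fractions in \[0, 1\], strictly
#'   increasing in `t`, equal to 0.5 at `model$tm_celsius`.
#' @export
ss_fraction <- function(t, model) {
  stopifnot(inherits(model, "melt_model"))
  1 / (1 + exp(-(t - model$tm_celsius) / model$width_celsius))
}

#' Read oligonucleotides from a FASTA file
#'
#' Reads sequences with [Biostrings::readDNAStringSet()] and parses optional
#' `key=value` tokens in the description line (`label5`, `label3`,
#' `chirality`, `role`) into metadata columns.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name`, `bases`, `length`, `gc_count`,
#'   `label5`, `label3`, `chirality`, `role`.
#' @export
read_oligo_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  parse_one <- function(h) {
    toks <- strsplit(trimws(h), "\\s+")[[1]]
    kv <- grepl("=", toks, fixed = TRUE)
    meta <- c(label5 = NA_character_, label3 = NA_character_,
              chirality = "D", role = NA_character_)
    for (tok in toks[kv]) {
      parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (parts[1] %in% names(meta)) meta[parts[1]] <- parts[2]
    }
    c(name = paste(toks[!kv], collapse = " "), meta)
  }
  meta <- t(vapply(headers, parse_one, character(5)))
  bases <- vapply(as.character(set), check_bases, character(1),
                  USE.NAMES = FALSE)
  tibble(
    name = unname(meta[, "name"]), bases = bases, length = nchar(bases),
    gc_count = gc_count(bases),
    label5 = unname(meta[, "label5"]), label3 = unname(meta[, "label3"]),
    chirality = unname(meta[, "chirality"]), role = unname(meta[, "role"])
  )
}

#' Bundled sensor, primer, probe and target sequences
#'
#' The oligonucleotide set used by the adaptive PCR assay modelled here:
#' L-DNA anneal and melt sensor duplex strands (fluorophore- and
#' quencher-labelled), the S. mitis primers, hydrolysis probe and synthetic
#' double-stranded target, and the (dT)21 carrier added to serial dilutions.
#' Shipped as a FASTA fixture in `inst/extdata/`.
#'
#' @return A tibble in the format of [read_oligo_fasta()].
#' @examples
#' salt_adjusted_tm(ldna_oligos())
#' @export
ldna_oligos <- function() {
  read_oligo_fasta(system.file("extdata", "table1_oligos.fasta",
                               package = "adaptivepcr", mustWork = TRUE))
}
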