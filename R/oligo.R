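# Average masses (Da) of internal nucleotide-5'-monophosphate residues,
# free acid. Ribose adds one oxygen (+16.00).
RESIDUE_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20, U = 290.17)
RIBO_DELTA <- 16.00
# n residues carry n phosphates; a 5'-OH/3'-OH oligo has n-1 internal
# phosphodiesters: subtract HPO3 (79.98) and add H2O (18.02).
TERMINUS_CORRECTION <- -61.96
# A triazole junction relative to the summed fragment residue masses:
# azido (+24.99) + propargyl (+38.05) termini are consumed into the
# triazole and one terminus correction (-61.96) disappears, so CuAAC
# ligation is exactly mass-additive (cycloaddition conserves atoms).
TRIAZOLE_JUNCTION_DELTA <- 24.99 + 38.05 - 61.96

#' Default terminal/internal modification masses
#'
#' Average-mass deltas relative to the unmodified 5'-OH / 3'-OH terminus.
#' The azido (+24.99, azide replacing hydroxyl), propargyl (+38.05,
#' O-propargyl ether) and Cy5 (+533.7) values are recoverable by
#' subtraction from the reference oligo set ([reference_oligos()]); the
#' remaining linker/label entries are nominal vendor-style values that feed
#' only consistency checks, never golden comparisons, and can be
#' recalibrated by passing an edited table to [oligo_mass()].
#'
#' @return Tibble with columns `name`, `delta` (Da), `provenance`.
#' @export
default_modifications <- function() {
  tibble::tribble(
    ~name,                  ~delta,  ~provenance,
    "azido",                 24.99,  "N3 replaces 5'-OH; consistent with reference oligo 2",
    "propargyl",             38.05,  "3'-O-propargyl ether (C3H3 replaces H)",
    "propargyl_TIPS",       194.40,  "propargyl + triisopropylsilyl protection (nominal)",
    "Cy5",                  533.70,  "5'-Cy5 phosphoramidite; consistent with reference oligos 4/5/6",
    "FAM",                  537.50,  "5'-6-FAM phosphoramidite (nominal vendor value)",
    "amino_C6",             190.20,  "5'-amino C6 linker (nominal vendor value)",
    "biotin_PEG4_amide",    473.00,  "biotin-PEG4 acid amide-coupled to amino linker; derived from reference ligation arithmetic (17,619 - 5,732 - 11,414)",
    "biotin_PEG4_CONH_C6",  663.20,  "amino_C6 + biotin_PEG4_amide (derived sum)",
    "biotin_TEG",           490.70,  "5'-biotin-TEG phosphoramidite (nominal vendor value)",
    "spacer_C3",            138.10,  "C3 spacer phosphoramidite (nominal vendor value)"
  )
}

# Notation aliases recognised by the parser, mapped to modification names.
MOD_ALIASES <- c(
  "BIOTIN-PEG4-CONH-C6" = "biotin_PEG4_CONH_C6",
  "BIOTIN-PEG4"         = "biotin_PEG4_amide",
  "BIOTIN-TEG"          = "biotin_TEG",
  "PROPARGYL-TIPS"      = "propargyl_TIPS",
  "TIPS-PROPARGYL"      = "propargyl_TIPS",
  "SPACERC3"            = "spacer_C3",
  "SPACER-C3"           = "spacer_C3",
  "(NH2-C6)"            = "amino_C6",
  "NH2-C6"              = "amino_C6",
  "PROPARGYL"           = "propargyl",
  "AZIDO"               = "azido",
  "CY5"                 = "Cy5",
  "FAM"                 = "FAM"
)

new_oligo <- function(residues, junctions = integer(),
                      five_prime_mods = character(),
                      three_prime_mods = character(),
                      source = NA_character_) {
  residues <- tibble::as_tibble(residues)
  stopifnot(all(c("base", "sugar") %in% names(residues)))
  junctions <- as.integer(junctions)
  n <- nrow(residues)
  if (length(junctions)) {
    stopifnot(all(junctions >= 1L), all(junctions < n),
              !is.unsorted(junctions, strictly = TRUE))
  }
  structure(
    list(residues = residues, junctions = junctions,
         five_prime_mods = five_prime_mods,
         three_prime_mods = three_prime_mods, source = source),
    class = "del_oligo"
  )
}

#' Parse a modified-oligonucleotide notation string
#'
#' Accepts the notation used throughout this package for chemically
#' modified oligos: whitespace-insensitive base strings over A/C/G/T/U,
#' an `r` prefix marking a ribose residue (`rG`), `^tr` after a residue
#' marking a triazole backbone junction at that position, a leading
#' `5'-<mod>-...` run of named modifications and a trailing `-3'-<mod>`.
#' Recognised modification names are the aliases of
#' [default_modifications()] (case-insensitive), e.g.
#' `"5'-azido-TATAGC...-3'-Propargyl"`.
#'
#' @param text Notation string.
#' @return An object of class `del_oligo`: residue table (`base`, `sugar`),
#'   triazole junction positions (junction `i` sits between residues `i`
#'   and `i + 1`), and terminal modification names.
#' @examples
#' parse_oligo("5'-Cy5-CAG TAC GCA AGC TCG")
#' @export
parse_oligo <- function(text) {
  x <- gsub("[ _′]", "", text)
  x <- gsub("’", "'", x)
  x <- sub("^5'-", "", x)

  five <- character()
  repeat {
    hit <- match_alias(x)
    if (is.na(hit)) break
    five <- c(five, MOD_ALIASES[[hit]])
    x <- substr(x, nchar(hit) + 2L, nchar(x))  # strip "<alias>-"
  }

  bases <- character(); sugars <- character(); junctions <- integer()
  pos <- 0L
  while (nchar(x) > 0 && !startsWith(x, "-")) {
    m <- regmatches(x, regexec("^(r?)([ACGTU])(\\^tr)?", x))[[1]]
    if (length(m) == 0L) {
      abort(sprintf("cannot parse residue at position %d of '%s' (near '%s')",
                    pos + 1L, text, substr(x, 1, 8)))
    }
    pos <- pos + 1L
    bases[pos] <- m[3]
    sugars[pos] <- if (m[2] == "r") "ribo" else "deoxy"
    if (m[4] == "^tr") junctions <- c(junctions, pos)
    x <- substr(x, nchar(m[1]) + 1L, nchar(x))
  }

  three <- character()
  if (nchar(x) > 0) {
    if (!startsWith(x, "-3'-")) {
      abort(sprintf("unexpected trailing text '%s' in '%s'", x, text))
    }
    x <- substr(x, 5L, nchar(x))
    while (nchar(x) > 0) {
      hit <- match_alias(x, terminal = TRUE)
      if (is.na(hit)) abort(sprintf("unknown 3' modification '%s' in '%s'", x, text))
      three <- c(three, MOD_ALIASES[[hit]])
      x <- substr(x, nchar(hit) + 2L, nchar(x))
    }
  }
  if (pos == 0L) abort(sprintf("no residues found in '%s'", text))

  new_oligo(tibble::tibble(base = bases, sugar = sugars),
            junctions, five, three, source = text)
}

match_alias <- function(x, terminal = FALSE) {
  up <- toupper(x)
  aliases <- names(MOD_ALIASES)[order(-nchar(names(MOD_ALIASES)))]  # longest first
  for (alias in aliases) {
    if (startsWith(up, alias)) {
      nxt <- substr(up, nchar(alias) + 1L, nchar(alias) + 1L)
      if (nxt == "-" || (terminal && nxt == "")) return(alias)
    }
  }
  NA_character_
}

#' @export
print.del_oligo <- function(x, ...) {
  cat("<del_oligo> ", nrow(x$residues), "-mer", sep = "")
  if (length(x$junctions)) cat(", ", length(x$junctions), " triazole junction(s)", sep = "")
  if (length(x$five_prime_mods)) cat(", 5'-", paste(x$five_prime_mods, collapse = "-"), sep = "")
  if (length(x$three_prime_mods)) cat(", 3'-", paste(x$three_prime_mods, collapse = "-"), sep = "")
  cat("\n  ", oligo_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Plain base sequence of a parsed oligo
#' @param oligo A `del_oligo`.
#' @return Character scalar (ribose and junction marks dropped).
#' @export
oligo_sequence <- function(oligo) paste(oligo$residues$base, collapse = "")

#' Average mass of one internal nucleotide residue
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`, `"U"` (vectorised).
#' @param sugar `"deoxy"` or `"ribo"`.
#' @return Average residue mass in Da.
#' @examples
#' residue_mass("A")                       # 313.21
#' residue_mass("G", "ribo") - residue_mass("G")   # +16, one oxygen
#' @export
residue_mass <- function(base, sugar = "deoxy") {
  if (any(!base %in% names(RESIDUE_MASS))) {
    abort(sprintf("unknown base(s): %s",
                  paste(setdiff(base, names(RESIDUE_MASS)), collapse = ", ")))
  }
  stopifnot(all(sugar %in% c("deoxy", "ribo")))
  unname(RESIDUE_MASS[base] + ifelse(sugar == "ribo", RIBO_DELTA, 0))
}

#' Average mass of a modified oligonucleotide
#'
#' Sums average residue masses, applies the 5'-OH/3'-OH terminus correction
#' (-61.96 Da), adds each named terminal-modification delta, and adds
#' +1.08 Da per triazole junction so that chemical ligation is exactly
#' mass-additive (see [ligate_mass()]).
#'
#' @param oligo A `del_oligo` (or a notation string, parsed on the fly).
#' @param mods Modification table, defaults to [default_modifications()].
#' @return Mass in Da.
#' @examples
#' oligo_mass("5'-Cy5-CAGTACGCAAGCTCG")   # ~5,096 Da
#' @export
oligo_mass <- function(oligo, mods = default_modifications()) {
  if (is.character(oligo)) oligo <- parse_oligo(oligo)
  stopifnot(inherits(oligo, "del_oligo"))
  named <- c(oligo$five_prime_mods, oligo$three_prime_mods)
  unknown <- setdiff(named, mods$name)
  if (length(unknown)) {
    abort(sprintf("modification(s) not in table: %s", paste(unknown, collapse = ", ")))
  }
  sum(residue_mass(oligo$residues$base, oligo$residues$sugar)) +
    TERMINUS_CORRECTION +
    TRIAZOLE_JUNCTION_DELTA * length(oligo$junctions) +
    sum(mods$delta[match(named, mods$name)])
}

#' Chemically ligate two oligos (CuAAC) and compute the product mass
#'
#' `ligate()` joins a 3'-propargyl (deprotected) oligo to a 5'-azido oligo,
#' recording a triazole junction at the seam; the azide and alkyne are
#' consumed into the triazole ring. `ligate_mass()` returns the product
#' mass, which equals the sum of the fragment masses because cycloaddition
#' conserves atoms.
#'
#' @param a Oligo carrying the 3'-propargyl alkyne (`del_oligo` or string).
#' @param b Oligo carrying the 5'-azido group.
#' @param mods Modification table for `ligate_mass()`.
#' @return `ligate()`: the ligated `del_oligo`; `ligate_mass()`: Da.
#' @export
ligate <- function(a, b) {
  if (is.character(a)) a <- parse_oligo(a)
  if (is.character(b)) b <- parse_oligo(b)
  check_click_pair(a, b)
  na <- nrow(a$residues)
  new_oligo(
    dplyr::bind_rows(a$residues, b$residues),
    junctions = c(a$junctions, na, b$junctions + na),
    five_prime_mods = a$five_prime_mods,
    three_prime_mods = b$three_prime_mods,
    source = NA_character_
  )
}

#' @rdname ligate
#' @export
ligate_mass <- function(a, b, mods = default_modifications()) {
  if (is.character(a)) a <- parse_oligo(a)
  if (is.character(b)) b <- parse_oligo(b)
  check_click_pair(a, b)
  oligo_mass(a, mods) + oligo_mass(b, mods)
}

check_click_pair <- function(a, b) {
  stopifnot(inherits(a, "del_oligo"), inherits(b, "del_oligo"))
  if (nrow(a$residues) == 0L || nrow(b$residues) == 0L) {
    abort("cannot ligate a zero-length oligo")
  }
  if ("propargyl_TIPS" %in% a$three_prime_mods) {
    abort("3' alkyne is TIPS-protected; deprotect before ligation")
  }
  if (!"propargyl" %in% a$three_prime_mods) {
    abort("chemistry mismatch: first oligo lacks a 3'-propargyl alkyne")
  }
  if (!"azido" %in% b$five_prime_mods) {
    abort("chemistry mismatch: second oligo lacks a 5'-azido group")
  }
  invisible(TRUE)
}

#' Mass shift of polymerase stall artifacts
#'
#' Stalled extension products appear with one deoxyadenosine residue lost
#' or (less often) gained relative to the expected stall mass.
#'
#' @param event `"minus_A"` or `"plus_A"`.
#' @return Signed mass delta in Da (one dA residue, -/+313.21).
#' @export
mass_delta <- function(event = c("minus_A", "plus_A")) {
  event <- match.arg(event)
  if (event == "minus_A") -RESIDUE_MASS[["A"]] else RESIDUE_MASS[["A"]]
}

#' Bundled reference oligonucleotides
#'
#' The triazole read-through reference set: ligation fragments, primers,
#' stalled and full-length extension products, and multi-junction templates,
#' each with its reported average molecular weight. Sequences are given in
#' the notation accepted by [parse_oligo()].
#'
#' @return Tibble with columns `id`, `notation`, `reported_mass`, `comment`.
#' @examples
#' ref <- reference_oligos()
#' oligo_mass(ref$notation[ref$id == 4])   # ~5,096 vs reported 5,095
#' @export
reference_oligos <- function() {
  path <- system.file("extdata", "reference_oligos.tsv", package = "clickdel",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_integer(), notation = readr::col_character(),
    reported_mass = readr::col_double(), comment = readr::col_character()
  ))
}
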