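# Atomic-structure container -------------------------------------------------
#
# A chb_structure is a list with two components:
#   * atoms    -- one row per atom: serial, name, altloc, resid, chain, resno,
#                 icode, x, y, z, occupancy, bfactor, element
#   * metadata -- entry_id, source ("experimental"/"predicted"), method,
#                 resolution [A], temperature [K], n_models, dbrefs (tibble),
#                 ssbonds (tibble)
# The flat atoms tibble is the working representation everywhere; residues are
# recovered by grouping on (chain, resno, icode).

#' Construct an atomic structure object
#'
#' Low-level constructor used by [read_structure()] and the synthetic-fixture
#' generator. Most users will not call it directly.
#'
#' @param atoms A data frame with columns `serial`, `name`, `altloc`, `resid`,
#'   `chain`, `resno`, `icode`, `x`, `y`, `z`, `occupancy`, `bfactor`,
#'   `element` (one row per atom).
#' @param entry_id Identifier for the entry (PDB id or synthetic id).
#' @param source `"experimental"` or `"predicted"`. For predicted models the
#'   `bfactor` column is interpreted as per-residue confidence (pLDDT,
#'   0--100), not as a displacement parameter.
#' @param method Experimental method string (e.g. `"X-RAY DIFFRACTION"`), or
#'   `NA`.
#' @param resolution Resolution in Angstrom, or `NA`.
#' @param temperature Data-collection temperature in Kelvin, or `NA`.
#' @param n_models Number of models in the source file (coordinates of model
#'   1 only are ever stored).
#' @param dbrefs Tibble of sequence-database cross-references with columns
#'   `chain`, `database`, `accession`, `seq_begin`, `seq_end`,
#'   `db_seq_begin`, `db_seq_end`; may be empty.
#' @param ssbonds Tibble of declared disulphides with columns `chain1`,
#'   `resno1`, `icode1`, `chain2`, `resno2`, `icode2`; may be empty.
#' @return An object of class `chb_structure`.
#' @export
chb_structure <- function(atoms, entry_id = "XXXX",
                          source = c("experimental", "predicted"),
                          method = NA_character_, resolution = NA_real_,
                          temperature = NA_real_, n_models = 1L,
                          dbrefs = empty_dbrefs(), ssbonds = empty_ssbonds()) {
  source <- match.arg(source)
  atoms <- as_tibble(atoms)
  required <- c("serial", "name", "altloc", "resid", "chain", "resno", "icode",
                "x", "y", "z", "occupancy", "bfactor", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) {
    abort("structure contains no atoms", class = "chalcogenr_empty_structure")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1))) {
    abort("occupancy outside [0, 1]")
  }
  if (any(!nzchar(atoms$element))) abort("empty element symbol")
  if (!is.na(resolution) && resolution <= 0) abort("resolution must be > 0")
  if (!is.na(temperature) && temperature <= 0) abort("temperature must be > 0")
  if (n_models < 1) abort("n_models must be >= 1")

  out <- structure(
    list(
      atoms = atoms,
      metadata = list(
        entry_id = entry_id, source = source, method = method,
        resolution = resolution, temperature = temperature,
        n_models = as.integer(n_models),
        dbrefs = as_tibble(dbrefs), ssbonds = as_tibble(ssbonds)
      )
    ),
    class = "chb_structure"
  )
  check_ssbond_resolvable(out)
  out
}

empty_dbrefs <- function() {
  tibble(chain = character(), database = character(), accession = character(),
         seq_begin = integer(), seq_end = integer(),
         db_seq_begin = integer(), db_seq_end = integer())
}

empty_ssbonds <- function() {
  tibble(chain1 = character(), resno1 = integer(), icode1 = character(),
         chain2 = character(), resno2 = integer(), icode2 = character())
}

# Warn (once per structure) about SSBOND records whose cysteines are absent
# from the coordinates; detection simply ignores them.
check_ssbond_resolvable <- function(s) {
  ss <- s$metadata$ssbonds
  if (nrow(ss) == 0) return(invisible(NULL))
  sg <- s$atoms[s$atoms$resid == "CYS" & s$atoms$name == "SG", ]
  key <- paste(sg$chain, sg$resno, sg$icode)
  bad <- !(paste(ss$chain1, ss$resno1, ss$icode1) %in% key &
             paste(ss$chain2, ss$resno2, ss$icode2) %in% key)
  if (any(bad)) {
    inform(paste0(s$metadata$entry_id, ": ", sum(bad),
                  " SSBOND record(s) reference residues without an SG atom; ",
                  "ignored"),
           class = "chalcogenr_log")
  }
  invisible(NULL)
}

#' @export
print.chb_structure <- function(x, ...) {
  m <- x$metadata
  cat("<chb_structure> ", m$entry_id, " (", m$source, ")\n", sep = "")
  nres <- nrow(distinct(x$atoms, .data$chain, .data$resno, .data$icode))
  cat("  ", nrow(x$atoms), " atoms, ", nres, " residues, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  if (!is.na(m$resolution)) cat("  resolution:", m$resolution, "A\n")
  if (!is.na(m$temperature)) cat("  temperature:", m$temperature, "K\n")
  if (nrow(m$dbrefs) > 0) {
    cat("  DBREF:", paste(unique(m$dbrefs$accession), collapse = ", "), "\n")
  }
  if (nrow(m$ssbonds) > 0) cat("  declared disulphides:", nrow(m$ssbonds), "\n")
  invisible(x)
}

# PDB reading ----------------------------------------------------------------

#' Read a protein structure file
#'
#' Loads atomic coordinates through \pkg{bio3d} and populates the metadata the
#' pipeline needs from the header records: resolution (REMARK 2), data
#' collection temperature (REMARK 200), experimental method (EXPDTA), model
#' count (NUMMDL / MODEL), sequence-database references (DBREF) and declared
#' disulphides (SSBOND). For multi-model files only the first model's
#' coordinates are kept, but `n_models` reflects the file. Alternate
#' locations other than blank or "A" are discarded with a log message, and
#' hydrogens are dropped (all detection geometry uses heavy atoms).
#'
#' @param path Path to the file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension;
#'   anything not ending in `.cif`/`.mmcif` is treated as PDB). mmCIF input
#'   is coordinates-only: header metadata is not extracted from it.
#' @param source `"auto"` (default), `"experimental"` or `"predicted"`.
#'   With `"auto"`, a file whose TITLE mentions ALPHAFOLD or PREDICTED is
#'   flagged predicted; everything else is experimental. For predicted
#'   models the B-factor column is carried through unchanged as pLDDT.
#' @return A [chb_structure()] object.
#' @examples
#' pdb <- system.file("extdata", "toy_chb_synthetic.pdb", package = "chalcogenr")
#' s <- read_structure(pdb)
#' s$metadata$resolution
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source = c("auto", "experimental", "predicted")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }

  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    hdr <- parse_pdb_header(lines)
    pdb <- tryCatch(
      suppressWarnings(suppressMessages(
        bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
      )),
      error = function(e) {
        abort(paste0("cannot parse PDB file '", path, "': ",
                     conditionMessage(e)),
              class = "chalcogenr_format_error")
      }
    )
    n_alt_removed <- sum(!is.na(pdb$atom$alt) & pdb$atom$alt != "A")
    atoms <- bio3d_atoms_to_tibble(pdb$atom)
  } else {
    pdb <- tryCatch(
      suppressWarnings(suppressMessages(bio3d::read.cif(path, verbose = FALSE))),
      error = function(e) {
        abort(paste0("cannot parse mmCIF file '", path, "': ",
                     conditionMessage(e)),
              class = "chalcogenr_format_error")
      }
    )
    hdr <- list(entry_id = toupper(sub("\\.(cif|mmcif)$", "",
                                       basename(path), ignore.case = TRUE)),
                method = NA_character_, resolution = NA_real_,
                temperature = NA_real_, n_models = 1L,
                dbrefs = empty_dbrefs(), ssbonds = empty_ssbonds(),
                title = "")
    inform("mmCIF input: coordinates only, header metadata not extracted",
           class = "chalcogenr_log")
    n_alt_removed <- sum(!is.na(pdb$atom$alt) & pdb$atom$alt != "A")
    atoms <- bio3d_atoms_to_tibble(pdb$atom)
  }

  # Drop remaining non-"blank or A" altlocs and hydrogens.
  keep <- (atoms$altloc %in% c("", "A")) & !(atoms$element %in% c("H", "D"))
  n_alt_removed <- n_alt_removed + sum(!(atoms$altloc %in% c("", "A")))
  if (n_alt_removed > 0) {
    inform(paste0(hdr$entry_id, ": discarded ", n_alt_removed,
                  " alternate-location atom(s) (keeping blank/'A' only)"),
           class = "chalcogenr_log")
  }
  atoms <- atoms[keep, , drop = FALSE]

  if (nrow(atoms) == 0 || !any(atoms$resid %in% AA_STANDARD)) {
    abort(paste0("'", path, "' contains no protein atoms"),
          class = "chalcogenr_empty_structure")
  }

  if (source == "auto") {
    predicted <- grepl("ALPHAFOLD|PREDICTED", hdr$title, ignore.case = TRUE)
    source <- if (predicted) "predicted" else "experimental"
  }

  chb_structure(
    atoms,
    entry_id = hdr$entry_id, source = source, method = hdr$method,
    resolution = hdr$resolution, temperature = hdr$temperature,
    n_models = hdr$n_models, dbrefs = hdr$dbrefs, ssbonds = hdr$ssbonds
  )
}

bio3d_atoms_to_tibble <- function(at) {
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  element <- blank(at$elesy)
  # Fall back to the first alphabetic character of the atom name when the
  # element column is absent (common in minimal files).
  fallback <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                  sub("^[0-9]+", "", at$elety)), 1, 1))
  element <- ifelse(nzchar(element), toupper(trimws(element)), fallback)
  tibble(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    altloc = blank(at$alt),
    resid = as.character(at$resid),
    chain = blank(at$chain),
    resno = as.integer(at$resno),
    icode = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    element = element
  )
}

parse_pdb_header <- function(lines) {
  field <- function(l, from, to) trimws(substr(l, from, to))
  num_or_na <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (length(v) == 0 || all(is.na(v))) NA_real_ else v[!is.na(v)][1]
  }

  entry_id <- NA_character_
  hl <- lines[startsWith(lines, "HEADER")]
  if (length(hl) > 0) entry_id <- field(hl[1], 63, 66)

  title <- paste(field(lines[startsWith(lines, "TITLE")], 11, 80),
                 collapse = " ")

  method <- NA_character_
  el <- lines[startsWith(lines, "EXPDTA")]
  if (length(el) > 0) method <- field(el[1], 11, 79)

  resolution <- NA_real_
  rl <- lines[startsWith(lines, "REMARK   2") & grepl("RESOLUTION", lines)]
  if (length(rl) > 0) {
    m <- regmatches(rl[1],
                    regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)", rl[1], perl = TRUE))
    resolution <- num_or_na(m)
  }

  temperature <- NA_real_
  tl <- lines[startsWith(lines, "REMARK 200") & grepl("TEMPERATURE", lines)]
  if (length(tl) > 0) {
    m <- regmatches(tl[1], regexpr("(?<=:)\\s*[0-9]+\\.?[0-9]*", tl[1], perl = TRUE))
    temperature <- num_or_na(trimws(m))
  }

  n_models <- 1L
  nm <- lines[startsWith(lines, "NUMMDL")]
  n_from_records <- sum(startsWith(lines, "MODEL "))
  if (length(nm) > 0) n_models <- as.integer(field(nm[1], 11, 14))
  n_models <- max(n_models, n_from_records, 1L, na.rm = TRUE)

  dl <- lines[startsWith(lines, "DBREF ")]
  dbrefs <- if (length(dl) == 0) empty_dbrefs() else tibble(
    chain = vapply(dl, field, "", 13, 13, USE.NAMES = FALSE),
    database = vapply(dl, field, "", 27, 32, USE.NAMES = FALSE),
    accession = vapply(dl, field, "", 34, 41, USE.NAMES = FALSE),
    seq_begin = as.integer(vapply(dl, field, "", 15, 18, USE.NAMES = FALSE)),
    seq_end = as.integer(vapply(dl, field, "", 21, 24, USE.NAMES = FALSE)),
    db_seq_begin = as.integer(vapply(dl, field, "", 56, 60, USE.NAMES = FALSE)),
    db_seq_end = as.integer(vapply(dl, field, "", 63, 67, USE.NAMES = FALSE))
  )
  if (is.na(entry_id) && length(dl) > 0) entry_id <- field(dl[1], 8, 11)

  sl <- lines[startsWith(lines, "SSBOND")]
  ssbonds <- if (length(sl) == 0) empty_ssbonds() else tibble(
    chain1 = vapply(sl, field, "", 16, 16, USE.NAMES = FALSE),
    resno1 = as.integer(vapply(sl, field, "", 18, 21, USE.NAMES = FALSE)),
    icode1 = vapply(sl, field, "", 22, 22, USE.NAMES = FALSE),
    chain2 = vapply(sl, field, "", 30, 30, USE.NAMES = FALSE),
    resno2 = as.integer(vapply(sl, field, "", 32, 35, USE.NAMES = FALSE)),
    icode2 = vapply(sl, field, "", 36, 36, USE.NAMES = FALSE)
  )

  list(entry_id = if (is.na(entry_id) || !nzchar(entry_id)) "XXXX" else entry_id,
       title = title, method = method, resolution = resolution,
       temperature = temperature, n_models = n_models,
       dbrefs = dbrefs, ssbonds = ssbonds)
}

# PDB writing ----------------------------------------------------------------

#' Write a structure as a PDB file
#'
#' Emits standard fixed-column records: HEADER, EXPDTA, REMARK 2 (resolution),
#' REMARK 200 (temperature), DBREF, SSBOND, ATOM, TER, END. Coordinates are
#' written at the format's 3-decimal precision, so
#' `read_structure(write_structure(s))` reproduces them to 0.001 Angstrom.
#' Predicted-model provenance is recorded in a TITLE line so that it survives
#' a round trip.
#'
#' @param structure A [chb_structure()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "chb_structure"))
  a <- structure$atoms
  m <- structure$metadata
  if (any(a$x >= 10000 | a$x <= -1000 | a$y >= 10000 | a$y <= -1000 |
            a$z >= 10000 | a$z <= -1000)) {
    abort("coordinates exceed the PDB fixed-column width (8 columns, 3 decimals)",
          class = "chalcogenr_serialization_error")
  }

  lines <- character(0)
  lines <- c(lines, sprintf("%-62s%4s", "HEADER    PROTEIN", m$entry_id))
  if (m$source == "predicted") {
    lines <- c(lines, "TITLE     PREDICTED MODEL (PLDDT IN B-FACTOR COLUMN)")
  }
  if (!is.na(m$method)) lines <- c(lines, sprintf("EXPDTA    %s", m$method))
  if (m$n_models > 1) lines <- c(lines, sprintf("NUMMDL    %-4d", m$n_models))
  if (!is.na(m$resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                              m$resolution))
  }
  if (!is.na(m$temperature)) {
    lines <- c(lines,
               sprintf("REMARK 200  TEMPERATURE           (KELVIN) : %g",
                       m$temperature))
  }
  d <- m$dbrefs
  for (i in seq_len(nrow(d))) {
    lines <- c(lines, sprintf(
      "DBREF  %4s %1s %4d  %4d  %-6s %-8s %-12s %5d  %5d",
      m$entry_id, d$chain[i], d$seq_begin[i], d$seq_end[i],
      d$database[i], d$accession[i], d$accession[i],
      d$db_seq_begin[i], d$db_seq_end[i]))
  }
  ss <- m$ssbonds
  for (i in seq_len(nrow(ss))) {
    lines <- c(lines, sprintf(
      "SSBOND %3d CYS %1s %4d%1s   CYS %1s %4d%1s",
      i, ss$chain1[i], ss$resno1[i], ss$icode1[i],
      ss$chain2[i], ss$resno2[i], ss$icode2[i]))
  }
  name_field <- ifelse(nchar(a$name) >= 4,
                       sprintf("%-4s", a$name),
                       sprintf(" %-3s", a$name))
  lines <- c(lines, sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, name_field, a$altloc, a$resid, a$chain, a$resno, a$icode,
    a$x, a$y, a$z, a$occupancy, a$bfactor, a$element))
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

# Composition ----------------------------------------------------------------

#' Fraction of atoms that are neither protein nor water
#'
#' Atoms belonging to residues outside the 20 standard amino acids and not
#' named HOH/WAT, divided by the total atom count. Used by the curation rule
#' that discards entries with more than 5\% non-protein, non-water content.
#'
#' @param structure A [chb_structure()] object.
#' @return A fraction in `[0, 1]`.
#' @export
nonprotein_fraction <- function(structure) {
  stopifnot(inherits(structure, "chb_structure"))
  a <- structure$atoms
  sum(!(a$resid %in% AA_STANDARD) & !(a$resid %in% WATER_NAMES)) / nrow(a)
}
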