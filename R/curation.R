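# Experimental-set curation --------------------------------------------------

#' Curation policy for experimental entries
#'
#' Thresholds for selecting the high-resolution experimental set: X-ray
#' entries at resolution <= 1.5 Angstrom collected at cryogenic temperature
#' (90--110 K), single-model refinements, and at most 5\% of atoms that are
#' neither protein nor water. The sequence-identity ceiling documents the
#' downstream redundancy-reduction stage (see [redundancy_filter()]); it is
#' not evaluated per entry.
#'
#' @param max_resolution Maximum resolution in Angstrom (inclusive).
#' @param temp_range Length-2 numeric, allowed temperature window in Kelvin
#'   (inclusive at both ends).
#' @param max_nonprotein_fraction Maximum fraction of non-protein, non-water
#'   atoms.
#' @param require_single_model Reject multi-model refinements?
#' @param require_xray Require an X-ray diffraction method string?
#' @param max_seq_identity Pairwise sequence-identity ceiling in percent for
#'   the redundancy stage.
#' @return An object of class `curation_policy`.
#' @export
curation_policy <- function(max_resolution = 1.5,
                            temp_range = c(90, 110),
                            max_nonprotein_fraction = 0.05,
                            require_single_model = TRUE,
                            require_xray = TRUE,
                            max_seq_identity = 40) {
  stopifnot(max_resolution > 0, length(temp_range) == 2,
            temp_range[1] <= temp_range[2],
            max_nonprotein_fraction >= 0, max_nonprotein_fraction <= 1)
  structure(
    list(max_resolution = max_resolution, temp_range = temp_range,
         max_nonprotein_fraction = max_nonprotein_fraction,
         require_single_model = isTRUE(require_single_model),
         require_xray = isTRUE(require_xray),
         max_seq_identity = max_seq_identity),
    class = "curation_policy"
  )
}

#' Apply the curation rules to one structure
#'
#' Every rule is evaluated independently, so a verdict lists all failures,
#' not just the first. Missing metadata required by a rule (e.g. no recorded
#' temperature) fails that rule: curation is conservative.
#'
#' @param structure A [chb_structure()] object.
#' @param policy A [curation_policy()] object.
#' @return A one-row tibble: `entry_id`, one logical column per rule
#'   (`xray`, `resolution`, `temperature`, `single_model`,
#'   `nonprotein_fraction`), `passed`, and a list-column `failed_rules`
#'   naming the rules that failed.
#' @export
apply_curation <- function(structure, policy = curation_policy()) {
  stopifnot(inherits(structure, "chb_structure"),
            inherits(policy, "curation_policy"))
  m <- structure$metadata
  rules <- c(
    xray = !policy$require_xray ||
      (!is.na(m$method) && grepl("X-RAY", m$method, ignore.case = TRUE)),
    resolution = !is.na(m$resolution) && m$resolution <= policy$max_resolution,
    temperature = !is.na(m$temperature) &&
      m$temperature >= policy$temp_range[1] &&
      m$temperature <= policy$temp_range[2],
    single_model = !policy$require_single_model || m$n_models == 1,
    nonprotein_fraction =
      nonprotein_fraction(structure) <= policy$max_nonprotein_fraction
  )
  failed <- names(rules)[!rules]
  out <- as_tibble(as.list(rules))
  out <- mutate(out, entry_id = m$entry_id, passed = length(failed) == 0,
                failed_rules = list(failed), .before = 1)
  out
}

#' Pairing key: does the entry carry a usable sequence-database accession?
#'
#' Predicted-model lookup keys on the sequence-database accession in the
#' entry's DBREF records. Entries without one (typically engineered mutants
#' absent from the sequence databases) cannot be paired.
#'
#' @param structure A [chb_structure()] object.
#' @return A list with `pairable` (logical) and `accession` (the first
#'   non-blank accession, preferring UniProt (`UNP`) references, or `NA`).
#' @export
has_pairable_accession <- function(structure) {
  stopifnot(inherits(structure, "chb_structure"))
  d <- structure$metadata$dbrefs
  d <- d[nzchar(d$accession), , drop = FALSE]
  if (nrow(d) == 0) return(list(pairable = FALSE, accession = NA_character_))
  unp <- d[d$database == "UNP", , drop = FALSE]
  acc <- if (nrow(unp) > 0) unp$accession[1] else d$accession[1]
  list(pairable = TRUE, accession = acc)
}

# Sequence-redundancy reduction ----------------------------------------------

# Global pairwise identity: Needleman-Wunsch with match +1, mismatch 0, each
# gap position -1; identity = matches / alignment length (in percent).
pairwise_identity <- function(a, b) {
  alph <- unique(strsplit(paste0(a, b), "")[[1]])
  mat <- matrix(0, length(alph), length(alph), dimnames = list(alph, alph))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

#' Reduce sequence redundancy among curated entries
#'
#' Interface to the redundancy-reduction stage of curation. When
#' `cdhit_path` points to a runnable clustering executable it is delegated
#' to (invoked on a temporary FASTA file; cluster representatives are
#' returned). Otherwise a documented stub is applied: sequences are visited
#' in order of decreasing length (ties keep input order) and a sequence is
#' retained only if its global pairwise identity to every already-retained
#' sequence is at most `max_identity` percent. Identity is computed on a
#' global alignment with match +1, mismatch 0, gap -1, as matches divided by
#' alignment length. The stub is deterministic and idempotent; a log message
#' records that the stub, not an external clusterer, produced the result.
#'
#' @param entries A data frame with columns `entry_id` and `sequence`
#'   (one-letter amino-acid strings).
#' @param max_identity Maximum allowed pairwise identity, percent.
#' @param cdhit_path Optional path to an external clustering executable.
#' @return Character vector of retained `entry_id`s.
#' @export
redundancy_filter <- function(entries, max_identity = 40, cdhit_path = NULL) {
  entries <- as_tibble(entries)
  stopifnot(all(c("entry_id", "sequence") %in% names(entries)))
  if (nrow(entries) == 0) return(character(0))

  if (!is.null(cdhit_path)) {
    if (!file.exists(cdhit_path) || file.access(cdhit_path, 1) != 0) {
      abort(paste0("external clustering tool not runnable: ", cdhit_path),
            class = "chalcogenr_tool_error")
    }
    fa <- tempfile(fileext = ".fasta")
    out <- tempfile()
    writeLines(paste0(">", entries$entry_id, "\n", entries$sequence), fa)
    status <- system2(cdhit_path,
                      c("-i", fa, "-o", out, "-c", max_identity / 100),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0 || !file.exists(out)) {
      abort("external clustering tool failed", class = "chalcogenr_tool_error")
    }
    reps <- readLines(out)
    return(sub("^>", "", reps[startsWith(reps, ">")]))
  }

  inform(paste0("redundancy_filter: using the built-in greedy alignment stub ",
                "(no external clusterer configured)"),
         class = "chalcogenr_log")
  ord <- order(-nchar(entries$sequence), seq_len(nrow(entries)))
  retained_idx <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in retained_idx) {
      if (pairwise_identity(entries$sequence[i], entries$sequence[j]) >
            max_identity) {
        ok <- FALSE
        break
      }
    }
    if (ok) retained_idx <- c(retained_idx, i)
  }
  entries$entry_id[sort(retained_idx)]
}
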