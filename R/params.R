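#' Chalcogen-bond detection parameters
#'
#' Bundles every threshold used by [detect_chbs()] and downstream comparison
#' functions. The defaults encode the survey criteria for protein structures:
#' a nucleophile--sulfur contact is a chalcogen bond when its distance `d`
#' does not exceed the sum of the two van der Waals radii plus a 0.1 Angstrom
#' tolerance, and its directionality angle `alpha` (deviation from the
#' prolongation of a covalent bond to the sulfur) does not exceed 25 degrees.
#' Both cutoffs are inclusive.
#'
#' @param vdw_radii Named numeric vector of van der Waals radii in Angstrom.
#'   Defaults to Bondi radii for the two default acceptor elements
#'   (O = 1.52, S = 1.80). Extend it to enable other acceptor elements.
#' @param distance_tolerance Margin added to the van der Waals sum, in
#'   Angstrom. Accounts for the coordinate accuracy of macromolecular
#'   structures relative to small-molecule crystallography.
#' @param alpha_max Maximum allowed `alpha` in degrees (25 rather than the
#'   20 used in small-molecule work, again an accuracy allowance).
#' @param ssbond_distance_max Maximum SG--SG distance, in Angstrom, for two
#'   cysteine sulfurs to count as a disulphide bridge. The default 2.5 is
#'   generous versus the canonical 2.05 bond length so that moderately
#'   distorted predicted models still register their bridges; a pair beyond
#'   it is reported as a broken disulphide.
#' @param acceptor_elements Character vector of element symbols eligible as
#'   nucleophiles. Every element listed must have an entry in `vdw_radii`.
#' @param exclude_same_residue Should atoms of the donor cysteine itself be
#'   excluded as acceptors? Default `TRUE`.
#' @param include_waters Should water oxygens be considered acceptors?
#'   Default `FALSE`.
#'
#' @return An object of class `chb_params` (a named list).
#' @seealso [vdw_contact_threshold()], [detect_chbs()]
#' @examples
#' p <- chb_params()
#' vdw_contact_threshold("O", "S", p$distance_tolerance, p$vdw_radii)
#' @export
chb_params <- function(vdw_radii = c(O = 1.52, S = 1.80),
                       distance_tolerance = 0.1,
                       alpha_max = 25,
                       ssbond_distance_max = 2.5,
                       acceptor_elements = c("O", "S"),
                       exclude_same_residue = TRUE,
                       include_waters = FALSE) {
  stopifnot(is.numeric(vdw_radii), !is.null(names(vdw_radii)))
  if (any(vdw_radii <= 0)) abort("all van der Waals radii must be positive")
  if (distance_tolerance < 0) abort("`distance_tolerance` must be >= 0")
  if (alpha_max <= 0 || alpha_max >= 90) abort("`alpha_max` must be in (0, 90)")
  if (ssbond_distance_max <= 0) abort("`ssbond_distance_max` must be positive")
  missing_r <- setdiff(acceptor_elements, names(vdw_radii))
  if (length(missing_r) > 0) {
    abort(paste0("no van der Waals radius for acceptor element(s): ",
                 paste(missing_r, collapse = ", ")))
  }
  structure(
    list(
      vdw_radii = vdw_radii,
      distance_tolerance = distance_tolerance,
      alpha_max = alpha_max,
      ssbond_distance_max = ssbond_distance_max,
      acceptor_elements = acceptor_elements,
      exclude_same_residue = isTRUE(exclude_same_residue),
      include_waters = isTRUE(include_waters)
    ),
    class = "chb_params"
  )
}

#' @export
print.chb_params <- function(x, ...) {
  cat("<chb_params>\n")
  cat("  vdW radii:         ",
      paste(names(x$vdw_radii), x$vdw_radii, sep = " = ", collapse = ", "),
      " [A]\n", sep = "")
  cat("  distance tolerance:", x$distance_tolerance, "A\n")
  cat("  alpha max:         ", x$alpha_max, "deg\n")
  cat("  SS distance max:   ", x$ssbond_distance_max, "A\n")
  cat("  acceptor elements: ", paste(x$acceptor_elements, collapse = ", "), "\n")
  invisible(x)
}

#' Van der Waals contact threshold for an element pair
#'
#' Returns the maximum nucleophile--chalcogen distance at which a contact
#' qualifies as a chalcogen bond: the sum of the two van der Waals radii plus
#' a tolerance. With the default radii the oxygen--sulfur threshold is
#' 1.52 + 1.80 + 0.1 = 3.42 Angstrom.
#'
#' @param elem_a,elem_b Element symbols, e.g. `"O"` and `"S"`.
#' @param tolerance Additive margin in Angstrom (default 0.1).
#' @param radii Named radii table in Angstrom; defaults to the
#'   [chb_params()] table.
#' @return The threshold distance in Angstrom (scalar).
#' @examples
#' vdw_contact_threshold("O", "S") # 3.42
#' @export
vdw_contact_threshold <- function(elem_a, elem_b, tolerance = 0.1,
                                  radii = chb_params()$vdw_radii) {
  for (e in c(elem_a, elem_b)) {
    if (!e %in% names(radii)) {
      abort(paste0("unknown element '", e, "': not in the radii table"),
            class = "chalcogenr_unknown_element")
    }
  }
  unname(radii[[elem_a]] + radii[[elem_b]] + tolerance)
}
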