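# Vector helpers ------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

# Angle at vertex `s` subtended by points `a` and `b`, in degrees.
angle_deg <- function(a, s, b) {
  v1 <- a - s
  v2 <- b - s
  n1 <- vnorm(v1)
  n2 <- vnorm(v2)
  if (n1 < 1e-9 || n2 < 1e-9) {
    rlang::abort("degenerate geometry: coincident points",
                 class = "chalcogenr_degenerate_geometry")
  }
  cosv <- sum(v1 * v2) / (n1 * n2)
  cosv <- min(1, max(-1, cosv))
  acos(cosv) * 180 / pi
}

#' Chalcogen-bond geometry for one nucleophile--sulfur contact
#'
#' Computes the two descriptors of a candidate chalcogen bond: the
#' nucleophile--sulfur distance `d`, and for each atom covalently bound to the
#' sulfur the angle `alpha = 180 - theta`, where `theta` is the angle
#' nucleophile--sulfur--partner. `alpha` measures how far the nucleophile
#' deviates from the prolongation of that covalent bond; a divalent sulfur has
#' two prolongations, and the smaller of the two alphas (`alpha_min`) is the
#' one tested against the angular cutoff. Both quantities are invariant under
#' rigid-body motion of the coordinates.
#'
#' @param nu Numeric length-3 coordinates of the nucleophile (Angstrom).
#' @param s Numeric length-3 coordinates of the sulfur.
#' @param partners A numeric length-3 vector, or a list / 2-row matrix of
#'   them: the atoms covalently bound to the sulfur (CB and the partner SG
#'   for a disulphide sulfur).
#' @return A list with `d` (Angstrom), `alphas` (degrees, one per partner)
#'   and `alpha_min`.
#' @examples
#' g <- chb_geometry(c(3, 0, 0), c(0, 0, 0), c(-1.8, 0, 0))
#' g$d          # 3
#' g$alpha_min  # 0: nucleophile exactly on the prolongation
#' @export
chb_geometry <- function(nu, s, partners) {
  nu <- as.numeric(nu)
  s <- as.numeric(s)
  if (is.matrix(partners)) {
    partners <- lapply(seq_len(nrow(partners)), function(i) as.numeric(partners[i, ]))
  } else if (!is.list(partners)) {
    partners <- list(as.numeric(partners))
  }
  stopifnot(length(nu) == 3, length(s) == 3, length(partners) >= 1)
  d <- vnorm(nu - s)
  if (d < 1e-9) {
    rlang::abort("degenerate geometry: nucleophile coincides with the sulfur",
                 class = "chalcogenr_degenerate_geometry")
  }
  alphas <- vapply(partners, function(p) 180 - angle_deg(nu, s, p), numeric(1))
  list(d = d, alphas = alphas, alpha_min = min(alphas))
}
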