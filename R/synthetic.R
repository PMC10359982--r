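# Synthetic fixtures: minimal disulphide structures with prescribed
# chalcogen-bond geometry, and Gaussian-perturbed "predicted" counterparts.

unitize <- function(v) v / vnorm(v)

#' Specification of a toy chalcogen-bond geometry
#'
#' Describes where to place a nucleophile relative to a disulphide sulfur:
#' at distance `d` from the donor SG and angle `alpha` off the prolongation
#' of its CB--SG bond, rotated by `dihedral_phi` about that prolongation
#' axis. [build_toy_chb()] inverts the (d, alpha) measurement exactly.
#'
#' @param d Nucleophile--sulfur distance, Angstrom.
#' @param alpha Deviation from the CB--SG prolongation, degrees, in
#'   `[0, 180]`.
#' @param dihedral_phi Rotation of the nucleophile about the prolongation
#'   axis, degrees.
#' @param acceptor_context `"backbone-O"` (glycine carbonyl oxygen),
#'   `"sidechain-O"` (serine OG) or `"sidechain-S"` (free-cysteine SG).
#' @return An object of class `toy_geometry_spec`.
#' @export
toy_geometry_spec <- function(d, alpha, dihedral_phi = 0,
                              acceptor_context = c("backbone-O", "sidechain-O",
                                                   "sidechain-S")) {
  acceptor_context <- match.arg(acceptor_context)
  stopifnot(is.numeric(d), d > 0, is.numeric(alpha), alpha >= 0, alpha <= 180)
  structure(
    list(d = d, alpha = alpha, dihedral_phi = dihedral_phi,
         acceptor_context = acceptor_context,
         acceptor_element = if (acceptor_context == "sidechain-S") "S" else "O"),
    class = "toy_geometry_spec"
  )
}

# Fixed two-cysteine scaffold. Donor SG at the origin, donor CB on -x so the
# CB--SG prolongation is +x; partner SG at 2.05 A with a 104 deg CB-S-S
# angle, its CB out of plane (90 deg disulphide dihedral). Backbone atoms
# point away from the +x/+y region where the nucleophile is placed.
toy_scaffold <- function() {
  sg1 <- c(0, 0, 0)
  cb1 <- c(-1.81, 0, 0)
  u <- c(cos(76 * pi / 180), -sin(76 * pi / 180), 0)
  sg2 <- 2.05 * u
  w <- cos(104 * pi / 180) * (-u) + sin(104 * pi / 180) * c(0, 0, 1)
  cb2 <- sg2 + 1.81 * w

  ca1 <- cb1 + 1.53 * unitize(c(-0.41, -0.79, -0.46))
  n1 <- ca1 + 1.47 * unitize(c(-1.2, 0.6, -0.5))
  c1 <- ca1 + 1.52 * unitize(c(-0.3, -0.9, 0.3))
  o1 <- c1 + 1.23 * unitize(c(0, -0.9, 0.44))

  ca2 <- cb2 + 1.53 * unitize(c(0.2, -0.8, 0.56))
  n2 <- ca2 + 1.47 * unitize(c(1.0, 0.3, 0))
  c2 <- ca2 + 1.52 * unitize(c(-0.5, -0.8, 0.33))
  o2 <- c2 + 1.23 * unitize(c(-0.8, -0.4, 0.45))

  # A distant glycine whose amide nitrogen sits 3.0 A from the donor's
  # carbonyl oxygen: a genuine non-adjacent main-chain O...N contact for the
  # control statistic.
  n7 <- o1 + 3.0 * unitize(c(0, -0.9, 0.44))
  ca7 <- n7 + 1.47 * unitize(c(-0.8, -0.5, 0.3))
  c7 <- ca7 + 1.52 * unitize(c(0.3, -0.9, 0.2))
  o7 <- c7 + 1.23 * unitize(c(0.9, -0.3, -0.3))

  list(
    res2 = list(resid = "CYS", atoms = list(N = n1, CA = ca1, C = c1, O = o1,
                                            CB = cb1, SG = sg1)),
    res3 = list(resid = "CYS", atoms = list(N = n2, CA = ca2, C = c2, O = o2,
                                            CB = cb2, SG = sg2)),
    res7 = list(resid = "GLY", atoms = list(N = n7, CA = ca7, C = c7, O = o7))
  )
}

toy_acceptor_fragment <- function(spec) {
  ar <- spec$alpha * pi / 180
  pr <- spec$dihedral_phi * pi / 180
  dir <- c(cos(ar), sin(ar) * cos(pr), sin(ar) * sin(pr))
  nu <- spec$d * dir
  out_ca <- unitize(dir + c(0, 0, 0.8))
  out_n <- unitize(dir + c(0, 0, -0.3))
  if (spec$acceptor_context == "backbone-O") {
    c5 <- nu + 1.23 * dir
    ca5 <- c5 + 1.53 * out_ca
    n5 <- ca5 + 1.47 * out_n
    list(resid = "GLY", atoms = list(N = n5, CA = ca5, C = c5, O = nu),
         nu_name = "O")
  } else if (spec$acceptor_context == "sidechain-O") {
    cb5 <- nu + 1.43 * dir
    ca5 <- cb5 + 1.53 * out_ca
    n5 <- ca5 + 1.47 * out_n
    c5 <- ca5 + 1.52 * unitize(dir + c(0, 0.7, 0.2))
    o5 <- c5 + 1.23 * unitize(dir + c(0, 0.9, 0))
    list(resid = "SER", atoms = list(N = n5, CA = ca5, C = c5, O = o5,
                                     CB = cb5, OG = nu),
         nu_name = "OG")
  } else {
    cb5 <- nu + 1.81 * dir
    ca5 <- cb5 + 1.53 * out_ca
    n5 <- ca5 + 1.47 * out_n
    c5 <- ca5 + 1.52 * unitize(dir + c(0, 0.7, 0.2))
    o5 <- c5 + 1.23 * unitize(dir + c(0, 0.9, 0))
    list(resid = "CYS", atoms = list(N = n5, CA = ca5, C = c5, O = o5,
                                     CB = cb5, SG = nu),
         nu_name = "SG")
  }
}

atom_element <- function(name) substr(name, 1, 1)

#' Build a minimal structure containing one prescribed chalcogen bond
#'
#' Emits a four-residue, single-chain structure: two cysteines forming a
#' canonical disulphide (SG--SG 2.05 A, CB--SG 1.81 A), an acceptor residue
#' whose nucleophile sits at exactly (`d`, `alpha`) relative to the donor SG
#' measured against the CB--SG prolongation, and a distant glycine providing
#' a main-chain O...N control contact. Metadata is experimental-grade (X-ray,
#' 1.2 A, 100 K), carries an SSBOND record and a synthetic sequence-database
#' accession with sequential numbering, so curation and pairing run
#' unmodified on fixtures.
#'
#' @param spec A [toy_geometry_spec()].
#' @param entry_id Entry identifier (4 characters fit the PDB header).
#' @param accession Synthetic database accession for the DBREF record.
#' @return A [chb_structure()] object, `source = "experimental"`.
#' @examples
#' s <- build_toy_chb(toy_geometry_spec(d = 3.0, alpha = 10))
#' detect_chbs(s)[, c("d", "alpha_min")]
#' @export
build_toy_chb <- function(spec, entry_id = "SYN1", accession = "SYNTH001") {
  stopifnot(inherits(spec, "toy_geometry_spec"))
  scaffold <- toy_scaffold()
  acceptor <- toy_acceptor_fragment(spec)

  residues <- list(
    `2` = scaffold$res2, `3` = scaffold$res3,
    `5` = acceptor, `7` = scaffold$res7
  )
  rows <- list()
  serial <- 0L
  for (rn in names(residues)) {
    r <- residues[[rn]]
    for (an in names(r$atoms)) {
      serial <- serial + 1L
      xyz <- r$atoms[[an]]
      rows[[serial]] <- tibble(
        serial = serial, name = an, altloc = "", resid = r$resid,
        chain = "A", resno = as.integer(rn), icode = "",
        x = xyz[1], y = xyz[2], z = xyz[3],
        occupancy = 1, bfactor = 10, element = atom_element(an)
      )
    }
  }
  atoms <- bind_rows(rows)

  # Feasibility: no two atoms from different residues (other than the
  # disulphide sulfurs) may come closer than 1.5 A.
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  same_res <- outer(atoms$resno, atoms$resno, "==")
  is_sg12 <- (atoms$resno %in% c(2, 3)) & (atoms$name == "SG")
  ss_pair <- outer(is_sg12, is_sg12, "&")
  clash <- dm < 1.5 & !same_res & !ss_pair
  diag(clash) <- FALSE
  if (any(clash)) {
    abort("infeasible toy spec: non-bonded atoms closer than 1.5 A",
          class = "chalcogenr_infeasible_spec")
  }

  chb_structure(
    atoms, entry_id = entry_id, source = "experimental",
    method = "X-RAY DIFFRACTION", resolution = 1.2, temperature = 100,
    n_models = 1L,
    dbrefs = tibble(chain = "A", database = "UNP", accession = accession,
                    seq_begin = 2L, seq_end = 7L,
                    db_seq_begin = 2L, db_seq_end = 7L),
    ssbonds = tibble(chain1 = "A", resno1 = 2L, icode1 = "",
                     chain2 = "A", resno2 = 3L, icode2 = "")
  )
}

#' Perturb a structure with isotropic Gaussian coordinate noise
#'
#' Adds independent zero-mean Gaussian noise with standard deviation `sigma`
#' to every coordinate of every atom -- the simplest noise model consistent
#' with a single scalar positional standard error. The result is flagged
#' `source = "predicted"`, its B-factor column is replaced by a constant
#' pLDDT, and SSBOND records are dropped (predicted-model files carry none;
#' bridges must be re-detected geometrically). Deterministic given `seed`.
#'
#' @param structure A [chb_structure()] object.
#' @param sigma Per-coordinate standard deviation, Angstrom (`>= 0`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param plddt Constant confidence value stored per atom (default 95).
#' @return A perturbed [chb_structure()], `source = "predicted"`.
#' @export
perturb_structure <- function(structure, sigma, seed = NULL, plddt = 95) {
  stopifnot(inherits(structure, "chb_structure"), sigma >= 0)
  atoms <- structure$atoms
  if (sigma > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
      }
      set.seed(seed)
    }
    n <- nrow(atoms)
    atoms$x <- atoms$x + rnorm(n, 0, sigma)
    atoms$y <- atoms$y + rnorm(n, 0, sigma)
    atoms$z <- atoms$z + rnorm(n, 0, sigma)
  }
  atoms$bfactor <- plddt
  chb_structure(
    atoms, entry_id = structure$metadata$entry_id, source = "predicted",
    method = NA_character_, resolution = NA_real_, temperature = NA_real_,
    n_models = 1L, dbrefs = structure$metadata$dbrefs,
    ssbonds = empty_ssbonds()
  )
}

#' Specification of a paired synthetic dataset
#'
#' Study conditions for the synthetic survey: each entry is a toy structure
#' with chalcogen-bond geometry sampled uniformly (defaults: `d` in
#' 2.90--3.35 A, `alpha` in 0--20 deg, comfortably inside the detection
#' criteria so an unperturbed dataset is fully recovered), paired with a
#' Gaussian-perturbed counterpart of per-coordinate noise `noise_sigma`.
#'
#' @param n_entries Number of structure pairs.
#' @param d_range,alpha_range Uniform sampling intervals for the bond
#'   geometry (Angstrom / degrees).
#' @param noise_sigma Per-coordinate Gaussian noise, Angstrom.
#' @param seed Integer seed controlling both sampling and perturbation.
#' @param acceptor_context Passed to [toy_geometry_spec()].
#' @return An object of class `paired_dataset_spec`.
#' @export
paired_dataset_spec <- function(n_entries, d_range = c(2.90, 3.35),
                                alpha_range = c(0, 20), noise_sigma = 0.1,
                                seed = 1L, acceptor_context = "backbone-O") {
  stopifnot(n_entries >= 1, noise_sigma >= 0,
            length(d_range) == 2, length(alpha_range) == 2)
  structure(
    list(n_entries = as.integer(n_entries), d_range = d_range,
         alpha_range = alpha_range, noise_sigma = noise_sigma,
         seed = as.integer(seed), acceptor_context = acceptor_context),
    class = "paired_dataset_spec"
  )
}

# Independent recomputation of the toy bond geometry from raw coordinates.
# Deliberately does not call chb_geometry(): the truth table must not share
# code with the detection path it validates.
toy_truth_geometry <- function(s, nu_name) {
  a <- s$atoms
  get1 <- function(resno, name) {
    r <- a[a$resno == resno & a$name == name, ]
    c(r$x[1], r$y[1], r$z[1])
  }
  sg1 <- get1(2, "SG"); sg2 <- get1(3, "SG"); cb1 <- get1(2, "CB")
  nu <- get1(5, nu_name)
  nrm <- function(v) sqrt(sum(v^2))
  ang <- function(p, q, r) { # angle at q, degrees
    v1 <- p - q; v2 <- r - q
    acos(max(-1, min(1, sum(v1 * v2) / (nrm(v1) * nrm(v2))))) * 180 / pi
  }
  d <- nrm(nu - sg1)
  a_cb <- 180 - ang(nu, sg1, cb1)
  a_ss <- 180 - ang(nu, sg1, sg2)
  list(d = d, alpha_cb = a_cb, alpha_ss = a_ss,
       alpha_min = min(a_cb, a_ss), ss = nrm(sg1 - sg2))
}

#' Generate a paired synthetic dataset with ground truth
#'
#' Builds `n_entries` toy structures with sampled bond geometry, perturbs
#' each into a "predicted" counterpart, and records a truth table: the bond
#' geometry before and after perturbation, recomputed directly from the raw
#' coordinates with arithmetic independent of the detection module, and
#' whether the perturbed geometry still satisfies the detection criteria
#' (including an intact disulphide). The truth table is the oracle against
#' which the pipeline's recovery fraction is checked exactly.
#'
#' @param spec A [paired_dataset_spec()].
#' @param params The [chb_params()] defining the pass criteria recorded in
#'   the truth table.
#' @return A list with `experimental` (list of structures), `models` (their
#'   perturbed counterparts) and `truth` (tibble: `entry_id`, `d_true`,
#'   `alpha_true`, `d_perturbed`, `alpha_perturbed`, `ss_perturbed`,
#'   `recovered_truth`).
#' @export
generate_paired_dataset <- function(spec, params = chb_params()) {
  stopifnot(inherits(spec, "paired_dataset_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)
  n <- spec$n_entries
  d_s <- stats::runif(n, spec$d_range[1], spec$d_range[2])
  a_s <- stats::runif(n, spec$alpha_range[1], spec$alpha_range[2])
  pert_seeds <- sample.int(.Machine$integer.max, n)

  experimental <- vector("list", n)
  models <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    gspec <- toy_geometry_spec(d_s[i], a_s[i],
                               acceptor_context = spec$acceptor_context)
    eid <- sprintf("S%03d", i)
    s <- build_toy_chb(gspec, entry_id = eid,
                       accession = sprintf("SYN%05d", i))
    m <- perturb_structure(s, spec$noise_sigma, seed = pert_seeds[i])
    nu_name <- switch(spec$acceptor_context,
                      "backbone-O" = "O", "sidechain-O" = "OG",
                      "sidechain-S" = "SG")
    gt_exp <- toy_truth_geometry(s, nu_name)
    gt_mod <- toy_truth_geometry(m, nu_name)
    elem <- if (spec$acceptor_context == "sidechain-S") "S" else "O"
    thr <- params$vdw_radii[[elem]] + params$vdw_radii[["S"]] +
      params$distance_tolerance
    truth[[i]] <- tibble(
      entry_id = eid,
      d_true = gt_exp$d, alpha_true = gt_exp$alpha_min,
      d_perturbed = gt_mod$d, alpha_perturbed = gt_mod$alpha_min,
      ss_perturbed = gt_mod$ss,
      recovered_truth = gt_mod$ss <= params$ssbond_distance_max &&
        gt_mod$d <= thr && gt_mod$alpha_min <= params$alpha_max
    )
    experimental[[i]] <- s
    models[[i]] <- m
  }
  list(experimental = experimental, models = models, truth = bind_rows(truth))
}
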