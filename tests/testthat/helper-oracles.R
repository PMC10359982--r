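# Independent oracles and random-fixture builders shared across test files.
# Everything here is deliberately naive: plain loops, no spatial indexing,
# no reuse of the package's geometry helpers.

o_norm <- function(v) sqrt(sum(v^2))

o_alpha <- function(nu, s, p) {
  v1 <- nu - s
  v2 <- p - s
  180 - acos(max(-1, min(1, sum(v1 * v2) / (o_norm(v1) * o_norm(v2))))) * 180 / pi
}

# Exhaustive O(N^2) chalcogen-bond scan. Returns a set of
# "donor_serial:acceptor_serial" keys for passing contacts.
oracle_detect <- function(s, params = chb_params()) {
  a <- as.data.frame(s$atoms)
  sg <- a[a$resid == "CYS" & a$name == "SG", ]
  # disulphide pairing: repeatedly take the globally closest unused pair
  pairs <- list()
  if (nrow(sg) >= 2) {
    cand <- list()
    for (i in seq_len(nrow(sg) - 1)) {
      for (j in (i + 1):nrow(sg)) {
        dij <- o_norm(c(sg$x[i] - sg$x[j], sg$y[i] - sg$y[j], sg$z[i] - sg$z[j]))
        if (dij <= params$ssbond_distance_max) {
          cand[[length(cand) + 1]] <- c(i, j, dij)
        }
      }
    }
    used <- rep(FALSE, nrow(sg))
    while (length(cand) > 0) {
      dists <- vapply(cand, function(p) p[3], numeric(1))
      k <- which.min(dists)
      i <- cand[[k]][1]; j <- cand[[k]][2]
      if (!used[i] && !used[j]) {
        pairs[[length(pairs) + 1]] <- c(i, j)
        used[i] <- used[j] <- TRUE
      }
      cand[[k]] <- NULL
    }
  }
  keys <- character(0)
  for (pr in pairs) {
    for (ord in list(pr, rev(pr))) {
      don <- sg[ord[1], ]
      par <- sg[ord[2], ]
      s_xyz <- c(don$x, don$y, don$z)
      partners <- list(c(par$x, par$y, par$z))
      cb <- a[a$chain == don$chain & a$resno == don$resno &
                a$icode == don$icode & a$name == "CB", ]
      cb_serial <- integer(0)
      if (nrow(cb) > 0) {
        partners <- c(partners, list(c(cb$x[1], cb$y[1], cb$z[1])))
        cb_serial <- cb$serial[1]
      }
      for (m in seq_len(nrow(a))) {
        at <- a[m, ]
        if (!(at$element %in% params$acceptor_elements)) next
        if (!params$include_waters && at$resid %in% c("HOH", "WAT")) next
        if (at$serial %in% c(don$serial, par$serial, cb_serial)) next
        if (params$exclude_same_residue && at$chain == don$chain &&
              at$resno == don$resno && at$icode == don$icode) next
        nu <- c(at$x, at$y, at$z)
        d <- o_norm(nu - s_xyz)
        thr <- params$vdw_radii[[at$element]] + params$vdw_radii[["S"]] +
          params$distance_tolerance
        alphas <- vapply(partners, function(p) o_alpha(nu, s_xyz, p), numeric(1))
        if (d <= thr && min(alphas) <= params$alpha_max) {
          keys <- c(keys, paste0(don$serial, ":", at$serial))
        }
      }
    }
  }
  sort(keys)
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- o_norm(v)
    if (n > 1e-6) return(v / n)
  }
}

# Random structure with a handful of disulphides, scattered O/S acceptors
# (some deliberately placed inside the detection shell), waters and inert
# carbon atoms. <= 500 atoms.
random_structure <- function(seed) {
  set.seed(seed)
  rows <- list()
  serial <- 0L
  resno <- 0L
  add_atom <- function(name, resid, xyz, element) {
    serial <<- serial + 1L
    rows[[serial]] <<- tibble::tibble(
      serial = serial, name = name, altloc = "", resid = resid,
      chain = "A", resno = resno, icode = "",
      x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = 1, bfactor = 20, element = element
    )
  }
  n_bridges <- sample(2:4, 1)
  sg_positions <- list()
  for (b in seq_len(n_bridges)) {
    center <- stats::runif(3, 0, 25)
    sg1 <- center
    sg2 <- center + 2.05 * rand_unit()
    sg_positions <- c(sg_positions, list(sg1, sg2))
    for (sgx in list(sg1, sg2)) {
      resno <- resno + 1L
      add_atom("CB", "CYS", sgx + 1.81 * rand_unit(), "C")
      add_atom("SG", "CYS", sgx, "S")
    }
  }
  # occasionally a stray third cysteine near a bridge (tie-break exercise)
  if (stats::runif(1) < 0.5) {
    resno <- resno + 1L
    near <- sg_positions[[1]] + stats::runif(1, 2.1, 2.6) * rand_unit()
    add_atom("CB", "CYS", near + 1.81 * rand_unit(), "C")
    add_atom("SG", "CYS", near, "S")
  }
  # acceptors in the shell of each sulfur
  for (sgx in sg_positions) {
    for (k in seq_len(2)) {
      resno <- resno + 1L
      elem <- sample(c("O", "S"), 1)
      name <- if (elem == "O") "O" else "SD"
      resid <- if (elem == "O") "GLY" else "MET"
      add_atom(name, resid, sgx + stats::runif(1, 2.6, 4.2) * rand_unit(), elem)
    }
  }
  # scattered background: acceptors, carbons, waters
  for (k in seq_len(sample(30:80, 1))) {
    resno <- resno + 1L
    xyz <- stats::runif(3, -5, 30)
    pick <- sample(c("O", "C", "W"), 1)
    if (pick == "O") add_atom("O", "GLY", xyz, "O")
    if (pick == "C") add_atom("CA", "GLY", xyz, "C")
    if (pick == "W") add_atom("O", "HOH", xyz, "O")
  }
  chalcogenr::chb_structure(dplyr::bind_rows(rows), entry_id = "RND1")
}

# Haar-ish random rotation matrix.
rand_rotation <- function(seed) {
  set.seed(seed)
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_structure <- function(s, rot, shift) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

chb_keys <- function(tab) {
  if (nrow(tab) == 0) return(character(0))
  sort(paste0(tab$donor_serial, ":", tab$acceptor_serial))
}

expect_quiet <- function(expr) {
  suppressMessages(withCallingHandlers(
    expr, chalcogenr_log = function(c) invokeRestart("muffleMessage")))
}
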