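# Disulphide and chalcogen-bond detection -----------------------------------

# Spatial grid for cutoff queries: buckets points into cubic cells of edge
# `cutoff`; all neighbours within `cutoff` of a query point lie in its 27
# surrounding cells. Purely an accelerator -- results must be identical to an
# all-pairs scan (tested against one).
make_cell_grid <- function(xyz, cutoff) {
  cells <- floor(xyz / cutoff)
  keys <- paste(cells[, 1], cells[, 2], cells[, 3])
  list(cutoff = cutoff, buckets = split(seq_len(nrow(xyz)), keys))
}

grid_candidates <- function(grid, point) {
  base <- floor(point / grid$cutoff)
  keys <- as.vector(outer(
    as.vector(outer(base[1] + (-1:1), base[2] + (-1:1), paste)),
    base[3] + (-1:1), paste))
  unlist(grid$buckets[keys], use.names = FALSE)
}

#' Find disulphide bridges in a structure
#'
#' Unions (a) SSBOND-declared cysteine pairs whose SG--SG distance is within
#' `ssbond_distance_max` and (b) geometrically detected cysteine SG pairs
#' within that cutoff. Route (b) matters for predicted models, whose files
#' carry no SSBOND records. Each SG joins at most one bridge; when a sulfur
#' has several candidates the closest pair wins (candidates are accepted in
#' order of increasing SG--SG distance).
#'
#' @param structure A [chb_structure()] object.
#' @param params A [chb_params()] object (only `ssbond_distance_max` is used).
#' @return A tibble with one row per bridge: `chain_a`, `resno_a`, `icode_a`,
#'   `serial_a`, and the `_b` counterparts, plus `ss_distance` in Angstrom.
#' @export
find_disulphides <- function(structure, params = chb_params()) {
  stopifnot(inherits(structure, "chb_structure"))
  sg <- filter(structure$atoms, .data$resid == "CYS", .data$name == "SG")
  cutoff <- params$ssbond_distance_max
  empty <- tibble(chain_a = character(), resno_a = integer(),
                  icode_a = character(), serial_a = integer(),
                  chain_b = character(), resno_b = integer(),
                  icode_b = character(), serial_b = integer(),
                  ss_distance = numeric())
  if (nrow(sg) < 2) return(empty)

  xyz <- as.matrix(sg[, c("x", "y", "z")])
  pairs <- utils::combn(nrow(sg), 2)
  dvec <- sqrt(rowSums((xyz[pairs[1, ], , drop = FALSE] -
                          xyz[pairs[2, ], , drop = FALSE])^2))
  cand <- tibble(i = pairs[1, ], j = pairs[2, ], dist = dvec)
  cand <- filter(cand, .data$dist <= cutoff)
  if (nrow(cand) == 0) return(empty)

  cand <- arrange(cand, .data$dist)
  used <- logical(nrow(sg))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used[i] && !used[j]) {
      keep[k] <- TRUE
      used[i] <- used[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(
    chain_a = sg$chain[cand$i], resno_a = sg$resno[cand$i],
    icode_a = sg$icode[cand$i], serial_a = sg$serial[cand$i],
    chain_b = sg$chain[cand$j], resno_b = sg$resno[cand$j],
    icode_b = sg$icode[cand$j], serial_b = sg$serial[cand$j],
    ss_distance = cand$dist
  )
}

# One row per disulphide sulfur acting as donor, with its covalent partners:
# its own CB (when present) and the partner SG. Used by detect_chbs() and by
# the model-side rematching in match_chbs().
disulphide_donors <- function(structure, bridges) {
  a <- structure$atoms
  if (nrow(bridges) == 0) {
    return(tibble(chain = character(), resno = integer(), icode = character(),
                  serial = integer(), sx = numeric(), sy = numeric(),
                  sz = numeric(), partner_serial = integer(),
                  partners = list()))
  }
  both <- bind_rows(
    tibble(serial = bridges$serial_a, partner_serial = bridges$serial_b),
    tibble(serial = bridges$serial_b, partner_serial = bridges$serial_a)
  )
  rows <- lapply(seq_len(nrow(both)), function(k) {
    s_at <- a[a$serial == both$serial[k], ][1, ]
    p_at <- a[a$serial == both$partner_serial[k], ][1, ]
    cb <- a[a$chain == s_at$chain & a$resno == s_at$resno &
              a$icode == s_at$icode & a$name == "CB", ]
    partners <- list(sg = c(p_at$x, p_at$y, p_at$z))
    partner_serials <- p_at$serial
    if (nrow(cb) > 0) {
      partners <- c(list(cb = c(cb$x[1], cb$y[1], cb$z[1])), partners)
      partner_serials <- c(cb$serial[1], partner_serials)
    }
    tibble(chain = s_at$chain, resno = s_at$resno, icode = s_at$icode,
           serial = s_at$serial, sx = s_at$x, sy = s_at$y, sz = s_at$z,
           partner_serial = both$partner_serial[k],
           partners = list(partners),
           partner_serials = list(partner_serials))
  })
  bind_rows(rows)
}

empty_chb_table <- function() {
  tibble(
    entry_id = character(),
    donor_chain = character(), donor_resno = integer(), donor_icode = character(),
    donor_serial = integer(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_icode = character(), acceptor_name = character(),
    acceptor_element = character(), acceptor_serial = integer(),
    d = numeric(), alpha_cb = numeric(), alpha_ss = numeric(),
    alpha_min = numeric(), vdw_sum = numeric(), passes = logical()
  )
}

#' Detect chalcogen bonds at disulphide bridges
#'
#' Evaluates every disulphide sulfur (both sulfurs of each bridge act as
#' donors) against every candidate nucleophile -- atoms whose element is in
#' `params$acceptor_elements`. The donor's covalent partners (its CB and the
#' partner SG), atoms of the donor residue itself (when
#' `exclude_same_residue`), and waters (unless `include_waters`) are never
#' acceptors. A candidate is reported when `d <= vdw_sum + tolerance` and
#' `alpha_min <= alpha_max`, both inclusive. Output rows are ordered by donor
#' chain/residue, then acceptor chain/residue/atom name, so runs are
#' deterministic.
#'
#' @param structure A [chb_structure()] object.
#' @param params A [chb_params()] object.
#' @param keep_candidates If `TRUE`, also return near-miss candidates inside
#'   the search radius with `passes = FALSE`. Default `FALSE` (bonds only).
#' @return A tibble of class `chb_table`; see the column list in
#'   `empty_chb_table()` (donor and acceptor identifiers, `d`, per-partner
#'   alphas, `alpha_min`, `vdw_sum`, `passes`).
#' @examples
#' s <- build_toy_chb(toy_geometry_spec(d = 3.0, alpha = 10))
#' detect_chbs(s)
#' @export
detect_chbs <- function(structure, params = chb_params(),
                        keep_candidates = FALSE) {
  stopifnot(inherits(structure, "chb_structure"))
  bridges <- find_disulphides(structure, params)
  donors <- disulphide_donors(structure, bridges)
  out <- empty_chb_table()
  if (nrow(donors) == 0) return(as_chb_table(out))

  a <- structure$atoms
  acc <- a[a$element %in% params$acceptor_elements, , drop = FALSE]
  if (!params$include_waters) acc <- acc[!(acc$resid %in% WATER_NAMES), , drop = FALSE]

  s_radius <- params$vdw_radii[["S"]]
  search_radius <- max(params$vdw_radii[params$acceptor_elements]) +
    s_radius + params$distance_tolerance

  rows <- list()
  if (nrow(acc) > 0) {
    axyz <- as.matrix(acc[, c("x", "y", "z")])
    grid <- make_cell_grid(axyz, search_radius)
    for (k in seq_len(nrow(donors))) {
      don <- donors[k, ]
      s_xyz <- c(don$sx, don$sy, don$sz)
      cand_idx <- grid_candidates(grid, s_xyz)
      if (length(cand_idx) == 0) next
      cand <- acc[cand_idx, , drop = FALSE]
      excl <- cand$serial %in% c(don$serial, don$partner_serials[[1]])
      if (params$exclude_same_residue) {
        excl <- excl | (cand$chain == don$chain & cand$resno == don$resno &
                          cand$icode == don$icode)
      }
      cand <- cand[!excl, , drop = FALSE]
      if (nrow(cand) == 0) next
      partners <- don$partners[[1]]
      for (m in seq_len(nrow(cand))) {
        nu_xyz <- c(cand$x[m], cand$y[m], cand$z[m])
        vdw_sum <- params$vdw_radii[[cand$element[m]]] + s_radius
        thr <- vdw_sum + params$distance_tolerance
        dmn <- vnorm(nu_xyz - s_xyz)
        if (dmn > search_radius) next
        g <- chb_geometry(nu_xyz, s_xyz, partners)
        passes <- (g$d <= thr) && (g$alpha_min <= params$alpha_max)
        if (!passes && !keep_candidates) next
        has_cb <- !is.null(partners$cb)
        rows[[length(rows) + 1]] <- tibble(
          entry_id = structure$metadata$entry_id,
          donor_chain = don$chain, donor_resno = don$resno,
          donor_icode = don$icode, donor_serial = don$serial,
          acceptor_chain = cand$chain[m], acceptor_resno = cand$resno[m],
          acceptor_icode = cand$icode[m], acceptor_name = cand$name[m],
          acceptor_element = cand$element[m], acceptor_serial = cand$serial[m],
          d = g$d,
          alpha_cb = if (has_cb) g$alphas[["cb"]] else NA_real_,
          alpha_ss = g$alphas[["sg"]],
          alpha_min = g$alpha_min, vdw_sum = vdw_sum, passes = passes
        )
      }
    }
  }
  out <- if (length(rows) > 0) bind_rows(rows) else out
  out <- arrange(out, .data$donor_chain, .data$donor_resno, .data$donor_icode,
                 .data$acceptor_chain, .data$acceptor_resno,
                 .data$acceptor_icode, .data$acceptor_name)
  as_chb_table(out)
}

as_chb_table <- function(x) {
  class(x) <- c("chb_table", setdiff(class(x), "chb_table"))
  x
}
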