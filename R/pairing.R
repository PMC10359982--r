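# Experimental/model residue mapping and ChB matching -----------------------

#' Map experimental residues onto a predicted model's numbering
#'
#' Predicted models are single-chain and numbered 1..L in sequence-database
#' coordinates, while deposited entries use author numbering. For each
#' experimental chain carrying a DBREF to the pairing accession, the model
#' residue number is `exp_resno - seq_begin + db_seq_begin`. Residues with
#' insertion codes are excluded (database offsets are undefined across
#' them), and a mapped pair must agree on residue name in both structures;
#' violations land in the `unmapped` attribute with a reason.
#'
#' @param exp Experimental [chb_structure()] with at least one DBREF record.
#' @param model Predicted-model [chb_structure()].
#' @return A tibble of class `chb_residue_map` with columns `chain`,
#'   `exp_resno`, `model_resno`, `resid`; attributes `accession` and
#'   `unmapped` (tibble with `chain`, `exp_resno`, `reason`).
#' @export
build_residue_map <- function(exp, model) {
  stopifnot(inherits(exp, "chb_structure"), inherits(model, "chb_structure"))
  acc <- has_pairable_accession(exp)
  if (!acc$pairable) {
    abort(paste0(exp$metadata$entry_id,
                 ": no sequence-database accession; cannot pair"),
          class = "chalcogenr_unpairable")
  }
  dbrefs <- filter(exp$metadata$dbrefs, .data$accession == acc$accession)

  exp_res <- distinct(exp$atoms, .data$chain, .data$resno, .data$icode,
                      .data$resid)
  model_res <- distinct(model$atoms, .data$resno, .data$resid)
  model_name <- setNames(model_res$resid, model_res$resno)

  mapped <- list()
  unmapped <- list()
  for (i in seq_len(nrow(dbrefs))) {
    db <- dbrefs[i, ]
    res <- filter(exp_res, .data$chain == db$chain,
                  .data$resno >= db$seq_begin, .data$resno <= db$seq_end)
    for (k in seq_len(nrow(res))) {
      r <- res[k, ]
      if (nzchar(r$icode)) {
        unmapped[[length(unmapped) + 1]] <-
          tibble(chain = r$chain, exp_resno = r$resno, reason = "insertion-code")
        next
      }
      m_no <- r$resno - db$seq_begin + db$db_seq_begin
      m_name <- model_name[as.character(m_no)]
      if (is.na(m_name)) {
        unmapped[[length(unmapped) + 1]] <-
          tibble(chain = r$chain, exp_resno = r$resno, reason = "not-in-model")
      } else if (m_name != r$resid) {
        unmapped[[length(unmapped) + 1]] <-
          tibble(chain = r$chain, exp_resno = r$resno, reason = "name-mismatch")
      } else {
        mapped[[length(mapped) + 1]] <-
          tibble(chain = r$chain, exp_resno = r$resno, model_resno = m_no,
                 resid = r$resid)
      }
    }
  }
  out <- if (length(mapped) > 0) bind_rows(mapped) else
    tibble(chain = character(), exp_resno = integer(),
           model_resno = integer(), resid = character())
  un <- if (length(unmapped) > 0) bind_rows(unmapped) else
    tibble(chain = character(), exp_resno = integer(), reason = character())
  if (nrow(un) > 0) {
    inform(paste0(exp$metadata$entry_id, ": ", nrow(un),
                  " residue(s) left unmapped (",
                  paste(unique(un$reason), collapse = ", "), ")"),
           class = "chalcogenr_log")
  }
  attr(out, "accession") <- acc$accession
  attr(out, "unmapped") <- un
  class(out) <- c("chb_residue_map", class(out))
  out
}

map_lookup <- function(map, chain, resno) {
  hit <- map$model_resno[map$chain == chain & map$exp_resno == resno]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

model_atom <- function(model_atoms, resno, name) {
  hit <- model_atoms[model_atoms$resno == resno & model_atoms$name == name, ]
  if (nrow(hit) == 0) NULL else hit[1, ]
}

residue_mean_bfactor <- function(model_atoms, resno) {
  b <- model_atoms$bfactor[model_atoms$resno == resno]
  if (length(b) == 0) NA_real_ else mean(b)
}

#' Locate experimental chalcogen bonds in the paired model
#'
#' For each experimental chalcogen bond, finds the donor SG and the acceptor
#' atom (same atom name) in the model through the residue map and recomputes
#' the bond geometry there, using the model's own covalent partners (CB and
#' the disulphide partner found in the model). A bond is `recovered` when
#' the model geometry passes the same [chb_params()] criteria. When the
#' donor cysteine is not part of any disulphide in the model the bond is
#' reported with `absent_reason = "disulphide-broken"`; unmappable residues
#' or missing atoms yield `"residue-unmapped"` / `"atom-missing"`. Delta
#' values are model minus experimental, and are reported for every bond
#' whose model geometry exists, recovered or not, since near-misses carry
#' the signal of interest. `mean_plddt` averages the model B-factor column
#' (pLDDT for predicted models) over the donor and acceptor residues.
#'
#' @param exp_chbs Output of [detect_chbs()] on the experimental structure.
#' @param exp,model The paired [chb_structure()] objects.
#' @param map Output of [build_residue_map()].
#' @param params The [chb_params()] used for detection.
#' @return A tibble of class `chb_matched` with the experimental geometry
#'   (`exp_d`, `exp_alpha_min`), model geometry (`model_d`,
#'   `model_alpha_min`), `delta_d`, `delta_alpha`, `recovered`,
#'   `mean_plddt` and `absent_reason`.
#' @export
match_chbs <- function(exp_chbs, exp, model, map, params = chb_params()) {
  stopifnot(inherits(exp, "chb_structure"), inherits(model, "chb_structure"))
  model_bridges <- find_disulphides(model, params)
  model_donors <- disulphide_donors(model, model_bridges)
  ma <- model$atoms

  rows <- lapply(seq_len(nrow(exp_chbs)), function(k) {
    b <- exp_chbs[k, ]
    base <- tibble(
      entry_id = b$entry_id,
      donor_chain = b$donor_chain, donor_resno = b$donor_resno,
      acceptor_chain = b$acceptor_chain, acceptor_resno = b$acceptor_resno,
      acceptor_name = b$acceptor_name,
      exp_d = b$d, exp_alpha_min = b$alpha_min,
      model_d = NA_real_, model_alpha_min = NA_real_,
      delta_d = NA_real_, delta_alpha = NA_real_,
      recovered = FALSE, mean_plddt = NA_real_,
      absent_reason = NA_character_
    )
    don_no <- map_lookup(map, b$donor_chain, b$donor_resno)
    acc_no <- map_lookup(map, b$acceptor_chain, b$acceptor_resno)
    if (is.na(don_no) || is.na(acc_no)) {
      base$absent_reason <- "residue-unmapped"
      return(base)
    }
    don_at <- model_atom(ma, don_no, "SG")
    acc_at <- model_atom(ma, acc_no, b$acceptor_name)
    if (is.null(don_at) || is.null(acc_at)) {
      base$absent_reason <- "atom-missing"
      return(base)
    }
    base$mean_plddt <- mean(c(residue_mean_bfactor(ma, don_no),
                              residue_mean_bfactor(ma, acc_no)))
    don_row <- model_donors[model_donors$serial == don_at$serial, ]
    if (nrow(don_row) == 0) {
      base$absent_reason <- "disulphide-broken"
      return(base)
    }
    g <- chb_geometry(c(acc_at$x, acc_at$y, acc_at$z),
                      c(don_at$x, don_at$y, don_at$z),
                      don_row$partners[[1]])
    thr <- vdw_contact_threshold(acc_at$element, "S",
                                 params$distance_tolerance, params$vdw_radii)
    base$model_d <- g$d
    base$model_alpha_min <- g$alpha_min
    base$delta_d <- g$d - b$d
    base$delta_alpha <- g$alpha_min - b$alpha_min
    base$recovered <- (g$d <= thr) && (g$alpha_min <= params$alpha_max)
    base$absent_reason <- "none"
    base
  })
  out <- if (length(rows) > 0) bind_rows(rows) else tibble(
    entry_id = character(), donor_chain = character(), donor_resno = integer(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_name = character(), exp_d = numeric(), exp_alpha_min = numeric(),
    model_d = numeric(), model_alpha_min = numeric(), delta_d = numeric(),
    delta_alpha = numeric(), recovered = logical(), mean_plddt = numeric(),
    absent_reason = character()
  )
  class(out) <- c("chb_matched", setdiff(class(out), "chb_matched"))
  out
}

#' Fraction of experimental chalcogen bonds recovered in the model
#'
#' Recovered bonds divided by all experimental bonds; bonds whose model
#' counterpart is absent for any reason count in the denominator only.
#'
#' @param matched Output of [match_chbs()].
#' @return A fraction in `[0, 1]`.
#' @export
recovery_fraction <- function(matched) {
  if (nrow(matched) == 0) {
    abort("recovery fraction undefined for an empty set of bonds",
          class = "chalcogenr_undefined_fraction")
  }
  mean(matched$recovered)
}

#' Main-chain O...N contact control
#'
#' Enumerates experimental contacts (< `cutoff`) between main-chain oxygen
#' ("O") and nitrogen ("N") atoms where at least one residue participates in
#' a chalcogen bond, then recomputes each distance in the model. Pairs
#' within the same residue or sequence-adjacent on the same chain
#' (|delta seq| <= `adjacency_exclusion`) are excluded, since their O...N
#' separation is fixed by covalent geometry and would deflate the control.
#' The resulting |delta d| distribution is the accuracy yardstick against
#' which chalcogen-bond |delta d| is compared: these contacts are largely
#' main-chain hydrogen bonds in the same structural region.
#'
#' @param exp,model Paired [chb_structure()] objects.
#' @param map Output of [build_residue_map()].
#' @param chb_residues Data frame with columns `chain`, `resno`: the union
#'   of donor and acceptor residues of the experimental bonds.
#' @param cutoff Contact distance cutoff in Angstrom (default 3.5,
#'   exclusive).
#' @param adjacency_exclusion Minimum |sequence separation| on the same
#'   chain (default 1, i.e. exclude i and i+/-1).
#' @return A tibble with one row per contact: the two residues, `exp_d`,
#'   `model_d`, `abs_delta_d`; contacts with unmapped residues are dropped
#'   with a log message.
#' @export
mainchain_contact_control <- function(exp, model, map, chb_residues,
                                      cutoff = 3.5, adjacency_exclusion = 1) {
  chb_residues <- distinct(as_tibble(chb_residues), .data$chain, .data$resno)
  a <- exp$atoms
  o_at <- a[a$name == "O" & a$resid %in% AA_STANDARD & !nzchar(a$icode), ]
  n_at <- a[a$name == "N" & a$resid %in% AA_STANDARD & !nzchar(a$icode), ]
  out <- tibble(o_chain = character(), o_resno = integer(),
                n_chain = character(), n_resno = integer(),
                exp_d = numeric(), model_d = numeric(),
                abs_delta_d = numeric())
  if (nrow(o_at) == 0 || nrow(n_at) == 0) return(out)

  in_chb <- function(chain, resno) {
    any(chb_residues$chain == chain & chb_residues$resno == resno)
  }
  ma <- model$atoms
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(o_at))) {
    for (j in seq_len(nrow(n_at))) {
      oi <- o_at[i, ]; nj <- n_at[j, ]
      same_res <- oi$chain == nj$chain && oi$resno == nj$resno
      adjacent <- oi$chain == nj$chain &&
        abs(oi$resno - nj$resno) <= adjacency_exclusion
      if (same_res || adjacent) next
      if (!(in_chb(oi$chain, oi$resno) || in_chb(nj$chain, nj$resno))) next
      d_exp <- vnorm(c(oi$x - nj$x, oi$y - nj$y, oi$z - nj$z))
      if (d_exp >= cutoff) next
      o_no <- map_lookup(map, oi$chain, oi$resno)
      n_no <- map_lookup(map, nj$chain, nj$resno)
      mo <- if (is.na(o_no)) NULL else model_atom(ma, o_no, "O")
      mn <- if (is.na(n_no)) NULL else model_atom(ma, n_no, "N")
      if (is.null(mo) || is.null(mn)) {
        n_skipped <- n_skipped + 1L
        next
      }
      d_mod <- vnorm(c(mo$x - mn$x, mo$y - mn$y, mo$z - mn$z))
      rows[[length(rows) + 1]] <- tibble(
        o_chain = oi$chain, o_resno = oi$resno,
        n_chain = nj$chain, n_resno = nj$resno,
        exp_d = d_exp, model_d = d_mod, abs_delta_d = abs(d_mod - d_exp))
    }
  }
  if (n_skipped > 0) {
    inform(paste0(exp$metadata$entry_id, ": skipped ", n_skipped,
                  " control contact(s) with unmapped residues"),
           class = "chalcogenr_log")
  }
  if (length(rows) > 0) bind_rows(rows) else out
}

#' Confidence band of a mean pLDDT value
#'
#' Stratifies model confidence the way prediction-quality discussions do:
#' below 50 is low (treat with caution), above 90 is high (side chains
#' expected reliable), and everything between -- including exactly 50 and
#' exactly 90 -- is medium.
#'
#' @param mean_plddt Numeric vector of values in `[0, 100]`.
#' @return Character vector: `"low"`, `"medium"` or `"high"` (`NA` in,
#'   `NA` out).
#' @export
plddt_band <- function(mean_plddt) {
  bad <- !is.na(mean_plddt) & (mean_plddt < 0 | mean_plddt > 100)
  if (any(bad)) {
    abort("pLDDT values must lie in [0, 100]", class = "chalcogenr_domain_error")
  }
  ifelse(is.na(mean_plddt), NA_character_,
         ifelse(mean_plddt < 50, "low",
                ifelse(mean_plddt > 90, "high", "medium")))
}
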