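# Residue mapping, bond matching and the comparison statistics

toy_pair <- function(d = 3.0, alpha = 10, sigma = 0, seed = 1, ...) {
  s <- build_toy_chb(toy_geometry_spec(d = d, alpha = alpha, ...))
  m <- perturb_structure(s, sigma = sigma, seed = seed)
  list(exp = s, model = m)
}

test_that("identical numbering gives the identity residue map", {
  p <- toy_pair()
  map <- build_residue_map(p$exp, p$model)
  expect_equal(map$model_resno, map$exp_resno)
  expect_equal(nrow(attr(map, "unmapped")), 0)
  expect_equal(attr(map, "accession"), "SYNTH001")
})

test_that("numbering offsets follow the DBREF arithmetic", {
  p <- toy_pair()
  # author numbering starts at 12 while the database numbering starts at 3:
  # exp residue 12 must land on model residue 3
  exp <- p$exp
  exp$atoms$resno <- exp$atoms$resno + 10L
  exp$metadata$dbrefs$seq_begin <- 12L
  exp$metadata$dbrefs$seq_end <- 17L
  exp$metadata$dbrefs$db_seq_begin <- 3L
  exp$metadata$dbrefs$db_seq_end <- 8L
  exp$metadata$ssbonds$resno1 <- 12L
  exp$metadata$ssbonds$resno2 <- 13L
  model <- p$model
  model$atoms$resno <- model$atoms$resno + 1L # model numbered 3,4,6,8
  map <- build_residue_map(exp, model)
  expect_equal(map$model_resno, map$exp_resno - 12L + 3L)
  expect_equal(nrow(attr(map, "unmapped")), 0)
})

test_that("residue-name disagreements and insertion codes go to unmapped", {
  p <- toy_pair()
  model <- p$model
  model$atoms$resid[model$atoms$resno == 5] <- "ALA"
  map <- expect_quiet(build_residue_map(p$exp, model))
  un <- attr(map, "unmapped")
  expect_true(5 %in% un$exp_resno)
  expect_equal(un$reason[un$exp_resno == 5], "name-mismatch")

  exp2 <- p$exp
  exp2$atoms$icode[exp2$atoms$resno == 7] <- "A"
  map2 <- expect_quiet(build_residue_map(exp2, p$model))
  un2 <- attr(map2, "unmapped")
  expect_equal(un2$reason[un2$exp_resno == 7], "insertion-code")
})

test_that("an entry without an accession is unpairable", {
  p <- toy_pair()
  exp <- p$exp
  exp$metadata$dbrefs <- exp$metadata$dbrefs[0, ]
  expect_error(build_residue_map(exp, p$model),
               class = "chalcogenr_unpairable")
})

test_that("self-comparison recovers every bond with all deltas exactly zero", {
  p <- toy_pair(sigma = 0)
  cmp <- expect_quiet(compare_structures(p$exp, p$model))
  expect_equal(recovery_fraction(cmp$matched), 1.0)
  expect_identical(cmp$matched$delta_d, 0)
  expect_identical(cmp$matched$delta_alpha, 0)
  expect_identical(cmp$control$abs_delta_d, 0)
})

test_that("a constructed acceptor displacement appears as delta_d = +0.20", {
  p <- toy_pair(d = 3.0, alpha = 10)
  model <- p$model
  # move the acceptor O 0.20 A further along the S -> Nu line (= +x direction
  # scaled by the bond geometry); donor SG sits at the origin
  i <- which(model$atoms$resno == 5 & model$atoms$name == "O")
  nu <- as.numeric(model$atoms[i, c("x", "y", "z")])
  shift <- 0.20 * nu / sqrt(sum(nu^2))
  model$atoms$x[i] <- model$atoms$x[i] + shift[1]
  model$atoms$y[i] <- model$atoms$y[i] + shift[2]
  model$atoms$z[i] <- model$atoms$z[i] + shift[3]
  cmp <- expect_quiet(compare_structures(p$exp, model))
  expect_equal(cmp$matched$delta_d, 0.20, tolerance = 1e-9)
  expect_equal(cmp$matched$delta_alpha, 0, tolerance = 1e-9)
  expect_true(cmp$matched$recovered) # 3.20 A is still inside the threshold
})

test_that("a broken model disulphide is reported as such, not as a miss", {
  p <- toy_pair(d = 3.0, alpha = 10)
  model <- p$model
  # drag the partner SG to 3.0 A from the donor SG
  i <- which(model$atoms$resno == 3 & model$atoms$name == "SG")
  sg2 <- as.numeric(model$atoms[i, c("x", "y", "z")])
  sg2 <- sg2 * 3.0 / sqrt(sum(sg2^2)) # donor SG is at the origin
  model$atoms$x[i] <- sg2[1]
  model$atoms$y[i] <- sg2[2]
  model$atoms$z[i] <- sg2[3]
  cmp <- expect_quiet(compare_structures(p$exp, model))
  expect_equal(cmp$matched$absent_reason, "disulphide-broken")
  expect_false(cmp$matched$recovered)
  expect_true(is.na(cmp$matched$delta_d))
  expect_equal(recovery_fraction(cmp$matched), 0)
})

test_that("swapping experimental and model roles negates every delta", {
  p <- toy_pair(sigma = 0.02, seed = 9)
  fwd <- expect_quiet(compare_structures(p$exp, p$model))
  # give the model the experimental metadata so it can act as reference
  rev_exp <- p$model
  rev_exp$metadata$ssbonds <- p$exp$metadata$ssbonds
  bwd <- expect_quiet(compare_structures(rev_exp, p$exp))
  expect_equal(nrow(fwd$matched), 1)
  expect_equal(nrow(bwd$matched), 1)
  expect_equal(bwd$matched$delta_d, -fwd$matched$delta_d, tolerance = 1e-12)
  expect_equal(bwd$matched$delta_alpha, -fwd$matched$delta_alpha,
               tolerance = 1e-12)
})

test_that("recovery_fraction counts absences in the denominator only", {
  m <- tibble::tibble(recovered = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(recovery_fraction(m), 0.5)
  expect_equal(recovery_fraction(tibble::tibble(recovered = TRUE)), 1.0)
  expect_equal(recovery_fraction(tibble::tibble(recovered = FALSE)), 0.0)
  expect_error(recovery_fraction(tibble::tibble(recovered = logical(0))),
               class = "chalcogenr_undefined_fraction")
})

test_that("main-chain O...N contacts obey the cutoff and adjacency exclusion", {
  p <- toy_pair(sigma = 0)
  map <- build_residue_map(p$exp, p$model)
  chb_res <- tibble::tibble(chain = "A", resno = c(2L, 5L))
  ctl <- mainchain_contact_control(p$exp, p$model, map, chb_res)
  # the toy carries exactly one non-adjacent contact: O(res 2)...N(res 7) at 3.0
  expect_equal(nrow(ctl), 1)
  expect_equal(ctl$o_resno, 2)
  expect_equal(ctl$n_resno, 7)
  expect_equal(ctl$exp_d, 3.0, tolerance = 1e-9)
  expect_equal(ctl$abs_delta_d, 0)
  # a 3.6 A contact is not enumerated (cutoff is strict)
  exp2 <- p$exp
  i <- which(exp2$atoms$resno == 7 & exp2$atoms$name == "N")
  o1 <- as.numeric(exp2$atoms[exp2$atoms$resno == 2 & exp2$atoms$name == "O",
                              c("x", "y", "z")])
  n7 <- as.numeric(exp2$atoms[i, c("x", "y", "z")])
  stretched <- o1 + (n7 - o1) * 3.6 / 3.0
  exp2$atoms$x[i] <- stretched[1]
  exp2$atoms$y[i] <- stretched[2]
  exp2$atoms$z[i] <- stretched[3]
  ctl2 <- mainchain_contact_control(exp2, p$model, map, chb_res)
  expect_equal(nrow(ctl2), 0)
})

test_that("control |delta-d| equals a direct recomputation on perturbed pairs", {
  p <- toy_pair(sigma = 0.15, seed = 21)
  map <- build_residue_map(p$exp, p$model)
  chb_res <- tibble::tibble(chain = "A", resno = c(2L, 5L))
  ctl <- mainchain_contact_control(p$exp, p$model, map, chb_res)
  get_xyz <- function(s, resno, name) {
    as.numeric(s$atoms[s$atoms$resno == resno & s$atoms$name == name,
                       c("x", "y", "z")])
  }
  d_exp <- o_norm(get_xyz(p$exp, 2, "O") - get_xyz(p$exp, 7, "N"))
  d_mod <- o_norm(get_xyz(p$model, 2, "O") - get_xyz(p$model, 7, "N"))
  expect_equal(ctl$abs_delta_d, abs(d_mod - d_exp), tolerance = 1e-12)
})

test_that("pLDDT bands use strict <50 / >90 boundaries with inclusive medium", {
  expect_equal(plddt_band(95), "high")
  expect_equal(plddt_band(45), "low")
  expect_equal(plddt_band(c(90, 50)), c("medium", "medium"))
  expect_equal(plddt_band(c(49.999, 90.001)), c("low", "high"))
  expect_error(plddt_band(120), class = "chalcogenr_domain_error")
  expect_error(plddt_band(-5), class = "chalcogenr_domain_error")
})

test_that("matched bonds carry the model's mean residue pLDDT", {
  p <- toy_pair(sigma = 0.05, seed = 4)
  cmp <- expect_quiet(compare_structures(p$exp, p$model))
  expect_equal(cmp$matched$mean_plddt, 95) # constant pLDDT by construction
  g <- glance(cmp)
  expect_equal(g$n_plddt_high, 1)
  expect_equal(g$n_plddt_low + g$n_plddt_medium, 0)
})
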