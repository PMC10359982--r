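# Curation rules, accession lookup and redundancy reduction

toy_with_metadata <- function(resolution = 1.40, temperature = 100,
                              method = "X-RAY DIFFRACTION", n_models = 1L,
                              hetero_n = 0L) {
  s <- build_toy_chb(toy_geometry_spec(d = 3.0, alpha = 10))
  s$metadata$resolution <- resolution
  s$metadata$temperature <- temperature
  s$metadata$method <- method
  s$metadata$n_models <- n_models
  if (hetero_n > 0) {
    extra <- s$atoms[rep(1, hetero_n), ]
    extra$serial <- max(s$atoms$serial) + seq_len(hetero_n)
    extra$resid <- "LIG"
    extra$resno <- 90L + seq_len(hetero_n)
    extra$x <- extra$x + 30 + seq_len(hetero_n)
    s$atoms <- dplyr::bind_rows(s$atoms, extra)
  }
  s
}

test_that("the selection rules accept and reject metadata fixtures as specified", {
  pass <- apply_curation(toy_with_metadata())
  expect_true(pass$passed)
  expect_length(pass$failed_rules[[1]], 0)

  v <- apply_curation(toy_with_metadata(resolution = 1.60))
  expect_false(v$passed)
  expect_true("resolution" %in% v$failed_rules[[1]])

  v <- apply_curation(toy_with_metadata(temperature = 293))
  expect_true("temperature" %in% v$failed_rules[[1]])

  # 20 protein atoms + 2 hetero -> 9.1% > 5%
  v <- apply_curation(toy_with_metadata(hetero_n = 2L))
  expect_true("nonprotein_fraction" %in% v$failed_rules[[1]])

  v <- apply_curation(toy_with_metadata(n_models = 2L))
  expect_true("single_model" %in% v$failed_rules[[1]])

  v <- apply_curation(toy_with_metadata(method = "SOLUTION NMR"))
  expect_true("xray" %in% v$failed_rules[[1]])
})

test_that("resolution and temperature bounds are inclusive", {
  expect_true(apply_curation(toy_with_metadata(resolution = 1.5))$passed)
  expect_true(apply_curation(toy_with_metadata(temperature = 90))$passed)
  expect_true(apply_curation(toy_with_metadata(temperature = 110))$passed)
  expect_false(apply_curation(toy_with_metadata(temperature = 110.5))$passed)
})

test_that("every failed rule is reported, not just the first", {
  v <- apply_curation(toy_with_metadata(resolution = 2.0, temperature = 293,
                                        method = "ELECTRON MICROSCOPY"))
  expect_setequal(v$failed_rules[[1]], c("xray", "resolution", "temperature"))
})

test_that("missing metadata fails the corresponding rule conservatively", {
  v <- apply_curation(toy_with_metadata(resolution = NA_real_,
                                        temperature = NA_real_))
  expect_true(all(c("resolution", "temperature") %in% v$failed_rules[[1]]))
})

test_that("pairable accessions are found and their absence reported", {
  s <- build_toy_chb(toy_geometry_spec(d = 3.0, alpha = 10))
  acc <- has_pairable_accession(s)
  expect_true(acc$pairable)
  expect_equal(acc$accession, "SYNTH001")

  s$metadata$dbrefs <- s$metadata$dbrefs[0, ]
  acc <- has_pairable_accession(s)
  expect_false(acc$pairable)
  expect_true(is.na(acc$accession))

  # two chains referencing the same accession deduplicate to it
  s2 <- build_toy_chb(toy_geometry_spec(d = 3.0, alpha = 10))
  s2$metadata$dbrefs <- dplyr::bind_rows(s2$metadata$dbrefs, s2$metadata$dbrefs)
  s2$metadata$dbrefs$chain <- c("A", "B")
  expect_equal(has_pairable_accession(s2)$accession, "SYNTH001")
})

test_that("redundancy stub rejects near-identical sequences and keeps distinct ones", {
  same <- tibble::tibble(entry_id = c("E1", "E2"),
                         sequence = c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_length(expect_quiet(redundancy_filter(same, 40)), 1)

  diff <- tibble::tibble(entry_id = c("E1", "E2"),
                         sequence = c("AAAAAAAAAA", "WWWWWWWWWW"))
  expect_length(expect_quiet(redundancy_filter(diff, 40)), 2)

  trio <- tibble::tibble(
    entry_id = c("E1", "E2", "E3"),
    sequence = c(strrep("A", 20), strrep("A", 20), "WYHKRDEQNC1WYHKRDEQN")
  )
  trio$sequence[3] <- "WYHKRDEQNCMWYHKRDEQN"
  kept <- expect_quiet(redundancy_filter(trio, 40))
  expect_length(kept, 2)
  expect_true("E3" %in% kept)
})

test_that("redundancy filtering is deterministic and idempotent", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  entries <- tibble::tibble(
    entry_id = paste0("E", 1:8),
    sequence = vapply(1:8, function(i) {
      paste(sample(aas, sample(15:25, 1), replace = TRUE), collapse = "")
    }, character(1))
  )
  # duplicate a couple of sequences so clusters exist
  entries$sequence[5] <- entries$sequence[1]
  entries$sequence[6] <- entries$sequence[2]
  kept1 <- expect_quiet(redundancy_filter(entries, 40))
  kept2 <- expect_quiet(redundancy_filter(entries, 40))
  expect_identical(kept1, kept2)
  again <- expect_quiet(
    redundancy_filter(entries[entries$entry_id %in% kept1, ], 40))
  expect_identical(again, kept1)
})

test_that("a configured but unrunnable external clusterer is an error", {
  entries <- tibble::tibble(entry_id = "E1", sequence = "ACDEFG")
  expect_error(redundancy_filter(entries, 40, cdhit_path = "/no/such/cd-hit"),
               class = "chalcogenr_tool_error")
})
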