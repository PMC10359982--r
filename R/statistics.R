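# Survey-level statistics ----------------------------------------------------

#' Mean and standard error of the mean
#'
#' Arithmetic mean and sample-standard-deviation / sqrt(n) (n - 1
#' denominator). A single value has, by convention, a standard error of 0;
#' a log message notes when that convention fires. All "+/-" figures in this
#' package's reports are standard errors of the mean, labelled as such.
#'
#' @param values Non-empty numeric vector.
#' @return A list with `mean`, `stderr`, `n`.
#' @export
mean_and_stderr <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) {
    abort("mean undefined for an empty vector", class = "chalcogenr_domain_error")
  }
  if (length(values) == 1) {
    inform("single observation: standard error set to 0 by convention",
           class = "chalcogenr_log")
    return(list(mean = values, stderr = 0, n = 1L))
  }
  list(mean = mean(values), stderr = sd(values) / sqrt(length(values)),
       n = length(values))
}

# One-row summary of a matched set + control contacts.
comparison_summary_row <- function(entry_id, matched, control) {
  has_model <- !is.na(matched$delta_d)
  dd <- abs(matched$delta_d[has_model])
  da <- abs(matched$delta_alpha[has_model])
  bands <- plddt_band(matched$mean_plddt[!is.na(matched$mean_plddt)])
  ms <- function(v) {
    if (length(v) == 0) list(mean = NA_real_, stderr = NA_real_, n = 0L)
    else suppressMessages(mean_and_stderr(v))
  }
  sdd <- ms(dd); sda <- ms(da); sc <- ms(control$abs_delta_d)
  tibble(
    entry_id = entry_id,
    n_exp_chbs = nrow(matched),
    n_recovered = sum(matched$recovered),
    recovery_fraction = if (nrow(matched) > 0) mean(matched$recovered) else NA_real_,
    mean_abs_delta_d = sdd$mean, se_abs_delta_d = sdd$stderr,
    mean_abs_delta_alpha = sda$mean, se_abs_delta_alpha = sda$stderr,
    n_control_contacts = nrow(control),
    control_mean_abs_delta_d = sc$mean, control_se_abs_delta_d = sc$stderr,
    n_plddt_low = sum(bands == "low"),
    n_plddt_medium = sum(bands == "medium"),
    n_plddt_high = sum(bands == "high")
  )
}

#' Compare an experimental structure with its predicted model
#'
#' Runs the full per-pair pipeline: chalcogen-bond detection on the
#' experimental structure, residue mapping through the sequence-database
#' accession, geometric rematching of every bond in the model, and the
#' main-chain O...N contact control over the residues involved in the
#' bonds.
#'
#' @param exp Experimental [chb_structure()].
#' @param model Predicted-model [chb_structure()].
#' @param params A [chb_params()] object.
#' @param control_cutoff Contact cutoff for the main-chain control,
#'   Angstrom.
#' @return An object of class `chb_comparison`: a list with `entry_id`,
#'   `matched` (per-bond tibble), `control` (per-contact tibble), `map`,
#'   and `params`. Use [generics::tidy()] for the per-bond table and
#'   [generics::glance()] for the one-row summary.
#' @examples
#' s <- build_toy_chb(toy_geometry_spec(d = 3.0, alpha = 10))
#' m <- perturb_structure(s, sigma = 0.05, seed = 1)
#' cmp <- compare_structures(s, m)
#' glance(cmp)
#' @export
compare_structures <- function(exp, model, params = chb_params(),
                               control_cutoff = 3.5) {
  chbs <- detect_chbs(exp, params)
  map <- build_residue_map(exp, model)
  matched <- match_chbs(chbs, exp, model, map, params)
  chb_res <- distinct(bind_rows(
    tibble(chain = chbs$donor_chain, resno = chbs$donor_resno),
    tibble(chain = chbs$acceptor_chain, resno = chbs$acceptor_resno)
  ))
  control <- mainchain_contact_control(exp, model, map, chb_res,
                                       cutoff = control_cutoff)
  structure(
    list(entry_id = exp$metadata$entry_id, matched = matched,
         control = control, map = map, params = params),
    class = "chb_comparison"
  )
}

#' @export
print.chb_comparison <- function(x, ...) {
  g <- glance(x)
  cat("<chb_comparison> ", x$entry_id, "\n", sep = "")
  cat("  ", g$n_recovered, "/", g$n_exp_chbs, " chalcogen bonds recovered\n",
      sep = "")
  if (!is.na(g$mean_abs_delta_d)) {
    cat(sprintf("  mean |delta-d| = %.3f +/- %.3f A (SEM), mean |delta-alpha| = %.2f +/- %.2f deg\n",
                g$mean_abs_delta_d, g$se_abs_delta_d,
                g$mean_abs_delta_alpha, g$se_abs_delta_alpha))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_structures
#' @param x A `chb_comparison` object.
#' @param ... Unused.
#' @method tidy chb_comparison
#' @export
tidy.chb_comparison <- function(x, ...) x$matched

#' @rdname compare_structures
#' @method glance chb_comparison
#' @export
glance.chb_comparison <- function(x, ...) {
  comparison_summary_row(x$entry_id, x$matched, x$control)
}

#' Pool per-pair comparisons into a survey report
#'
#' Pooled statistics are computed over the concatenated per-bond and
#' per-contact values (not over per-entry means), so counts stay additive:
#' the pooled recovery fraction is total recovered / total experimental
#' bonds. Per-entry rows are also kept, so either convention can be read
#' off. The report embeds the exact detection parameters used.
#'
#' @param comparisons A list of `chb_comparison` objects (see
#'   [compare_structures()]).
#' @return An object of class `chb_survey`: list with `per_entry`
#'   (one summary row per pair), `matched` (all bonds, concatenated),
#'   `control` (all control contacts), `pooled` (one-row summary) and
#'   `params`. `tidy()` returns the per-entry rows; `glance()` the pooled
#'   row.
#' @export
pool_comparisons <- function(comparisons) {
  stopifnot(length(comparisons) >= 1,
            all(vapply(comparisons, inherits, logical(1), "chb_comparison")))
  per_entry <- bind_rows(lapply(comparisons, glance))
  matched <- bind_rows(lapply(comparisons, function(x) x$matched))
  control <- bind_rows(lapply(comparisons, function(x) x$control))
  pooled <- comparison_summary_row("pooled", matched, control)
  structure(
    list(per_entry = per_entry, matched = matched, control = control,
         pooled = pooled, params = comparisons[[1]]$params),
    class = "chb_survey"
  )
}

#' @export
print.chb_survey <- function(x, ...) {
  p <- x$pooled
  cat("<chb_survey> ", nrow(x$per_entry), " structure pair(s)\n", sep = "")
  cat(sprintf("  recovery: %d/%d (%.1f%%)\n", p$n_recovered, p$n_exp_chbs,
              100 * p$recovery_fraction))
  if (!is.na(p$mean_abs_delta_d)) {
    cat(sprintf("  mean |delta-d|     = %.3f +/- %.3f A (SEM)\n",
                p$mean_abs_delta_d, p$se_abs_delta_d))
    cat(sprintf("  mean |delta-alpha| = %.2f +/- %.2f deg (SEM)\n",
                p$mean_abs_delta_alpha, p$se_abs_delta_alpha))
  }
  if (p$n_control_contacts > 0) {
    cat(sprintf("  control |delta-d|  = %.3f +/- %.3f A (SEM, %d contacts)\n",
                p$control_mean_abs_delta_d, p$control_se_abs_delta_d,
                p$n_control_contacts))
  }
  cat(sprintf("  pLDDT bands: low %d / medium %d / high %d\n",
              p$n_plddt_low, p$n_plddt_medium, p$n_plddt_high))
  invisible(x)
}

#' @rdname pool_comparisons
#' @param x A `chb_survey` object.
#' @param ... Unused.
#' @method tidy chb_survey
#' @export
tidy.chb_survey <- function(x, ...) x$per_entry

#' @rdname pool_comparisons
#' @method glance chb_survey
#' @export
glance.chb_survey <- function(x, ...) x$pooled

#' Write survey report files
#'
#' Writes the per-bond table (TSV, d at 3 decimals and angles at 2), the
#' per-entry summary (CSV) and the pooled summary (CSV) next to each other.
#'
#' @param survey A `chb_survey` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_survey_report <- function(survey, dir, prefix = "chb_survey") {
  stopifnot(inherits(survey, "chb_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- survey$matched
  for (col in c("exp_d", "model_d", "delta_d")) {
    fmt[[col]] <- sprintf("%.3f", fmt[[col]])
  }
  for (col in c("exp_alpha_min", "model_alpha_min", "delta_alpha")) {
    fmt[[col]] <- sprintf("%.2f", fmt[[col]])
  }
  files <- c(
    matched = file.path(dir, paste0(prefix, "_bonds.tsv")),
    per_entry = file.path(dir, paste0(prefix, "_per_entry.csv")),
    pooled = file.path(dir, paste0(prefix, "_pooled.csv"))
  )
  utils::write.table(fmt, files["matched"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(tidy(survey), files["per_entry"], row.names = FALSE)
  utils::write.csv(glance(survey), files["pooled"], row.names = FALSE)
  invisible(files)
}
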