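#' @title Regioselectivity ratios and prediction scoring
#' @name selectivity
#' @description Convert per-site activation energies into Boltzmann-
#'   weighted regioisomeric ratios (kinetic control), rank sites, and
#'   score predictions against experimental site labels.
NULL

#' Boltzmann regioisomeric ratios from activation energies
#'
#' Under kinetic control the fraction of product formed at site class i is
#' \deqn{r_i = 100 \, g_i e^{-E_i/RT} / \sum_j g_j e^{-E_j/RT}}
#' with \eqn{g_i} the class degeneracy (number of symmetry-equivalent
#' sites) and \eqn{E_i} the activation energy in kcal/mol. The sum is
#' evaluated after subtracting the minimum energy (max-shift trick) so
#' large barriers cannot underflow the ratio of the others. Classes with
#' missing (failed) energies are excluded and reported via the
#' `"failed_classes"` attribute.
#'
#' @param energies numeric vector of per-class activation energies
#'   (kcal/mol); `NA` marks a failed class.
#' @param degeneracies per-class site counts (same length; default all 1).
#' @param temperature temperature in K (default 298.15).
#' @return Numeric vector of ratio percents (sums to 100 over the
#'   non-failed classes), aligned with `energies`; failed classes get
#'   `NA`.
#' @examples
#' boltzmann_ratios(c(0, 0))                   # 50 / 50
#' rt_ln2 <- regiots_constants()$r_kcal_mol_k * 298.15 * log(2)
#' boltzmann_ratios(c(0, rt_ln2))              # 66.67 / 33.33
#' @export
boltzmann_ratios <- function(energies, degeneracies = rep(1, length(energies)),
                             temperature = 298.15) {
  stopifnot(length(energies) == length(degeneracies), temperature > 0)
  ok <- !is.na(energies)
  if (!any(ok)) stop("empty-report error: no converged activation energies")
  out <- rep(NA_real_, length(energies))
  e <- energies[ok]
  g <- degeneracies[ok]
  shifted <- -(e - min(e)) / (R_KCAL * temperature)
  w <- g * exp(shifted)
  out[ok] <- 100 * w / sum(w)
  if (any(!ok)) attr(out, "failed_classes") <- which(!ok)
  out
}

#' Assemble a selectivity report for one compound
#'
#' Groups sites by symmetry class, takes one activation energy per class
#' (classes are redundant by construction: symmetry-equivalent sites share
#' a barrier), Boltzmann-weights the classes, and distributes each class
#' ratio equally over its member sites so the per-site ratios sum to 100.
#'
#' @param compound_id compound label.
#' @param radical_name radical label.
#' @param sites [enumerate_sites()] output.
#' @param ts_results list of `TSResult`, one per computed site (at least
#'   one per symmetry class).
#' @param temperature temperature in K.
#' @param config see [regiots_config()].
#' @return A `SelectivityReport`: data.frame `sites` with columns
#'   `site_id`, `atom_index`, `symmetry_class`, `activation_energy`,
#'   `degeneracy`, `ratio_percent`, sorted by descending ratio;
#'   `predicted_major` (site_id); `temperature`; `failures` (site_ids of
#'   classes with no converged TS); `tie` flag.
#' @export
selectivity_report <- function(compound_id, radical_name, sites, ts_results,
                               temperature = NULL, config = regiots_config()) {
  stopifnot(inherits(sites, "data.frame"))
  temperature <- temperature %||% config$temperature_k
  class_energy <- new.env(parent = emptyenv())
  for (res in ts_results) {
    if (!inherits(res, "TSResult")) stop("ts_results must contain TSResult objects")
    cls <- as.character(res$site$symmetry_class)
    if (identical(res$status, "true_ts") && !is.na(res$activation_energy)) {
      prev <- if (exists(cls, class_energy)) get(cls, class_energy) else NA_real_
      if (is.na(prev)) assign(cls, res$activation_energy, class_energy)
    } else if (!exists(cls, class_energy)) {
      assign(cls, NA_real_, class_energy)
    }
  }
  cls_lab <- as.character(sites$symmetry_class)
  e_site <- vapply(cls_lab, function(cl) {
    if (exists(cl, class_energy)) get(cl, class_energy) else NA_real_
  }, 0)
  deg <- as.integer(table(cls_lab)[cls_lab])

  classes <- unique(cls_lab)
  e_class <- e_site[match(classes, cls_lab)]
  g_class <- as.integer(table(cls_lab)[classes])
  ratios_class <- boltzmann_ratios(e_class, g_class, temperature)
  ratio_site <- ratios_class[match(cls_lab, classes)] / deg

  df <- data.frame(site_id = sites$site_id, atom_index = sites$atom_index,
                   symmetry_class = sites$symmetry_class,
                   activation_energy = unname(e_site), degeneracy = deg,
                   ratio_percent = unname(ratio_site))
  failures <- df$site_id[is.na(df$ratio_percent)]
  dfc <- df[!is.na(df$ratio_percent), , drop = FALSE]
  dfc <- dfc[order(-dfc$ratio_percent, dfc$site_id), , drop = FALSE]
  best <- dfc$ratio_percent[1]
  top <- abs(dfc$ratio_percent - best) < 1e-12
  # sites of one symmetry class legitimately share a ratio; flag a tie only
  # when distinct classes are exactly level
  tie <- length(unique(dfc$symmetry_class[top])) > 1
  if (tie) message("tie for predicted major site in ", compound_id,
                   "; breaking by lowest site_id")
  ordered <- rbind(dfc, df[is.na(df$ratio_percent), , drop = FALSE])
  rownames(ordered) <- NULL
  structure(list(
    compound_id = compound_id, radical_name = radical_name,
    sites = ordered, predicted_major = dfc$site_id[1],
    temperature = temperature, failures = failures, tie = tie
  ), class = "SelectivityReport")
}

#' Predicted major site of a selectivity report
#'
#' Returns the site with maximal ratio; exact ties are broken by lowest
#' `site_id` (flagged in the report). The full descending-ratio ranking is
#' preserved in `report$sites`, so "next most favourable" sites can be
#' read off directly.
#'
#' @param report a `SelectivityReport`.
#' @return The predicted major `site_id`.
#' @export
predict_major <- function(report) {
  stopifnot(inherits(report, "SelectivityReport"))
  report$predicted_major
}

#' @export
print.SelectivityReport <- function(x, ...) {
  cat("<SelectivityReport> ", x$compound_id, " + ", x$radical_name,
      " @ ", x$temperature, " K\n", sep = "")
  df <- x$sites
  df$activation_energy <- round(df$activation_energy, 2)
  df$ratio_percent <- round(df$ratio_percent, 1)
  print(df, row.names = FALSE)
  cat("predicted major site: ", x$predicted_major,
      if (x$tie) " (tie, lowest id)" else "", "\n", sep = "")
  if (length(x$failures)) cat("failed sites: ", paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}

#' Score predictions against experimental site labels
#'
#' A site is *predicted reactive* when it is the predicted major site or
#' its ratio is at least `reactive_ratio_percent` (so strong secondary
#' sites count as predicted). Each labelled site then scores correct when
#' the binary prediction agrees with its experimental 0/1 label; the tally
#' aggregates over all sites of all labelled compounds.
#'
#' @param reports list of `SelectivityReport`s.
#' @param labels data.frame with columns `compound_id`, `site_id`,
#'   `observed` (0/1), covering every site of each labelled compound.
#' @param config supplies `reactive_ratio_percent` (default 25).
#' @return An `AccuracyTally`: `n_sites_total`, `n_sites_correct`,
#'   `accuracy_percent` (= 100 * correct / total).
#' @export
score_accuracy <- function(reports, labels, config = regiots_config()) {
  stopifnot(is.data.frame(labels),
            all(c("compound_id", "site_id", "observed") %in% names(labels)))
  by_id <- stats::setNames(reports, vapply(reports, `[[`, "", "compound_id"))
  total <- 0L
  correct <- 0L
  for (cid in unique(labels$compound_id)) {
    rep_i <- by_id[[cid]]
    if (is.null(rep_i)) stop("data error: no report for labelled compound ", cid)
    lab <- labels[labels$compound_id == cid, , drop = FALSE]
    if (!setequal(lab$site_id, rep_i$sites$site_id)) {
      stop("data error: site set mismatch for compound ", cid)
    }
    thr <- config$reactive_ratio_percent
    pred_reactive <- rep_i$sites$site_id[
      !is.na(rep_i$sites$ratio_percent) &
        (rep_i$sites$ratio_percent >= thr |
           rep_i$sites$site_id == rep_i$predicted_major)]
    agree <- (lab$site_id %in% pred_reactive) == (lab$observed == 1)
    total <- total + nrow(lab)
    correct <- correct + sum(agree)
  }
  structure(list(n_sites_total = total, n_sites_correct = correct,
                 accuracy_percent = 100 * correct / total),
            class = "AccuracyTally")
}

#' @export
print.AccuracyTally <- function(x, ...) {
  cat(sprintf("<AccuracyTally> %d/%d sites correct = %.1f%%\n",
              x$n_sites_correct, x$n_sites_total, x$accuracy_percent))
  invisible(x)
}
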