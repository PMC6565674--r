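# Dose-response evaluation of mono- and duotherapy conditions: per-condition
# efficacy (from LFP seizure counts) and side-effect scores, and the
# polytherapy-vs-monotherapy comparisons.

#' A treatment condition on the dose grid
#'
#' @param compounds character vector of 1 or 2 compound ids.
#' @param doses numeric fractions of the screening concentration, one per
#'   compound (the semi-log grid is `c(0.1, 0.3, 1.0)`).
#' @return object of class `treatment_condition` with a canonical `label`.
#' @export
treatment_condition <- function(compounds, doses) {
  stopifnot(length(compounds) >= 1, length(compounds) <= 2,
            length(doses) == length(compounds), all(doses > 0))
  o <- order(compounds)
  compounds <- compounds[o]; doses <- doses[o]
  structure(list(compounds = compounds, doses = doses,
                 label = paste(sprintf("%s@%g", compounds, doses),
                               collapse = "+")),
            class = "treatment_condition")
}

#' Evaluate one treatment condition
#'
#' Efficacy: mean and SD of per-larva efficacy scores from baseline/post
#' LFP pairs (run through [detect_seizures()] when traces are supplied,
#' or taken directly as frequencies). Side effect: RMS behavioral
#' divergence of the treated group from the untreated baseline group.
#'
#' @param cond a `treatment_condition`.
#' @param lfp_pairs list, one element per larva, each a list with `baseline`
#'   and `post` (each an `lfp_trace`, `seizure_calls`, or bare frequency).
#' @param behavior treated-group feature matrix (larvae x 6), or NULL.
#' @param behavior_baseline untreated-group feature matrix.
#' @param detector a `seizure_classifier`, required when traces are given.
#' @return data.frame row with condition label, doses, efficacy (mean, sd),
#'   side effect (score, sd) and group sizes; per-larva efficacy scores in
#'   attribute `per_larva_efficacy`.
#' @export
evaluate_condition <- function(cond, lfp_pairs, behavior = NULL,
                               behavior_baseline = NULL, detector = NULL) {
  freq_of <- function(x) {
    if (inherits(x, "seizure_calls")) return(x$frequency)
    if (inherits(x, "lfp_trace")) {
      if (is.null(detector)) stop_fc("detector required for raw LFP traces")
      return(detect_seizures(x, detector)$frequency)
    }
    as.numeric(x)
  }
  if (!length(lfp_pairs)) stop_fc("no LFP recordings for condition %s", cond$label)
  eff <- vapply(lfp_pairs, function(p) {
    if (is.null(p$baseline) || is.null(p$post))
      stop_fc("missing baseline or post recording in condition %s", cond$label)
    efficacy_score(freq_of(p$baseline), freq_of(p$post))$score
  }, numeric(1))
  if (length(eff) < 5)
    warning(sprintf("condition %s: only %d larvae for efficacy (expected >= 5)",
                    cond$label, length(eff)))
  se <- NULL
  if (!is.null(behavior)) {
    if (is.null(behavior_baseline))
      stop_fc("behavior_baseline required with behavior group")
    if (nrow(behavior) < 10)
      warning(sprintf("condition %s: only %d larvae for side effect (expected >= 10)",
                      cond$label, nrow(behavior)))
    se <- side_effect_score(behavior, behavior_baseline)
  }
  out <- data.frame(condition = cond$label,
                    compounds = paste(cond$compounds, collapse = "+"),
                    doses = paste(cond$doses, collapse = "+"),
                    n_arity = length(cond$compounds),
                    efficacy = mean(eff), efficacy_sd = stats::sd(eff),
                    side_effect = if (is.null(se)) NA_real_ else se$x_combined,
                    side_effect_sd = if (is.null(se)) NA_real_ else se$sd,
                    n_efficacy = length(eff),
                    n_behavior = if (is.null(behavior)) 0L else nrow(behavior))
  attr(out, "per_larva_efficacy") <- eff
  out
}

#' Assemble the dose-response table
#'
#' @param rows list of [evaluate_condition()] results.
#' @param grid optional expected condition labels; an error is raised if any
#'   is absent or duplicated.
#' @return data.frame with one row per condition; per-larva efficacy scores
#'   kept in attribute `per_larva`.
#' @export
dose_response_table <- function(rows, grid = NULL) {
  tab <- do.call(rbind, rows)
  per <- lapply(rows, attr, "per_larva_efficacy")
  names(per) <- tab$condition
  if (anyDuplicated(tab$condition))
    stop_fc("duplicated condition rows: %s",
            paste(unique(tab$condition[duplicated(tab$condition)]), collapse = ", "))
  if (!is.null(grid)) {
    miss <- setdiff(grid, tab$condition)
    if (length(miss))
      stop_fc("dose grid conditions missing from table: %s",
              paste(miss, collapse = ", "))
  }
  attr(tab, "per_larva") <- per
  tab
}

#' Enumerate the mono- and duotherapy dose grid
#'
#' All single compounds at each dose plus all compound pairs over the dose
#' grid (`doses^2` combinations per pair).
#'
#' @param compounds character vector of compound ids.
#' @param doses dose fractions (default the semi-log grid `c(0.1, 0.3, 1)`).
#' @return list of `treatment_condition`s.
#' @export
condition_grid <- function(compounds, doses = c(0.1, 0.3, 1)) {
  out <- list()
  for (c1 in compounds) for (d in doses)
    out[[length(out) + 1L]] <- treatment_condition(c1, d)
  if (length(compounds) > 1) {
    prs <- utils::combn(sort(compounds), 2L)
    for (p in seq_len(ncol(prs))) for (d1 in doses) for (d2 in doses)
      out[[length(out) + 1L]] <- treatment_condition(prs[, p], c(d1, d2))
  }
  out
}

#' Compare a duotherapy against its component monotherapies
#'
#' Unpaired two-tailed t-tests of the per-larva efficacy scores of the
#' combination against each same-dose monotherapy.
#'
#' @param table a [dose_response_table()] result.
#' @param combo condition label of the combination.
#' @param components condition labels of the two monotherapies.
#' @return named numeric vector of p-values.
#' @export
compare_poly_vs_mono <- function(table, combo, components) {
  per <- attr(table, "per_larva")
  if (is.null(per)) stop_fc("table lacks per-larva efficacy scores")
  ec <- per[[combo]]
  if (is.null(ec)) stop_fc("condition %s not in table", combo)
  vapply(components, function(m) {
    em <- per[[m]]
    if (is.null(em)) stop_fc("condition %s not in table", m)
    if (length(ec) < 2 || length(em) < 2)
      stop_fc("need >= 2 larvae per group for the t-test")
    if (stats::sd(ec) == 0 && stats::sd(em) == 0)
      return(if (isTRUE(all.equal(mean(ec), mean(em)))) 1 else 0)
    stats::t.test(ec, em, var.equal = FALSE)$p.value
  }, numeric(1))
}
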