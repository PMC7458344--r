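#' Stratification rule for high/low infiltration
#'
#' @param kind `"median"` or `"percentile"`.
#' @param q Percentile in (0, 100); required when `kind = "percentile"`.
#' @return A `strat_rule` object.
#' @export
strat_rule <- function(kind = c("median", "percentile"), q = NULL) {
  kind <- match.arg(kind)
  if (kind == "percentile") {
    if (is.null(q) || q <= 0 || q >= 100) stop("percentile q must lie in (0, 100)")
  } else {
    q <- 50
  }
  structure(list(kind = kind, q = q), class = "strat_rule")
}

#' Split patients into high and low groups at a cutoff
#'
#' The cutoff is the median or the q-th percentile (linear interpolation
#' between order statistics, i.e. the default quantile convention). A value
#' is labelled `"high"` only when strictly greater than the cutoff, so
#' values tied with the cutoff fall in the low group; missing values get
#' missing labels.
#'
#' @param values Numeric vector, one value per patient.
#' @param rule A [strat_rule()]; default median split.
#' @return Character vector of `"high"`/`"low"` (`NA` where the value is
#'   missing), with attribute `cutoff`. All-identical values yield all-low
#'   with a warning.
#' @export
stratify <- function(values, rule = strat_rule("median")) {
  stopifnot(inherits(rule, "strat_rule"))
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) stop("need at least 2 non-missing values")
  cutoff <- unname(stats::quantile(obs, rule$q / 100, type = 7))
  if (min(obs) == max(obs)) {
    warning("all values identical; degenerate split, everyone labelled low")
  }
  labels <- ifelse(is.na(values), NA_character_,
                   ifelse(values > cutoff, "high", "low"))
  structure(labels, cutoff = cutoff)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function under right censoring.
#' Censored times reduce the risk set without creating a step.
#'
#' @param time Non-negative event/censoring times.
#' @param event Logical (or 0/1) event indicator; `FALSE` means censored.
#' @return Data frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event), all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected log-rank with the hypergeometric
#' variance (tie-corrected), 1 degree of freedom.
#'
#' @param time,event Survival times and event indicators.
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `p`, and per-group sizes `n`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("log-rank test needs exactly 2 groups")
  if (any(table(group) == 0L)) stop("empty group")
  if (sum(event) < 1L) stop("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  chisq <- unname(sd_$chisq)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       n = stats::setNames(as.vector(sd_$n), levels(group)))
}

#' Survival stratified by an infiltration cutoff
#'
#' Convenience wrapper: stratifies `values` by `rule`, then compares the
#' resulting high and low groups by Kaplan-Meier / log-rank.
#'
#' @param time,event Survival data.
#' @param values Per-patient infiltration values (IHC density or composite
#'   score).
#' @param rule A [strat_rule()].
#' @return A `km_comparison`: list with `labels`, `cutoff`, per-group
#'   [km_estimate()] tables, and the [logrank_test()] result.
#' @export
survival_by_cutoff <- function(time, event, values, rule = strat_rule("median")) {
  labels <- stratify(values, rule)
  keep <- !is.na(labels)
  lr <- logrank_test(time[keep], event[keep], labels[keep])
  curves <- lapply(c(high = "high", low = "low"), function(g) {
    sel <- keep & labels == g
    km_estimate(time[sel], event[sel])
  })
  structure(list(labels = labels, cutoff = attr(labels, "cutoff"),
                 curves = curves, logrank = lr),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat(sprintf("high/low survival comparison at cutoff %.4g\n", x$cutoff))
  cat(sprintf("  n = %d high, %d low; log-rank chisq = %.3f, p = %.4g\n",
              x$logrank$n["high"], x$logrank$n["low"],
              x$logrank$chisq, x$logrank$p))
  invisible(x)
}

#' @export
plot.km_comparison <- function(x, main = "Kaplan-Meier by infiltration", ...) {
  cols <- c(high = "red3", low = "blue3")
  plot(NA, xlim = c(0, max(vapply(x$curves, function(cv) max(c(0, cv$time)), 1))),
       ylim = c(0, 1), xlab = "Time", ylab = "Survival", main = main, ...)
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), do.points = FALSE,
                    col = cols[g])
  }
  graphics::legend("topright", legend = names(x$curves), col = cols, lty = 1)
  invisible(x)
}

#' Two-factor survival analysis
#'
#' Within each stratum of the primary variable (e.g. CD3-high and CD3-low
#' separately), compares survival between high and low groups of the
#' secondary variable (e.g. CD68) by log-rank. This asks whether macrophage
#' infiltration refines the outcome groups defined by T-cell infiltration.
#' Strata with fewer than 2 patients, with a constant secondary label, or
#' with no events are skipped with a log note. The four comparisons are
#' reported individually, without multiplicity correction.
#'
#' @param time,event Survival data.
#' @param primary,secondary Per-patient values of the two variables.
#' @param primary_rule,secondary_rule [strat_rule()]s for the two cutoffs.
#' @return Data frame with one row per primary stratum: stratum label, group
#'   sizes, log-rank chi-square and p (NA where skipped), and a `note`.
#' @export
two_factor_survival <- function(time, event, primary, secondary,
                                primary_rule = strat_rule("percentile", 75),
                                secondary_rule = strat_rule("percentile", 75)) {
  p_lab <- stratify(primary, primary_rule)
  s_lab <- stratify(secondary, secondary_rule)
  out <- lapply(c("high", "low"), function(ps) {
    sel <- !is.na(p_lab) & !is.na(s_lab) & p_lab == ps
    row <- data.frame(primary_stratum = ps,
                      n_secondary_high = sum(s_lab[sel] == "high"),
                      n_secondary_low = sum(s_lab[sel] == "low"),
                      chisq = NA_real_, p = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    if (sum(sel) < 2L) {
      row$note <- "skipped: fewer than 2 patients"
    } else if (length(unique(s_lab[sel])) < 2L) {
      row$note <- "skipped: secondary label constant in stratum"
    } else if (sum(event[sel]) < 1L) {
      row$note <- "skipped: no events in stratum"
    } else {
      lr <- logrank_test(time[sel], event[sel], s_lab[sel])
      row$chisq <- lr$chisq
      row$p <- lr$p
    }
    row
  })
  do.call(rbind, out)
}
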