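#' Declarative guideline rule
#'
#' One treatment-selection rule: for staging combinations matched by the
#' given T/N/M state sets and tolerance condition, the treatment is indicated
#' with probability `p_true`. Rules are resolved per CPT cell: the matching
#' rule with the highest `priority` wins; among equal priorities the one
#' listed last wins (a warning is emitted when equal-priority rules disagree
#' on `p_true`); a cell matched by no rule falls back to the treatment's
#' default.
#'
#' @param treatment name of the (binary) treatment node the rule sets.
#' @param t,n,m character vectors of T/N/M states the rule applies to, or
#'   `"any"`.
#' @param tolerance `"tolerant"`, `"intolerant"` or `"any"`. Only meaningful
#'   for treatments whose CPT has the chemotherapy-tolerance parent.
#' @param p_true probability in `[0, 1]` that the treatment is indicated.
#' @param priority integer; higher is more specific and wins.
#' @return A list of class `"guideline_rule"`.
#' @export
guideline_rule <- function(treatment, t = "any", n = "any", m = "any",
                           tolerance = "any", p_true, priority = 1L) {
  stopifnot(is.numeric(p_true), length(p_true) == 1L, p_true >= 0, p_true <= 1)
  structure(list(treatment = treatment, t = t, n = n, m = m,
                 tolerance = tolerance, p_true = as.numeric(p_true),
                 priority = as.integer(priority)),
            class = "guideline_rule")
}

#' Ordered set of guideline rules with per-treatment defaults
#'
#' @param rules list of [guideline_rule()] objects, in listing order (order
#'   breaks ties between equal-priority rules: last listed wins).
#' @param defaults named numeric vector: fallback `p_true` per treatment for
#'   cells no rule matches.
#' @return A list of class `"guideline_ruleset"`.
#' @export
guideline_ruleset <- function(rules, defaults) {
  stopifnot(all(vapply(rules, inherits, TRUE, "guideline_rule")),
            is.numeric(defaults), !is.null(names(defaults)),
            all(defaults >= 0 & defaults <= 1))
  treatments <- unique(vapply(rules, `[[`, "", "treatment"))
  missing_def <- setdiff(treatments, names(defaults))
  if (length(missing_def) > 0L) {
    stop("no default p_true for treatment(s): ",
         paste(missing_def, collapse = ", "), call. = FALSE)
  }
  structure(list(rules = rules, defaults = defaults),
            class = "guideline_ruleset")
}

#' @export
print.guideline_ruleset <- function(x, ...) {
  cat(sprintf("Guideline rule set: %d rules, %d treatment defaults\n",
              length(x$rules), length(x$defaults)))
  invisible(x)
}

set_label <- function(s) if (identical(s, "any")) "any" else paste(s, collapse = "|")

#' @export
print.guideline_rule <- function(x, ...) {
  cat(sprintf("[p%d] T=%s N=%s M=%s tol=%s -> P(%s) = %.3f\n", x$priority,
              set_label(x$t), set_label(x$n), set_label(x$m), x$tolerance,
              x$treatment, x$p_true))
  invisible(x)
}

rule_matches <- function(rule, t, n, m, tol) {
  (identical(rule$t, "any") || t %in% rule$t) &&
    (identical(rule$n, "any") || n %in% rule$n) &&
    (identical(rule$m, "any") || m %in% rule$m) &&
    (identical(rule$tolerance, "any") || (!is.na(tol) && tol == rule$tolerance))
}

check_rule_states <- function(rule, spec) {
  bad <- character()
  if (!identical(rule$t, "any")) bad <- c(bad, setdiff(rule$t, spec$t_states))
  if (!identical(rule$n, "any")) bad <- c(bad, setdiff(rule$n, spec$n_states))
  if (!identical(rule$m, "any")) bad <- c(bad, setdiff(rule$m, spec$m_states))
  if (!rule$tolerance %in% c("any", spec$tolerance_states)) {
    bad <- c(bad, rule$tolerance)
  }
  if (length(bad) > 0L) {
    stop(sprintf("rule for '%s' references unknown state(s): %s",
                 rule$treatment, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!rule$treatment %in% spec$treatments) {
    stop(sprintf("unknown treatment '%s'", rule$treatment), call. = FALSE)
  }
  if (rule$tolerance != "any" &&
      !"chemo_tolerance" %in% spec$treatment_parents[[rule$treatment]]) {
    stop(sprintf(
      "rule for '%s' conditions on tolerance, but that node is not a parent of '%s'",
      rule$treatment, rule$treatment), call. = FALSE)
  }
  invisible(NULL)
}

#' Compile a guideline rule set into treatment CPTs
#'
#' Expands the ordered rule set over the full Cartesian product of each
#' treatment's parent states. For every parent-state combination the winning
#' rule (highest priority; among equals the last listed; otherwise the
#' treatment default) sets `P(true)`, and `P(false) = 1 - P(true)`, so every
#' compiled column is normalized by construction.
#'
#' @param ruleset a [guideline_ruleset()].
#' @param spec a model specification as returned by [larynx_spec()]; defines
#'   states and each treatment's parent set.
#' @return Named list of CPT arrays, one per treatment node (first dimension
#'   `false`/`true`, then the parents).
#' @export
compile_cpts <- function(ruleset, spec = larynx_spec()) {
  for (r in ruleset$rules) check_rule_states(r, spec)
  missing_def <- setdiff(spec$treatments, names(ruleset$defaults))
  if (length(missing_def) > 0L) {
    stop("no default p_true for treatment(s): ",
         paste(missing_def, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (trt in spec$treatments) {
    pars <- spec$treatment_parents[[trt]]
    parent_states <- list(T = spec$t_states, N = spec$n_states,
                          M = spec$m_states,
                          chemo_tolerance = spec$tolerance_states)[pars]
    grid <- expand.grid(parent_states, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    rules <- Filter(function(r) r$treatment == trt, ruleset$rules)
    p <- rep(ruleset$defaults[[trt]], nrow(grid))
    conflicts <- 0L
    for (i in seq_len(nrow(grid))) {
      tol <- if ("chemo_tolerance" %in% pars) grid$chemo_tolerance[i] else NA_character_
      hit <- which(vapply(rules, rule_matches, TRUE,
                          t = grid$T[i], n = grid$N[i], m = grid$M[i], tol = tol))
      if (length(hit) == 0L) next
      prio <- vapply(rules[hit], `[[`, 1L, "priority")
      top <- hit[prio == max(prio)]
      if (length(top) > 1L) {
        ps <- vapply(rules[top], `[[`, 1.0, "p_true")
        if (length(unique(ps)) > 1L) conflicts <- conflicts + 1L
      }
      p[i] <- rules[[top[length(top)]]]$p_true
    }
    if (conflicts > 0L) {
      warning(sprintf(
        "equal-priority rules disagree for '%s' in %d cell(s); last listed wins",
        trt, conflicts), call. = FALSE)
    }
    dims <- c(2L, vapply(parent_states, length, 1L))
    dn <- c(list(c("false", "true")), parent_states)
    names(dn) <- c(trt, pars)
    out[[trt]] <- array(rbind(1 - p, p), dim = dims, dimnames = dn)
  }
  out
}
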