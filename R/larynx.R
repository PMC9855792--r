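#' Specification of the laryngeal-carcinoma treatment model
#'
#' Fixed variable/state design of the packaged model: TNM staging nodes with
#' the full subcategory ranges (T: TX--T4b including T0 and TIS; N: NX--N3b;
#' M: MX, M0, M1), a binary chemotherapy-tolerance prerequisite node, and
#' five binary treatment nodes. Each treatment node has the three staging
#' nodes as parents; the tolerance node is additionally a parent of the
#' three systemic-therapy-dependent treatments (surgery, chemotherapy,
#' radiochemotherapy), giving 18 edges over 9 nodes.
#'
#' @return A list with elements `t_states`, `n_states`, `m_states`,
#'   `tolerance_states`, `treatments`, `observables` and `treatment_parents`.
#' @export
larynx_spec <- function() {
  list(
    t_states = c("TX", "T0", "TIS", "T1", "T1a", "T1b", "T2", "T3", "T4a", "T4b"),
    n_states = c("NX", "N0", "N1", "N2a", "N2b", "N2c", "N3a", "N3b"),
    m_states = c("MX", "M0", "M1"),
    tolerance_states = c("tolerant", "intolerant"),
    observables = c("T", "N", "M", "chemo_tolerance"),
    treatments = c("larynx_surgery", "radiotherapy", "radiochemotherapy",
                   "chemotherapy", "immunotherapy"),
    treatment_parents = list(
      larynx_surgery    = c("T", "N", "M", "chemo_tolerance"),
      radiotherapy      = c("T", "N", "M"),
      radiochemotherapy = c("T", "N", "M", "chemo_tolerance"),
      chemotherapy      = c("T", "N", "M", "chemo_tolerance"),
      immunotherapy     = c("T", "N", "M")
    )
  )
}

#' Default root priors of the packaged model
#'
#' The T prior is the empirical T-state distribution of the reference
#' tumor-board cohort (counts out of 97; T0 is a declared state but was
#' never observed, so its prior mass is 0). N, M and chemotherapy-tolerance
#' priors default to uniform because no empirical marginals are available
#' for them; all priors are configurable. Root priors do not affect
#' inference once full staging evidence is set.
#'
#' @return Named list of prior distributions for `T`, `N`, `M` and
#'   `chemo_tolerance`.
#' @export
larynx_priors <- function() {
  spec <- larynx_spec()
  t_counts <- c(TX = 1, T0 = 0, TIS = 1, T1 = 5, T1a = 19, T1b = 8,
                T2 = 16, T3 = 22, T4a = 23, T4b = 2)
  list(
    T = t_counts[spec$t_states] / sum(t_counts),
    N = stats::setNames(rep(1 / 8, 8), spec$n_states),
    M = stats::setNames(rep(1 / 3, 3), spec$m_states),
    chemo_tolerance = c(tolerant = 0.5, intolerant = 0.5)
  )
}

#' The packaged guideline rule set
#'
#' Reads the rule file shipped with the package
#' (`larynx_nccn_like.yaml`). It contains the two fixed surgery anchors —
#' P(surgery) = 0.74 for (T2, N2a, M0, tolerant) and 0.17 for
#' (T2, N2a, M1, tolerant) — plus guideline-flavored rules for early,
#' locally advanced, unresectable and metastatic disease and for
#' chemotherapy intolerance. All values other than the two anchors are a
#' documented elicitation, not a published table.
#'
#' @return A [guideline_ruleset()].
#' @export
default_ruleset <- function() {
  path <- system.file("extdata", "larynx_nccn_like.yaml", package = "laryngobn")
  if (!nzchar(path)) stop("packaged rule file not found", call. = FALSE)
  read_ruleset(path)
}

# The two printed anchor probabilities of the packaged model.
larynx_anchors <- function() {
  list(
    list(T = "T2", N = "N2a", M = "M0", chemo_tolerance = "tolerant", p_true = 0.74),
    list(T = "T2", N = "N2a", M = "M1", chemo_tolerance = "tolerant", p_true = 0.17)
  )
}

#' Build the laryngeal-carcinoma treatment network
#'
#' Compiles the rule set into treatment CPTs and assembles the 9-node /
#' 18-edge network: observable nodes `T`, `N`, `M`, `chemo_tolerance` and
#' target nodes `larynx_surgery`, `radiotherapy`, `radiochemotherapy`,
#' `chemotherapy`, `immunotherapy`. With the default arguments this is the
#' packaged model, whose compiled surgery CPT must reproduce the two anchor
#' probabilities (0.74 / 0.17) exactly; building with a rule set that omits
#' or overrides them is refused unless `require_anchors = FALSE`.
#'
#' @param ruleset a [guideline_ruleset()]; defaults to [default_ruleset()].
#' @param priors named list of root priors as in [larynx_priors()].
#' @param require_anchors check that the two anchor probabilities survive
#'   compilation (default `TRUE`; set `FALSE` for custom models).
#' @return A `"bn"` object.
#' @examples
#' net <- larynx_model()
#' summary(net) # 9 nodes, 18 edges
#' @export
larynx_model <- function(ruleset = NULL, priors = larynx_priors(),
                         require_anchors = TRUE) {
  packaged <- is.null(ruleset) && missing(priors) && isTRUE(require_anchors)
  if (packaged && !is.null(.laryngobn_cache$packaged_model)) {
    return(.laryngobn_cache$packaged_model)
  }
  if (is.null(ruleset)) ruleset <- default_ruleset()
  spec <- larynx_spec()
  cpts <- compile_cpts(ruleset, spec)
  if (require_anchors) {
    for (a in larynx_anchors()) {
      got <- cpts$larynx_surgery["true", a$T, a$N, a$M, a$chemo_tolerance]
      if (!isTRUE(all.equal(unname(got), a$p_true, tolerance = 1e-12))) {
        stop(sprintf(
          "rule set does not preserve the anchor P(surgery|T=%s,N=%s,M=%s,%s) = %.2f (compiled: %.4f); pass require_anchors = FALSE to build a custom model",
          a$T, a$N, a$M, a$chemo_tolerance, a$p_true, got), call. = FALSE)
      }
    }
  }
  variables <- c(
    list(T = spec$t_states, N = spec$n_states, M = spec$m_states,
         chemo_tolerance = spec$tolerance_states),
    lapply(stats::setNames(spec$treatments, spec$treatments),
           function(trt) c("false", "true"))
  )
  roles <- stats::setNames(
    c(rep("observable", 4L), rep("target", length(spec$treatments))),
    names(variables))
  parents <- spec$treatment_parents
  all_cpts <- c(priors[c("T", "N", "M", "chemo_tolerance")], cpts)
  net <- bn_network(variables, parents, all_cpts, roles)
  if (packaged) .laryngobn_cache$packaged_model <- net
  net
}

.laryngobn_cache <- new.env(parent = emptyenv())

#' Names of the treatment (target) nodes of a network
#'
#' @param net a `"bn"` object.
#' @return Character vector of variables with role `"target"`.
#' @export
bn_targets <- function(net) names(net$roles)[net$roles == "target"]

#' @rdname bn_targets
#' @export
bn_observables <- function(net) names(net$roles)[net$roles == "observable"]
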