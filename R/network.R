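#' Construct a discrete Bayesian network
#'
#' A network is a directed acyclic graph of categorical variables in which
#' every variable carries one conditional probability table (CPT) given its
#' parents; root variables carry their prior. The joint distribution
#' factorizes by the chain rule over the CPTs.
#'
#' @param variables named list; one entry per variable, each a character
#'   vector of at least two unique state labels, in declared order. The
#'   declared order is semantic: it is the tie-breaking order used by
#'   [map_state()].
#' @param parents named list mapping each variable to the character vector of
#'   its parent variables (possibly empty). Variables missing from the list
#'   are roots.
#' @param cpts named list of numeric arrays, one per variable. The first
#'   dimension indexes the child's states, the remaining dimensions the
#'   parents' states in the order given by `parents`. A root CPT is its prior
#'   (a plain numeric vector is accepted). Every column (child distribution
#'   for one parent-state combination) must sum to 1 within `1e-9`.
#' @param roles named character vector with values `"observable"` or
#'   `"target"`; defaults to `"observable"` for every variable.
#' @param validate if `TRUE` (default), structural invariants are checked and
#'   violations raise an error. Set to `FALSE` to assemble a deliberately
#'   malformed network for inspection with [bn_validate()].
#'
#' @return An object of class `"bn"`.
#' @seealso [bn_validate()], [bn_posterior()], [larynx_model()]
#' @examples
#' net <- bn_network(
#'   variables = list(A = c("a1", "a2"), B = c("b1", "b2")),
#'   parents = list(B = "A"),
#'   cpts = list(
#'     A = c(a1 = 0.3, a2 = 0.7),
#'     B = matrix(c(0.9, 0.1, 0.2, 0.8), nrow = 2,
#'                dimnames = list(c("b1", "b2"), c("a1", "a2")))
#'   )
#' )
#' bn_joint(net, c(A = "a1", B = "b1")) # 0.3 * 0.9
#' @export
bn_network <- function(variables, parents = list(), cpts, roles = NULL,
                       validate = TRUE) {
  stopifnot(is.list(variables), !is.null(names(variables)))
  vnames <- names(variables)
  parents <- parents[intersect(names(parents), vnames)]
  full_parents <- stats::setNames(vector("list", length(vnames)), vnames)
  for (v in vnames) full_parents[[v]] <- as.character(parents[[v]])
  if (is.null(roles)) roles <- stats::setNames(rep("observable", length(vnames)), vnames)
  roles <- roles[vnames]

  cpts <- lapply(vnames, function(v) {
    arr <- cpts[[v]]
    dn <- c(list(variables[[v]]), variables[full_parents[[v]]])
    names(dn) <- c(v, full_parents[[v]])
    dims <- vapply(dn, length, 1L)
    if (length(arr) != prod(dims)) {
      stop(sprintf("CPT for '%s' has %d values, expected %d", v,
                   length(arr), prod(dims)), call. = FALSE)
    }
    array(as.numeric(arr), dim = dims, dimnames = dn)
  })
  names(cpts) <- vnames

  net <- structure(
    list(variables = variables, roles = roles, parents = full_parents,
         cpts = cpts),
    class = "bn")
  if (validate) {
    rep <- bn_validate(net)
    if (length(rep$problems) > 0L) {
      stop("invalid network:\n  ", paste(rep$problems, collapse = "\n  "),
           call. = FALSE)
    }
  }
  net
}

#' Derived edge set of a network
#'
#' @param net a `"bn"` object.
#' @return two-column character matrix (`parent`, `child`), one row per edge,
#'   derived from the CPT parent lists.
#' @export
bn_edges <- function(net) {
  rows <- do.call(rbind, lapply(names(net$parents), function(v) {
    p <- net$parents[[v]]
    if (length(p) == 0L) NULL else cbind(parent = p, child = v)
  }))
  if (is.null(rows)) rows <- matrix(character(), ncol = 2,
                                    dimnames = list(NULL, c("parent", "child")))
  rows
}

# Kahn's algorithm on the parent lists.
bn_is_acyclic <- function(net) {
  indeg <- vapply(net$parents, length, 1L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  children <- lapply(names(net$parents), function(v) {
    names(net$parents)[vapply(net$parents, function(p) v %in% p, TRUE)]
  })
  names(children) <- names(net$parents)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen == length(net$parents)
}

#' Structural validation report
#'
#' Checks the network invariants — unique variable and state names, declared
#' parents, acyclicity, CPT dimensions, and per-column normalization within
#' `1e-9` — and reports node and edge counts. Violations are listed, not
#' raised, so callers can inspect a malformed network.
#'
#' @param net a `"bn"` object (possibly assembled with `validate = FALSE`).
#' @return A list of class `"bn_structure_report"` with elements `n_nodes`,
#'   `n_edges`, `acyclic`, `cpt_normalized` (named logical per variable) and
#'   `problems` (character vector, empty when the network is valid).
#' @export
bn_validate <- function(net) {
  problems <- character()
  vnames <- names(net$variables)
  if (anyDuplicated(vnames)) {
    problems <- c(problems, paste("duplicated variable names:",
                                  paste(unique(vnames[duplicated(vnames)]), collapse = ", ")))
  }
  for (v in vnames) {
    st <- net$variables[[v]]
    if (length(st) < 2L) problems <- c(problems, sprintf("variable '%s' has fewer than 2 states", v))
    if (anyDuplicated(st)) problems <- c(problems, sprintf("variable '%s' has duplicated state labels", v))
    undeclared <- setdiff(net$parents[[v]], vnames)
    if (length(undeclared) > 0L) {
      problems <- c(problems, sprintf("parent(s) of '%s' not declared: %s", v,
                                      paste(undeclared, collapse = ", ")))
    }
  }
  acyclic <- bn_is_acyclic(net)
  if (!acyclic) problems <- c(problems, "graph contains a directed cycle")

  cpt_ok <- stats::setNames(rep(NA, length(vnames)), vnames)
  for (v in vnames) {
    arr <- net$cpts[[v]]
    if (is.null(arr)) { problems <- c(problems, sprintf("missing CPT for '%s'", v)); next }
    if (any(arr < 0)) {
      cpt_ok[[v]] <- FALSE
      problems <- c(problems, sprintf("CPT for '%s' has negative entries", v))
      next
    }
    cols <- if (length(dim(arr)) > 1L) apply(arr, seq_along(dim(arr))[-1L], sum) else sum(arr)
    cpt_ok[[v]] <- all(abs(cols - 1) <= 1e-9)
    if (!cpt_ok[[v]]) {
      problems <- c(problems, sprintf("CPT column(s) of '%s' do not sum to 1 (max deviation %.3g)",
                                      v, max(abs(cols - 1))))
    }
  }
  structure(list(n_nodes = length(vnames), n_edges = nrow(bn_edges(net)),
                 acyclic = acyclic, cpt_normalized = cpt_ok,
                 problems = problems),
            class = "bn_structure_report")
}

#' @export
print.bn_structure_report <- function(x, ...) {
  cat(sprintf("Network structure: %d nodes, %d edges, %s\n", x$n_nodes,
              x$n_edges, if (x$acyclic) "acyclic" else "CYCLIC"))
  cat(sprintf("CPTs normalized: %d/%d\n",
              sum(x$cpt_normalized, na.rm = TRUE), length(x$cpt_normalized)))
  if (length(x$problems) > 0L) {
    cat("Problems:\n"); cat(paste0("  - ", x$problems, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
print.bn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges\n",
              length(x$variables), nrow(bn_edges(x))))
  roles <- split(names(x$roles), x$roles)
  for (r in names(roles)) {
    cat(sprintf("  %s: %s\n", r, paste(roles[[r]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.bn <- function(object, ...) bn_validate(object)

#' @export
coef.bn <- function(object, ...) object$cpts

# Shared checks for evidence / assignments.
check_states <- function(net, assignment, what = "evidence") {
  if (length(assignment) == 0L) return(invisible(NULL))
  unknown <- setdiff(names(assignment), names(net$variables))
  if (length(unknown) > 0L) {
    stop(sprintf("%s names not in network: %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (v in names(assignment)) {
    if (!assignment[[v]] %in% net$variables[[v]]) {
      stop(sprintf("'%s' is not a state of variable '%s'",
                   assignment[[v]], v), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Joint probability of a full assignment
#'
#' Chain-rule product over all CPT entries: the probability of one complete
#' configuration of the network.
#'
#' @param net a `"bn"` object.
#' @param assignment named character vector or list assigning a state label
#'   to every variable of the network.
#' @return A probability in `[0, 1]`.
#' @export
bn_joint <- function(net, assignment) {
  assignment <- unlist(assignment)
  missing <- setdiff(names(net$variables), names(assignment))
  if (length(missing) > 0L) {
    stop("assignment must cover every variable; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_states(net, assignment, "assignment")
  joint_many(net, as.data.frame(as.list(assignment), stringsAsFactors = FALSE))
}

# Vectorized chain-rule product over the rows of a data frame of full
# assignments (columns = variables, values = state labels). Used by the
# enumeration oracle and the EM learner.
joint_many <- function(net, df) {
  p <- rep(1, nrow(df))
  for (v in names(net$variables)) {
    arr <- net$cpts[[v]]
    codes <- cbind(match(df[[v]], net$variables[[v]]))
    for (par in net$parents[[v]]) {
      codes <- cbind(codes, match(df[[par]], net$variables[[par]]))
    }
    p <- p * unname(arr[codes])
  }
  p
}
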