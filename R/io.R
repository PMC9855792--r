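#' Read and write guideline rule sets
#'
#' Rule files are YAML with a `defaults` mapping (treatment -> fallback
#' `p_true`) and a `rules` sequence; each rule record carries `treatment`,
#' `p_true`, `priority` and optional `t_states`/`n_states`/`m_states`/
#' `tolerance` conditions (omitted means `"any"`). Listing order is
#' preserved, since it breaks ties between equal-priority rules.
#'
#' @param path file path.
#' @return `read_ruleset()` returns a [guideline_ruleset()];
#'   `write_ruleset()` returns `path` invisibly.
#' @export
read_ruleset <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$defaults) || is.null(doc$rules)) {
    stop("rule file must contain 'defaults' and 'rules'", call. = FALSE)
  }
  defaults <- unlist(doc$defaults)
  rules <- lapply(doc$rules, function(r) {
    get <- function(key, default) {
      if (is.null(r[[key]])) default else as.character(unlist(r[[key]]))
    }
    guideline_rule(
      treatment = r[["treatment"]],
      t = get("t_states", "any"), n = get("n_states", "any"),
      m = get("m_states", "any"),
      tolerance = get("tolerance", "any"),
      p_true = r[["p_true"]],
      priority = if (is.null(r[["priority"]])) 1L else r[["priority"]]
    )
  })
  guideline_ruleset(rules, defaults)
}

#' @rdname read_ruleset
#' @param ruleset a [guideline_ruleset()].
#' @export
write_ruleset <- function(ruleset, path) {
  rules <- lapply(ruleset$rules, function(r) {
    rec <- list(treatment = r$treatment)
    if (!identical(r$t, "any")) rec$t_states <- as.list(r$t)
    if (!identical(r$n, "any")) rec$n_states <- as.list(r$n)
    if (!identical(r$m, "any")) rec$m_states <- as.list(r$m)
    if (!identical(r$tolerance, "any")) rec$tolerance <- r$tolerance
    rec$p_true <- r$p_true
    rec$priority <- r$priority
    rec
  })
  yaml::write_yaml(list(defaults = as.list(ruleset$defaults), rules = rules),
                   path, precision = 17L)
  invisible(path)
}

#' Serialize and load a network
#'
#' Networks are stored as JSON listing each variable's name, states, role,
#' parents and flattened CPT values (column-major, child states first).
#' Doubles are written at full precision, so a load -> save -> load round
#' trip is lossless bit for bit.
#'
#' @param net a `"bn"` object.
#' @param path file path.
#' @return `read_network()` returns a `"bn"` object; `write_network()`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  doc <- list(
    format = "laryngobn-network",
    version = 1L,
    variables = lapply(names(net$variables), function(v) {
      list(name = v, states = as.list(net$variables[[v]]),
           role = net$roles[[v]], parents = as.list(net$parents[[v]]),
           cpt = as.vector(net$cpts[[v]]))
    })
  )
  # I(17) = 17 significant digits: doubles survive the round trip bit-exact
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "laryngobn-network")) {
    stop("not a laryngobn network file: ", path, call. = FALSE)
  }
  vars <- list(); parents <- list(); cpts <- list(); roles <- character()
  for (rec in doc$variables) {
    vars[[rec$name]] <- as.character(unlist(rec$states))
    parents[[rec$name]] <- as.character(unlist(rec$parents))
    cpts[[rec$name]] <- as.numeric(unlist(rec$cpt))
    roles[[rec$name]] <- rec$role
  }
  bn_network(vars, parents, cpts, roles)
}

#' Export a network to GeNIe XDSL (write-only, best effort)
#'
#' Writes the network in the XDSL XML dialect used by the GeNIe modeler so
#' the model can be opened there for interactive inspection. Probabilities
#' are emitted in XDSL order (first parent slowest, child states fastest).
#' The exporter covers plain CPT nodes only and is not re-read by this
#' package.
#'
#' @param net a `"bn"` object.
#' @param path output file path.
#' @param id network identifier written into the file.
#' @return `path`, invisibly.
#' @export
write_xdsl <- function(net, path, id = "laryngobn") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  writeLines(sprintf(
    '<?xml version="1.0" encoding="UTF-8"?>\n<smile version="1.0" id="%s" numsamples="10000">\n  <nodes>',
    esc(id)), con)
  for (v in names(net$variables)) {
    arr <- net$cpts[[v]]
    k <- length(dim(arr))
    # XDSL linear order: child fastest, then last parent, ..., first parent
    vals <- if (k > 1L) as.vector(aperm(arr, c(1L, rev(seq(2L, k))))) else as.vector(arr)
    writeLines(sprintf('    <cpt id="%s">', esc(v)), con)
    writeLines(sprintf('      <state id="%s" />', esc(net$variables[[v]])), con)
    if (length(net$parents[[v]]) > 0L) {
      writeLines(sprintf('      <parents>%s</parents>',
                         paste(esc(net$parents[[v]]), collapse = " ")), con)
    }
    writeLines(sprintf('      <probabilities>%s</probabilities>',
                       paste(format(vals, digits = 17, trim = TRUE,
                                    scientific = FALSE), collapse = " ")), con)
    writeLines("    </cpt>", con)
  }
  writeLines("  </nodes>\n</smile>", con)
  invisible(path)
}

#' Content hash of a network or rule set
#'
#' MD5 digest of the canonical serialized form; used to stamp provenance
#' into reports.
#'
#' @param x a `"bn"` or `"guideline_ruleset"` object.
#' @return Length-1 character MD5 hash.
#' @export
content_hash <- function(x) {
  tmp <- tempfile(fileext = if (inherits(x, "bn")) ".json" else ".yaml")
  on.exit(unlink(tmp))
  if (inherits(x, "bn")) write_network(x, tmp) else write_ruleset(x, tmp)
  unname(tools::md5sum(tmp))
}
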