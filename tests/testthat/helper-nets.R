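# Small fixture networks, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A(prior 0.3/0.7) -> B with configurable columns.
two_node_net <- function(pb1_a1 = 0.9, pb1_a2 = 0.2) {
  bn_network(
    variables = list(A = c("a1", "a2"), B = c("b1", "b2")),
    parents = list(B = "A"),
    cpts = list(
      A = c(a1 = 0.3, a2 = 0.7),
      B = matrix(c(pb1_a1, 1 - pb1_a1, pb1_a2, 1 - pb1_a2), nrow = 2,
                 dimnames = list(c("b1", "b2"), c("a1", "a2")))
    )
  )
}

# Fully deterministic chain: every CPT entry on the (a1, b1) path is 1.
deterministic_net <- function() {
  bn_network(
    variables = list(A = c("a1", "a2"), B = c("b1", "b2")),
    parents = list(B = "A"),
    cpts = list(
      A = c(a1 = 1, a2 = 0),
      B = matrix(c(1, 0, 0, 1), nrow = 2,
                 dimnames = list(c("b1", "b2"), c("a1", "a2")))
    )
  )
}

# Random partial evidence over the observables of a network (assumes the
# caller has fixed the RNG seed).
random_evidence <- function(net, max_vars = length(bn_observables(net))) {
  k <- sample(0:max_vars, 1)
  if (k == 0) return(NULL)
  vars <- sample(bn_observables(net), k)
  ev <- vapply(vars, function(v) sample(net$variables[[v]], 1), "")
  # avoid the zero-prior T0 state of the packaged model
  if ("T" %in% names(ev) && identical(unname(ev[["T"]]), "T0")) ev[["T"]] <- "TX"
  ev
}

# Assemble a bn_predictions data frame by hand for metric unit tests.
make_preds <- function(p_true, truth, target = "trt",
                       case_id = sprintf("c%02d", seq_along(p_true))) {
  out <- data.frame(
    case_id = case_id, target = target, p_true = p_true,
    predicted = ifelse(p_true > 0.5, "true", "false"),
    truth = truth, evidence_complete = TRUE, flagged = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bn_predictions", "data.frame")
  out
}

# Mann-Whitney pair-counting AUC oracle (ties count 1/2).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  pairs <- expand.grid(p = pos, n = neg)
  mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
}
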