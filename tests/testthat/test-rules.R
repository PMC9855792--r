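test_that("rule compilation resolves specificity by priority and order", {
  # two-rule toy: a broad metastatic rule and a narrower high-priority one
  rs <- guideline_ruleset(
    list(
      guideline_rule("immunotherapy", m = "M1", p_true = 0.1, priority = 1),
      guideline_rule("immunotherapy", t = "T1a", m = "M1", p_true = 0.9,
                     priority = 2)
    ),
    defaults = c(larynx_surgery = 0.5, radiotherapy = 0.5,
                 radiochemotherapy = 0.5, chemotherapy = 0.5,
                 immunotherapy = 0.5)
  )
  cpts <- compile_cpts(rs)
  expect_equal(unname(cpts$immunotherapy["true", "T1a", "N0", "M1"]), 0.9)
  expect_equal(unname(cpts$immunotherapy["true", "T2", "N0", "M1"]), 0.1)
  expect_equal(unname(cpts$immunotherapy["true", "T1a", "N3b", "M1"]), 0.9)
  # unmatched cells fall back to the default
  expect_equal(unname(cpts$immunotherapy["true", "T1a", "N0", "M0"]), 0.5)
  # every compiled column is normalized
  for (trt in names(cpts)) {
    sums <- apply(cpts[[trt]], seq_along(dim(cpts[[trt]]))[-1], sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("an empty rule list compiles to the defaults everywhere", {
  rs <- guideline_ruleset(list(), defaults = c(
    larynx_surgery = 0.5, radiotherapy = 0.5, radiochemotherapy = 0.5,
    chemotherapy = 0.5, immunotherapy = 0.5))
  cpts <- compile_cpts(rs)
  for (trt in names(cpts)) expect_true(all(cpts[[trt]] == 0.5))
})

test_that("equal-priority conflicts warn and the last listed rule wins", {
  rs <- guideline_ruleset(
    list(
      guideline_rule("radiotherapy", m = "M1", p_true = 0.2, priority = 1),
      guideline_rule("radiotherapy", t = "T2", p_true = 0.8, priority = 1)
    ),
    defaults = c(larynx_surgery = 0.5, radiotherapy = 0.5,
                 radiochemotherapy = 0.5, chemotherapy = 0.5,
                 immunotherapy = 0.5)
  )
  expect_warning(cpts <- compile_cpts(rs), "equal-priority")
  expect_equal(unname(cpts$radiotherapy["true", "T2", "N0", "M1"]), 0.8)
})

test_that("rules referencing unknown states or wrong parents are rejected", {
  defs <- c(larynx_surgery = 0.5, radiotherapy = 0.5, radiochemotherapy = 0.5,
            chemotherapy = 0.5, immunotherapy = 0.5)
  expect_error(
    compile_cpts(guideline_ruleset(
      list(guideline_rule("radiotherapy", t = "T9", p_true = 0.5)), defs)),
    "unknown state")
  # radiotherapy has no tolerance parent, so a tolerance condition is invalid
  expect_error(
    compile_cpts(guideline_ruleset(
      list(guideline_rule("radiotherapy", tolerance = "intolerant",
                          p_true = 0.5)), defs)),
    "not a parent")
  expect_error(
    compile_cpts(guideline_ruleset(
      list(guideline_rule("cryotherapy", p_true = 0.5),
           guideline_rule("larynx_surgery", p_true = 0.5)),
      c(defs, cryotherapy = 0.5))),
    "unknown treatment")
})

test_that("compiled CPTs are invariant to rule permutation under strict priorities", {
  defs <- c(larynx_surgery = 0.5, radiotherapy = 0.5, radiochemotherapy = 0.5,
            chemotherapy = 0.5, immunotherapy = 0.5)
  rules <- list(
    guideline_rule("larynx_surgery", t = c("T1", "T2"), p_true = 0.9, priority = 1),
    guideline_rule("larynx_surgery", m = "M1", p_true = 0.2, priority = 2),
    guideline_rule("larynx_surgery", tolerance = "intolerant", p_true = 0.4,
                   priority = 3),
    guideline_rule("larynx_surgery", t = "T4b", n = "N3b", m = "M1",
                   tolerance = "intolerant", p_true = 0.05, priority = 4)
  )
  ref <- compile_cpts(guideline_ruleset(rules, defs))
  set.seed(9)
  for (i in 1:5) {
    perm <- compile_cpts(guideline_ruleset(sample(rules), defs))
    expect_identical(perm, ref)
  }
})

test_that("the packaged rule set carries the anchors and compiles cleanly", {
  rs <- default_ruleset()
  p_trues <- vapply(rs$rules, `[[`, 1.0, "p_true")
  expect_true(all(p_trues >= 0 & p_trues <= 1))
  expect_true(any(p_trues == 0.74))
  expect_true(any(p_trues == 0.17))
  expect_no_warning(cpts <- compile_cpts(rs))
  expect_equal(unname(cpts$larynx_surgery["true", "T2", "N2a", "M0", "tolerant"]),
               0.74)
  expect_equal(unname(cpts$larynx_surgery["true", "T2", "N2a", "M1", "tolerant"]),
               0.17)
})

test_that("the packaged model has the published structure and anchor inference", {
  net <- larynx_model()
  rep <- bn_validate(net)
  expect_equal(rep$n_nodes, 9L)
  expect_equal(rep$n_edges, 18L)
  expect_true(rep$acyclic)
  expect_true(all(rep$cpt_normalized))
  # tolerance feeds exactly the three systemic-prerequisite treatments
  edges <- bn_edges(net)
  tol_children <- sort(edges[edges[, "parent"] == "chemo_tolerance", "child"])
  expect_identical(tol_children,
                   c("chemotherapy", "larynx_surgery", "radiochemotherapy"))

  ev0 <- c(T = "T2", N = "N2a", M = "M0", chemo_tolerance = "tolerant")
  ev1 <- c(T = "T2", N = "N2a", M = "M1", chemo_tolerance = "tolerant")
  expect_equal(bn_posterior(net, ev0, "larynx_surgery")[["true"]], 0.74,
               tolerance = 1e-12)
  expect_equal(bn_posterior(net, ev1, "larynx_surgery")[["true"]], 0.17,
               tolerance = 1e-12)
})

test_that("uninformative staging yields uncertain recommendations", {
  net <- larynx_model()
  for (trt in bn_targets(net)) {
    p <- bn_posterior(net, c(T = "TX"), trt)[["true"]]
    expect_gt(p, 0.05)
    expect_lt(p, 0.95)
  }
})

test_that("building the packaged model without the anchors is refused", {
  rs <- default_ruleset()
  # drop the anchor rules
  rs$rules <- Filter(function(r) !r$p_true %in% c(0.74, 0.17), rs$rules)
  expect_error(larynx_model(ruleset = rs), "anchor")
  custom <- larynx_model(ruleset = rs, require_anchors = FALSE)
  expect_s3_class(custom, "bn")
  expect_equal(bn_validate(custom)$n_edges, 18L)
})
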