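test_that("cohort generation is reproducible from the seed", {
  net <- larynx_model()
  cfg <- cohort_config(n = 50, seed = 123, missingness = 0.1,
                       inconsistency_rate = 0.05)
  a <- generate_cohort(cfg, net)
  b <- generate_cohort(cfg, net)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n = 50, seed = 124, missingness = 0.1,
                                     inconsistency_rate = 0.05), net)
  expect_false(identical(a, c))
})

test_that("argmax mode without noise reproduces the model's recommendations", {
  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 40, treatment_mode = "argmax_noise",
                                      epsilon = 0, seed = 31), net)
  for (i in c(1, 7, 23)) {
    ev <- unlist(co[i, c("T", "N", "M", "chemo_tolerance")])
    for (trt in bn_targets(net)) {
      p <- bn_posterior(net, ev, trt)[["true"]]
      expect_identical(co[[trt]][i], if (p > 0.5) "true" else "false")
    }
  }
  # and prediction on such a cohort is perfectly accurate
  expect_identical(accuracy(predict(net, co))$overall$accuracy, 1)
})

test_that("empirical marginals converge to the configured distributions", {
  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 100000, seed = 99), net)
  expect_lt(abs(mean(co$T == "T4a") - 23 / 97), 0.005)
  expect_lt(abs(mean(co$gender == "male") - 83 / 97), 0.005)
  expect_lt(abs(mean(co$M == "M1") - 1 / 3), 0.005)
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(marginals = list(M = c(MX = 0.5, M0 = 0.4, M1 = 0.2))),
               "not a normalized")
  expect_error(cohort_config(marginals = list(bogus = c(a = 1))), "unknown marginal")
  net <- larynx_model()
  expect_warning(generate_cohort(cohort_config(n = 5, treatment_mode = "sample",
                                               epsilon = 0.2, seed = 1), net),
                 "ignored")
})

test_that("the consistency screen excludes what it should, with reasons", {
  net <- larynx_model()
  clean <- generate_cohort(cohort_config(n = 30, seed = 8), net)
  scr <- screen_cohort(clean, net)
  expect_equal(nrow(scr$excluded), 0L)
  # screening kept records again excludes nothing (idempotence)
  expect_equal(nrow(screen_cohort(scr$kept, net)$excluded), 0L)

  bad <- clean
  bad$chemo_tolerance[1] <- "intolerant"; bad$chemotherapy[1] <- "true"
  bad$T[2] <- "T99"
  bad$T[3] <- NA; bad$N[3] <- NA; bad$M[3] <- NA
  scr <- screen_cohort(bad, net)
  expect_equal(nrow(scr$excluded), 3L)
  expect_setequal(scr$reasons$reason,
                  c("prerequisite_violation", "invalid_state", "staging_missing"))
})

test_that("inconsistency injection is screened out at roughly the configured rate", {
  net <- larynx_model()
  excl <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(n = 97, inconsistency_rate = 5 / 97,
                                        seed = 600 + s), net)
    nrow(screen_cohort(co, net)$excluded)
  }, 1L)
  expect_gt(mean(excl), 3)   # E = 5, SE of the mean over 20 runs ~ 0.5
  expect_lt(mean(excl), 7)
})

test_that("cohort summaries reproduce counts and the count/n convention", {
  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 97, seed = 14), net)
  s <- summarize_cohort(co)
  expect_equal(sum(s$gender$count), 97L)
  expect_equal(sum(s$age_group$count), 97L)
  expect_equal(sum(s$t_state$count), 97L)
  expect_equal(s$gender$rel_freq, round(s$gender$count / 97, 3))
  # the no-surgery table is the T distribution of the surgery = false subset
  expect_equal(sum(s$t_state_no_surgery$count), sum(co$larynx_surgery == "false"))

  # a cohort engineered to the published gender count reproduces its fraction
  co2 <- co
  co2$gender <- rep(c("male", "female"), c(83, 14))
  expect_equal(summarize_cohort(co2)$gender$rel_freq[1:2], c(0.856, 0.144))

  empty <- summarize_cohort(co[0, ])
  expect_equal(nrow(empty$gender), 0L)
  expect_equal(empty$n, 0L)
})

test_that("CSV case files round-trip losslessly including missing cells", {
  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 25, seed = 5, missingness = 0.2), net)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cases(co, f)
  back <- read_cases(f, net)
  expect_identical(as.data.frame(back), as.data.frame(co))
  # a missing M cell stays missing and is marginalized at inference time
  expect_true(any(is.na(back$M)))
  preds <- predict(net, back)
  expect_false(any(is.na(preds$p_true)))

  # unknown columns are preserved but flagged
  co$comment <- "x"
  write_cases(co, f)
  expect_warning(back <- read_cases(f, net), "unknown column")
  expect_identical(attr(back, "unknown_columns"), "comment")
  expect_identical(back$comment, co$comment)
})

test_that("simulate() on the network is a seeded cohort draw", {
  net <- larynx_model()
  a <- simulate(net, nsim = 10, seed = 77)
  b <- simulate(net, nsim = 10, seed = 77)
  expect_identical(a, b)
  expect_equal(nrow(a), 10L)
})
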