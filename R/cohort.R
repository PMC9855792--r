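# Vectorized P(treatment = "true" | parent states) lookup over the rows of a
# staging data frame. Rows with a missing parent get NA.
treatment_p_true <- function(net, trt, df) {
  arr <- net$cpts[[trt]]
  n <- nrow(df)
  idx <- cbind(rep(match("true", net$variables[[trt]]), n))
  for (p in net$parents[[trt]]) {
    idx <- cbind(idx, match(df[[p]], net$variables[[p]]))
  }
  arr[idx]
}

#' Configuration of a synthetic tumor-board cohort
#'
#' Defines the study conditions a generated cohort emulates. The default
#' marginals are the empirical frequencies of the 97-patient reference
#' cohort for gender, age group and T state (counts divided by 97); N, M and
#' tolerance marginals have no published counterpart and default to the
#' packaged model's priors (uniform). Staging and demographics are sampled
#' independently; treatment truth labels are assigned either by sampling
#' each treatment from its CPT (`"sample"`) or by taking the model's argmax
#' recommendation and flipping it with probability `epsilon`
#' (`"argmax_noise"`).
#'
#' @param n number of cases.
#' @param marginals named list of category distributions for `gender`,
#'   `age_group`, `T`, `N`, `M`, `chemo_tolerance`; each a named numeric
#'   vector summing to 1 (within `1e-9`). Missing entries take the defaults
#'   above.
#' @param treatment_mode `"sample"` or `"argmax_noise"`.
#' @param epsilon label-flip probability in `[0, 1]` for `"argmax_noise"`
#'   mode (ignored with a warning in `"sample"` mode when nonzero).
#' @param missingness per-field probability that an observable value
#'   (T/N/M/tolerance) is blanked after truth assignment.
#' @param inconsistency_rate per-case probability of injecting an
#'   inconsistent record (chemotherapy marked performed for a
#'   chemotherapy-intolerant patient), emulating records that a consistency
#'   screen should exclude.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 92, marginals = list(),
                          treatment_mode = c("sample", "argmax_noise"),
                          epsilon = 0, missingness = 0,
                          inconsistency_rate = 0, seed = NULL) {
  treatment_mode <- match.arg(treatment_mode)
  spec <- larynx_spec()
  priors <- larynx_priors()
  defaults <- list(
    gender = c(male = 83, female = 14) / 97,
    age_group = c("51-60" = 30, "61-70" = 32, "71-80" = 21,
                  "81-90" = 12, "unknown" = 2) / 97,
    T = priors$T, N = priors$N, M = priors$M,
    chemo_tolerance = priors$chemo_tolerance
  )
  for (nm in names(marginals)) {
    if (!nm %in% names(defaults)) stop("unknown marginal: ", nm, call. = FALSE)
    defaults[[nm]] <- marginals[[nm]]
  }
  for (nm in names(defaults)) {
    p <- defaults[[nm]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop(sprintf("marginal '%s' is not a normalized distribution", nm),
           call. = FALSE)
    }
  }
  stopifnot(epsilon >= 0, epsilon <= 1, missingness >= 0, missingness <= 1,
            inconsistency_rate >= 0, inconsistency_rate <= 1)
  structure(list(n = as.integer(n), marginals = defaults,
                 treatment_mode = treatment_mode, epsilon = epsilon,
                 missingness = missingness,
                 inconsistency_rate = inconsistency_rate, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic tumor-board cohort
#'
#' Draws demographics and staging independently from the configured
#' marginals, assigns the five treatment truth labels per
#' `config$treatment_mode`, then injects missingness and inconsistent
#' records. Demographics (gender, age group) are carried for realism but are
#' not evidence: the network has no such nodes.
#'
#' @param config a [cohort_config()].
#' @param model the network used for treatment assignment (default: the
#'   packaged [larynx_model()]).
#' @return Data frame of class `"cohort"`: one row per case with columns
#'   `case_id`, `gender`, `age_group`, `T`, `N`, `M`, `chemo_tolerance`, the
#'   five treatment labels (`"true"`/`"false"`), and `consistency_flag`
#'   (`FALSE` for injected inconsistent records). `NA` means missing.
#' @export
generate_cohort <- function(config, model = larynx_model()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  draw <- function(p) {
    if (n == 0L) character() else
      sample(names(p), n, replace = TRUE, prob = p)
  }
  rec <- data.frame(
    case_id = sprintf("case_%04d", seq_len(n)),
    gender = draw(config$marginals$gender),
    age_group = draw(config$marginals$age_group),
    T = draw(config$marginals$T),
    N = draw(config$marginals$N),
    M = draw(config$marginals$M),
    chemo_tolerance = draw(config$marginals$chemo_tolerance),
    stringsAsFactors = FALSE
  )
  targets <- bn_targets(model)
  if (config$treatment_mode == "sample" && config$epsilon > 0) {
    warning("epsilon is ignored in 'sample' treatment mode", call. = FALSE)
  }
  for (trt in targets) {
    p <- treatment_p_true(model, trt, rec)
    lab <- if (config$treatment_mode == "sample") {
      stats::runif(n) < p
    } else {
      # model argmax (exact tie -> negative state) with flip noise epsilon
      xor(p > 0.5, stats::runif(n) < config$epsilon)
    }
    rec[[trt]] <- ifelse(lab, "true", "false")
  }
  if (config$missingness > 0) {
    for (v in c("T", "N", "M", "chemo_tolerance")) {
      rec[[v]][stats::runif(n) < config$missingness] <- NA_character_
    }
  }
  rec$consistency_flag <- TRUE
  if (config$inconsistency_rate > 0 && n > 0L) {
    bad <- stats::runif(n) < config$inconsistency_rate
    rec$chemo_tolerance[bad] <- "intolerant"
    rec$chemotherapy[bad] <- "true"
    rec$consistency_flag[bad] <- FALSE
  }
  class(rec) <- c("cohort", "data.frame")
  rec
}

#' @param object a `"bn"` object (the model to simulate from).
#' @param nsim number of cases.
#' @param seed integer seed.
#' @param config optional [cohort_config()]; when supplied, `nsim` and
#'   `seed` override its `n` and `seed`.
#' @param ... unused.
#' @rdname generate_cohort
#' @export
simulate.bn <- function(object, nsim = 92, seed = NULL, config = NULL, ...) {
  if (is.null(config)) config <- cohort_config()
  config$n <- as.integer(nsim)
  if (!is.null(seed)) config$seed <- seed
  generate_cohort(config, model = object)
}

#' Consistency screen for case records
#'
#' Reproduces the pre-analysis data screen that removes records with
#' inconsistent content. A record is excluded when (i) any model field
#' carries a label that is not a valid state of its variable
#' (`"invalid_state"`), (ii) a treatment with a hard prerequisite is marked
#' performed while the prerequisite is violated — chemotherapy or
#' radiochemotherapy `"true"` with `chemo_tolerance = "intolerant"`
#' (`"prerequisite_violation"`), or (iii) all staging fields T, N, M are
#' missing (`"staging_missing"`). The published screen's concrete rules are
#' not documented; this rule list is a reconstruction and each exclusion
#' carries its machine-readable reason.
#'
#' @param records a cohort data frame.
#' @param net network defining the valid state labels (default packaged
#'   model).
#' @return List with `kept` (screened cohort), `excluded` (the removed
#'   records) and `reasons` (data frame `case_id`, `reason`).
#' @export
screen_cohort <- function(records, net = larynx_model()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  model_cols <- intersect(names(net$variables), names(records))
  for (v in model_cols) {
    bad <- !is.na(records[[v]]) & !(records[[v]] %in% net$variables[[v]])
    reason[bad & is.na(reason)] <- "invalid_state"
  }
  intol <- !is.na(records$chemo_tolerance) &
    records$chemo_tolerance == "intolerant"
  for (trt in intersect(c("chemotherapy", "radiochemotherapy"), names(records))) {
    bad <- intol & !is.na(records[[trt]]) & records[[trt]] == "true"
    reason[bad & is.na(reason)] <- "prerequisite_violation"
  }
  all_missing <- is.na(records$T) & is.na(records$N) & is.na(records$M)
  reason[all_missing & is.na(reason)] <- "staging_missing"

  keep <- is.na(reason)
  list(kept = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE],
       reasons = data.frame(case_id = records$case_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

freq_table <- function(x, categories, denom) {
  x <- as.character(x)
  x[is.na(x)] <- "missing"
  categories <- c(categories, if (any(x == "missing")) "missing")
  counts <- vapply(categories, function(s) sum(x == s), 1L)
  data.frame(category = categories, count = as.integer(counts),
             rel_freq = round(counts / denom, 3), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Frequency summaries of a cohort
#'
#' Absolute and relative frequency tables for gender, age group, T state (in
#' total and among cases without surgical intervention) and per-treatment
#' performed counts. Relative frequencies are computed against the
#' pre-exclusion cohort size (`denominator`, default the number of rows
#' passed in) and rounded to 3 decimals, matching the reporting convention
#' of the reference cohort tables.
#'
#' @param records a cohort data frame.
#' @param denominator denominator for relative frequencies.
#' @return List of class `"cohort_summary"` with data frames `gender`,
#'   `age_group`, `t_state`, `t_state_no_surgery`, `treatments`, and the
#'   scalar `n`.
#' @export
summarize_cohort <- function(records, denominator = nrow(records)) {
  spec <- larynx_spec()
  if (nrow(records) == 0L) {
    empty <- data.frame(category = character(), count = integer(),
                        rel_freq = numeric(), stringsAsFactors = FALSE)
    return(structure(list(gender = empty, age_group = empty, t_state = empty,
                          t_state_no_surgery = empty, treatments = empty,
                          n = 0L),
                     class = "cohort_summary"))
  }
  no_surgery <- records[!is.na(records$larynx_surgery) &
                          records$larynx_surgery == "false", , drop = FALSE]
  trt_present <- intersect(spec$treatments, names(records))
  trt_counts <- vapply(trt_present, function(trt) {
    sum(!is.na(records[[trt]]) & records[[trt]] == "true")
  }, 1L)
  structure(list(
    gender = freq_table(records$gender, c("male", "female"), denominator),
    age_group = freq_table(records$age_group,
                           c("51-60", "61-70", "71-80", "81-90", "unknown"),
                           denominator),
    t_state = freq_table(records$T, spec$t_states, denominator),
    t_state_no_surgery = freq_table(no_surgery$T, spec$t_states, denominator),
    treatments = data.frame(category = trt_present,
                            count = as.integer(trt_counts),
                            rel_freq = round(trt_counts / denominator, 3),
                            row.names = NULL, stringsAsFactors = FALSE),
    n = nrow(records)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n))
  for (nm in c("gender", "age_group", "t_state", "t_state_no_surgery",
               "treatments")) {
    tab <- x[[nm]]
    tab <- tab[tab$count > 0L, , drop = FALSE]
    if (nrow(tab) == 0L) next
    cat("\n", nm, ":\n", sep = "")
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Read and write CSV case files
#'
#' Case files have one header row of field/node names and one row per case;
#' the empty string encodes a missing value, so files round-trip losslessly
#' including missing cells. Columns that are neither model variables nor
#' known cohort fields are preserved and flagged via the
#' `"unknown_columns"` attribute (with a warning).
#'
#' @param path CSV file path.
#' @param net network used to recognize model columns (default packaged
#'   model).
#' @return `read_cases()` returns a cohort data frame; `write_cases()`
#'   returns `path` invisibly.
#' @export
read_cases <- function(path, net = larynx_model()) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                        check.names = FALSE, stringsAsFactors = FALSE)
  known <- c("case_id", "gender", "age_group", "consistency_flag",
             names(net$variables))
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0L) {
    warning("unknown column(s) preserved: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  if (!"case_id" %in% names(df)) {
    df$case_id <- sprintf("case_%04d", seq_len(nrow(df)))
  }
  if ("consistency_flag" %in% names(df)) {
    df$consistency_flag <- as.logical(df$consistency_flag)
  }
  if (length(unknown) > 0L) attr(df, "unknown_columns") <- unknown
  class(df) <- c("cohort", "data.frame")
  df
}

#' @param records a cohort data frame.
#' @rdname read_cases
#' @export
write_cases <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
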