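# Dirichlet-smoothed counting over complete rows: counts + alpha per cell,
# normalized per parent combination.
count_cpts <- function(net, df, alpha) {
  undefined <- character()
  cpts <- list()
  for (v in names(net$variables)) {
    fam <- c(v, net$parents[[v]])
    f <- lapply(fam, function(u) factor(df[[u]], levels = net$variables[[u]]))
    counts <- do.call(table, f)
    arr <- array(as.numeric(counts) + alpha, dim = dim(counts),
                 dimnames = stats::setNames(dimnames(counts), fam))
    norm <- if (length(fam) > 1L) {
      sweep(arr, seq_along(fam)[-1L], apply(arr, seq_along(fam)[-1L], sum), "/")
    } else arr / sum(arr)
    if (any(!is.finite(norm))) undefined <- c(undefined, v)
    cpts[[v]] <- norm
  }
  list(cpts = cpts, undefined = undefined)
}

uniform_cpts <- function(net) {
  lapply(names(net$variables), function(v) {
    arr <- net$cpts[[v]]
    k <- length(net$variables[[v]])
    array(1 / k, dim = dim(arr), dimnames = dimnames(arr))
  }) |> stats::setNames(names(net$variables))
}

# One EM expectation pass: expected family counts given current parameters.
# Rows are grouped by identical content; each group's missing variables are
# enumerated jointly and weighted by the current-model posterior.
expected_counts <- function(net, df, groups) {
  counts <- lapply(names(net$variables), function(v) {
    arr <- net$cpts[[v]]
    array(0, dim = dim(arr), dimnames = dimnames(arr))
  }) |> stats::setNames(names(net$variables))
  vnames <- names(net$variables)
  for (g in groups) {
    row <- df[g$row, vnames, drop = FALSE]
    miss <- vnames[is.na(unlist(row))]
    if (length(miss) == 0L) {
      grid <- row
      w <- g$mult
    } else {
      grid <- expand.grid(net$variables[miss], KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      for (v in setdiff(vnames, miss)) grid[[v]] <- row[[v]]
      w <- joint_many(net, grid)
      z <- sum(w)
      if (z <= 0) next # inconsistent row under current parameters
      w <- w / z * g$mult
    }
    for (v in vnames) {
      fam <- c(v, net$parents[[v]])
      codes <- vapply(fam, function(u) match(grid[[u]], net$variables[[u]]),
                      integer(nrow(grid)))
      codes <- matrix(codes, nrow = nrow(grid))
      dims <- dim(counts[[v]])
      strides <- cumprod(c(1L, dims[-length(dims)]))
      lin <- as.vector((codes - 1L) %*% strides) + 1L
      add <- rowsum(w, lin)
      idx <- as.integer(rownames(add))
      counts[[v]][idx] <- counts[[v]][idx] + add[, 1L]
    }
  }
  counts
}

#' Fit network parameters from case data
#'
#' Estimates every CPT of a fixed network structure from a cohort. With
#' complete data this is Dirichlet-uniform posterior-mean counting: each
#' cell receives its observed count plus `prior_strength` pseudo-counts and
#' columns are normalized. When rows contain missing values, parameters are
#' estimated by EM started from uniform CPTs (uniform parameter
#' initialization), iterating expectation over the jointly enumerated
#' missing values and Dirichlet-smoothed maximization until the largest CPT
#' change falls below `em_tol` or `em_max_iter` iterations.
#'
#' @param structure a `"bn"` giving variables, parents and roles; its CPT
#'   values are ignored (dimension template only).
#' @param data data frame with one column per network variable (state
#'   labels, `NA` = missing). Extra columns are ignored; absent variable
#'   columns are treated as entirely missing.
#' @param prior_strength Dirichlet pseudo-count per cell (default 1). With
#'   `prior_strength = 0` a parent combination that never occurs yields an
#'   undefined (NaN) column, reported in `$undefined_columns`.
#' @param em_tol,em_max_iter EM stopping rule: maximum absolute CPT change
#'   below `em_tol` (default `1e-6`) or `em_max_iter` iterations (default
#'   200).
#' @return An object of class `c("bn_fit", "bn")`: the network with learned
#'   CPTs plus fields `method` (`"counting"` or `"em"`), `n_rows`,
#'   `prior_strength`, `iterations` and `undefined_columns`. All `"bn"`
#'   methods (inference, prediction, simulation) apply to it directly.
#' @export
bn_fit <- function(structure, data, prior_strength = 1, em_tol = 1e-6,
                   em_max_iter = 200L) {
  stopifnot(inherits(structure, "bn"), prior_strength >= 0)
  net <- structure
  vnames <- names(net$variables)
  df <- as.data.frame(data)[intersect(names(data), vnames)]
  for (v in setdiff(vnames, names(df))) df[[v]] <- NA_character_
  for (v in vnames) {
    bad <- !is.na(df[[v]]) & !(df[[v]] %in% net$variables[[v]])
    if (any(bad)) {
      stop(sprintf("invalid state label(s) for '%s': %s", v,
                   paste(unique(df[[v]][bad]), collapse = ", ")), call. = FALSE)
    }
  }
  complete <- nrow(df) == 0L || all(!is.na(df[vnames]))
  if (complete) {
    res <- count_cpts(net, df, prior_strength)
    net$cpts <- res$cpts
    out <- net
    out$method <- "counting"
    out$iterations <- NA_integer_
    out$undefined_columns <- res$undefined
  } else {
    cur <- net
    cur$cpts <- uniform_cpts(net)
    key <- do.call(paste, c(df[vnames], sep = "\r"))
    first <- !duplicated(key)
    mult <- as.vector(table(factor(key, levels = key[first])))
    groups <- Map(function(r, m) list(row = r, mult = m),
                  which(first), mult)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      counts <- expected_counts(cur, df, groups)
      delta <- 0
      for (v in vnames) {
        fam_dims <- dim(counts[[v]])
        arr <- counts[[v]] + prior_strength
        newcpt <- if (length(fam_dims) > 1L) {
          sweep(arr, seq_along(fam_dims)[-1L],
                apply(arr, seq_along(fam_dims)[-1L], sum), "/")
        } else arr / sum(arr)
        ok <- is.finite(newcpt) & is.finite(cur$cpts[[v]])
        if (any(ok)) delta <- max(delta, max(abs(newcpt[ok] - cur$cpts[[v]][ok])))
        cur$cpts[[v]] <- newcpt
      }
      if (delta < em_tol || iter >= em_max_iter) break
    }
    out <- cur
    out$method <- "em"
    out$iterations <- iter
    out$undefined_columns <- vnames[vapply(cur$cpts, function(a) any(!is.finite(a)), TRUE)]
  }
  out$prior_strength <- prior_strength
  out$n_rows <- nrow(df)
  class(out) <- c("bn_fit", "bn")
  out
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf("Fitted network parameters (%s, n = %d, prior strength %g)\n",
              x$method, x$n_rows, x$prior_strength))
  if (identical(x$method, "em")) cat(sprintf("EM iterations: %d\n", x$iterations))
  if (length(x$undefined_columns) > 0L) {
    cat("Variables with undefined columns:",
        paste(x$undefined_columns, collapse = ", "), "\n")
  }
  NextMethod()
}

#' k-fold cross-validation of parameter learning
#'
#' Shuffles the cohort with the given seed into `k` near-equal folds (any
#' remainder cases are spread over the first folds), then for each fold
#' learns parameters on the other `k - 1` folds with [bn_fit()] (uniform
#' initialization, Dirichlet pseudo-count `prior_strength`) and scores
#' argmax predictions on the held-out fold.
#'
#' @param structure a `"bn"` (defines structure and roles).
#' @param data cohort data frame with truth labels for the target nodes.
#' @param k number of folds (default 10); must not exceed the number of
#'   cases.
#' @param seed integer seed for the fold shuffle.
#' @param prior_strength passed to [bn_fit()].
#' @param targets target nodes to score (default all target-role nodes).
#' @return List of class `"bn_cv"`: `fold_accuracy` (length `k`),
#'   `mean_accuracy`, `fold_sizes`, `k`, `seed`.
#' @export
kfold_cv <- function(structure, data, k = 10L, seed = NULL,
                     prior_strength = 1, targets = bn_targets(structure)) {
  n <- nrow(data)
  if (k > n) stop(sprintf("k = %d exceeds the number of cases (%d)", k, n),
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- rep(seq_len(k), sizes)[order(idx)] # fold id per original row
  accs <- numeric(k)
  for (f in seq_len(k)) {
    train <- data[fold_of != f, , drop = FALSE]
    test <- data[fold_of == f, , drop = FALSE]
    fit <- bn_fit(structure, train, prior_strength = prior_strength)
    preds <- predict(fit, test, targets = targets)
    accs[f] <- accuracy(preds)$overall$accuracy
  }
  res <- list(fold_accuracy = accs, mean_accuracy = mean(accs),
              fold_sizes = sizes, k = k, seed = seed)
  class(res) <- "bn_cv"
  res
}

#' @export
print.bn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %s)\n", x$k,
              if (is.null(x$seed)) "unset" else x$seed))
  cat("fold accuracies:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  cat(sprintf("mean accuracy: %.4f\n", x$mean_accuracy))
  invisible(x)
}
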