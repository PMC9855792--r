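# Internal factor algebra for exact inference. A factor is a list with
#   vars   : character vector (scope, in dimension order)
#   values : numeric array, dim = state counts of the scope; a factor with
#            empty scope is stored as a length-1 numeric (scalar).
# Dimnames always carry the state labels so evidence reduction can index
# by label.

new_factor <- function(vars, values) {
  structure(list(vars = vars, values = values), class = "bn_factor")
}

factor_is_scalar <- function(f) length(f$vars) == 0L

# Array for a CPT: first dim = child states, then parents in declared order.
factor_from_cpt <- function(net, var) {
  cpt <- net$cpts[[var]]
  new_factor(c(var, net$parents[[var]]), cpt)
}

# Fix observed variables to their evidence state, dropping those dimensions.
factor_reduce <- function(f, evidence) {
  hit <- intersect(f$vars, names(evidence))
  if (length(hit) == 0L) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  for (v in hit) idx[[match(v, f$vars)]] <- evidence[[v]]
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  keep <- setdiff(f$vars, hit)
  if (length(keep) == 0L) return(new_factor(character(), sum(vals)))
  # fixed dims have length 1; dropping them preserves the remaining order
  dn <- dimnames(f$values)[match(keep, f$vars)]
  vals <- array(as.vector(vals), dim = vapply(dn, length, 1L), dimnames = dn)
  new_factor(keep, vals)
}

# Expand a factor to a larger scope by recycling over the missing variables,
# then permuting dimensions into the target order.
factor_expand <- function(f, vars, dimnames_full) {
  if (factor_is_scalar(f)) {
    dims <- vapply(dimnames_full[vars], length, 1L)
    return(array(f$values, dim = dims, dimnames = dimnames_full[vars]))
  }
  miss <- setdiff(vars, f$vars)
  arr <- f$values
  for (v in miss) arr <- outer(arr, rep(1, length(dimnames_full[[v]])))
  arr <- aperm(arr, match(vars, c(f$vars, miss)))
  dimnames(arr) <- dimnames_full[vars]
  arr
}

factor_product <- function(f, g) {
  if (factor_is_scalar(f) && factor_is_scalar(g)) {
    return(new_factor(character(), f$values * g$values))
  }
  if (factor_is_scalar(f)) {
    return(new_factor(g$vars, g$values * as.numeric(f$values)))
  }
  if (factor_is_scalar(g)) {
    return(new_factor(f$vars, f$values * as.numeric(g$values)))
  }
  vars <- union(f$vars, g$vars)
  dn <- c(stats::setNames(dimnames(f$values), f$vars),
          stats::setNames(dimnames(g$values), g$vars))
  dn <- dn[!duplicated(names(dn))]
  new_factor(vars, factor_expand(f, vars, dn) * factor_expand(g, vars, dn))
}

factor_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (length(keep) == 0L) return(new_factor(character(), sum(f$values)))
  dn <- dimnames(f$values)[match(keep, f$vars)]
  vals <- apply(f$values, match(keep, f$vars), sum)
  vals <- array(vals, dim = vapply(dn, length, 1L), dimnames = dn)
  new_factor(keep, vals)
}
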