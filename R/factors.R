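# Internal factor algebra over discrete variables.
#
# A factor is a numeric array whose dimnames are a named list mapping
# variable name -> state labels. A factor over zero variables is a plain
# numeric scalar. All inference code (variable elimination, EM E-step)
# is built on the three primitives below: product, marginalization, and
# evidence reduction.

factor_vars <- function(f) {
  if (!is.array(f)) return(character(0))
  names(dimnames(f))
}

new_factor <- function(states, vals) {
  # states: named list var -> character vector of state labels
  array(vals, dim = vapply(states, length, integer(1)), dimnames = states)
}

# Multiply two factors; result variables are union(vars(a), vars(b)),
# with a's variables first.
factor_product <- function(a, b) {
  if (!is.array(a)) return(b * as.numeric(a))
  if (!is.array(b)) return(a * as.numeric(b))
  va <- factor_vars(a)
  vb <- factor_vars(b)
  add <- setdiff(vb, va)
  if (length(add)) {
    dn_add <- dimnames(b)[add]
    a2 <- array(a, dim = c(dim(a), vapply(dn_add, length, integer(1))),
                dimnames = c(dimnames(a), dn_add))
  } else {
    a2 <- a
  }
  target <- names(dimnames(a2))
  miss <- setdiff(target, vb)
  if (length(miss)) {
    dn_miss <- dimnames(a2)[miss]
    b2 <- array(b, dim = c(dim(b), vapply(dn_miss, length, integer(1))),
                dimnames = c(dimnames(b), dn_miss))
  } else {
    b2 <- b
  }
  b2 <- aperm(b2, match(target, names(dimnames(b2))))
  a2 * b2
}

# Sum a factor over the variables in `drop`, keeping the order of the rest.
factor_marginalize <- function(f, drop) {
  if (!is.array(f)) return(f)
  vars <- factor_vars(f)
  drop <- intersect(drop, vars)
  if (!length(drop)) return(f)
  keep <- setdiff(vars, drop)
  if (!length(keep)) return(sum(f))
  g <- aperm(f, c(keep, drop))
  kd <- dim(g)[seq_along(keep)]
  m <- rowSums(array(g, dim = c(prod(kd), prod(dim(g)) / prod(kd))))
  array(m, dim = kd, dimnames = dimnames(f)[keep])
}

# Fix variable `var` to state `state` and drop that dimension.
factor_reduce <- function(f, var, state) {
  vars <- factor_vars(f)
  k <- match(var, vars)
  if (is.na(k)) return(f)
  i <- match(state, dimnames(f)[[k]])
  if (is.na(i)) {
    stop(sprintf("state '%s' is not legal for node '%s'", state, var), call. = FALSE)
  }
  idx <- lapply(dim(f), seq_len)
  idx[[k]] <- i
  g <- do.call(`[`, c(list(f), idx, list(drop = FALSE)))
  nd <- dim(g)[-k]
  if (!length(nd)) return(as.numeric(g))
  array(as.numeric(g), dim = nd, dimnames = dimnames(f)[-k])
}

# Multiply a list of factors (scalars allowed).
factor_product_all <- function(factors) {
  out <- 1
  for (f in factors) out <- factor_product(out, f)
  out
}

# Variable elimination: multiply the (evidence-reduced) factors and sum out
# every variable not in `keep`, using a greedy smallest-intermediate-factor
# ordering. Returns an unnormalized factor over (a subset of) `keep`,
# or a scalar when everything is summed out.
ve_eliminate <- function(factors, keep = character(0)) {
  scalar <- 1
  arrs <- list()
  for (f in factors) {
    if (is.array(f)) arrs <- c(arrs, list(f)) else scalar <- scalar * as.numeric(f)
  }
  repeat {
    all_vars <- unique(unlist(lapply(arrs, factor_vars)))
    elim <- setdiff(all_vars, keep)
    if (!length(elim)) break
    # dimension lookup across factors
    var_dim <- integer(0)
    for (f in arrs) {
      d <- dim(f)
      names(d) <- factor_vars(f)
      var_dim <- c(var_dim, d[setdiff(names(d), names(var_dim))])
    }
    cost <- vapply(elim, function(v) {
      touch <- Filter(function(f) v %in% factor_vars(f), arrs)
      vars <- unique(unlist(lapply(touch, factor_vars)))
      prod(var_dim[vars])
    }, numeric(1))
    v <- elim[which.min(cost)]
    hit <- vapply(arrs, function(f) v %in% factor_vars(f), logical(1))
    reduced <- factor_marginalize(factor_product_all(arrs[hit]), v)
    arrs <- arrs[!hit]
    if (is.array(reduced)) {
      arrs <- c(arrs, list(reduced))
    } else {
      scalar <- scalar * as.numeric(reduced)
    }
  }
  out <- factor_product_all(arrs)
  if (is.array(out)) out * scalar else as.numeric(out) * scalar
}
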