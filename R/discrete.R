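# Discretized-network verifier: an independent, deliberately simple route to
# the same posterior as the importance-weighting path. Continuous
# compression is histogrammed into bins; inference on the resulting discrete
# factor graph is exact (variable elimination), so any disagreement with the
# importance-weighted answer is pure discretization error and must shrink as
# bins are refined.

#' Construct a discrete factor
#'
#' A factor is a nonnegative table over the cross-product of the states of
#' its variables, stored as an array with named dimnames.
#'
#' @param variables character vector of variable names.
#' @param states list of state-name vectors, one per variable.
#' @param values numeric array (or vector, filled in array order) of
#'   nonnegative entries.
#' @return An object of class `discrete_factor`.
#' @export
discrete_factor <- function(variables, states, values) {
  dims <- lengths(states)
  arr <- array(as.numeric(values), dim = dims, dimnames = setNames(states, variables))
  if (any(arr < 0) || any(!is.finite(arr)))
    stop("factor entries must be finite and >= 0", call. = FALSE)
  structure(list(variables = variables, table = arr), class = "discrete_factor")
}

.factor_product <- function(f1, f2) {
  vars <- union(f1$variables, f2$variables)
  states <- c(dimnames(f1$table), dimnames(f2$table))
  states <- states[vars]
  grid <- expand.grid(lapply(lengths(states), seq_len))
  names(grid) <- vars
  idx1 <- as.matrix(grid[f1$variables])
  idx2 <- as.matrix(grid[f2$variables])
  vals <- f1$table[idx1] * f2$table[idx2]
  discrete_factor(vars, states, array(vals, dim = lengths(states)))
}

.factor_marginalize <- function(f, var) {
  keep <- setdiff(f$variables, var)
  if (!length(keep)) {
    return(discrete_factor("const", list(const = "1"), sum(f$table)))
  }
  margin <- match(keep, f$variables)
  tab <- apply(f$table, margin, sum)
  discrete_factor(keep, dimnames(f$table)[keep], array(tab, dim = lengths(dimnames(f$table)[keep])))
}

.factor_reduce <- function(f, var, state) {
  if (!var %in% f$variables) return(f)
  i <- match(var, f$variables)
  sel <- match(state, dimnames(f$table)[[i]])
  if (is.na(sel)) stop(sprintf("state '%s' unknown for variable '%s'", state, var),
                       call. = FALSE)
  idx <- rep(list(quote(expr = )), length(f$variables))
  idx[[i]] <- sel
  tab <- do.call(`[`, c(list(f$table), idx, list(drop = FALSE)))
  keep <- setdiff(f$variables, var)
  if (!length(keep)) return(discrete_factor("const", list(const = "1"), sum(tab)))
  dn <- dimnames(f$table)[keep]
  discrete_factor(keep, dn, array(tab, dim = lengths(dn)))
}

#' Build the discretized compression/injury network
#'
#' Histograms the (weighted) compression marginal into `bins`
#' equal-probability bins and attaches the conditional probability table of
#' the Boolean injury node, with the strength-exceedance probability
#' evaluated analytically at each bin midpoint. Returns the two factors
#' P(C) and P(I | C) plus the bin bookkeeping used to turn a posterior over
#' bins back into a number (each bin's representative value is the weighted
#' mean of the draws it contains).
#'
#' @param samples a `sample_set` with a `compression_n` column.
#' @param strength a [strength_model()].
#' @param bins number of bins, at least 10.
#' @return A list of class `discrete_network` with elements `factors` (list
#'   of `discrete_factor`), `bin_edges`, `bin_values` (per-bin
#'   representative compression, N).
#' @export
build_discrete_network <- function(samples, strength = strength_model(), bins = 50) {
  if (bins < 10) stop("at least 10 bins are required", call. = FALSE)
  x <- samples$compression_n
  w <- samples$weight
  edges <- unique(weighted_quantile(x, w, seq(0, 1, length.out = bins + 1)))
  edges[1] <- edges[1] - 1e-9
  nb <- length(edges) - 1
  bin <- findInterval(x, edges, left.open = TRUE, all.inside = TRUE)
  pc <- vapply(seq_len(nb), function(b) sum(w[bin == b]), numeric(1))
  pc <- pc / sum(pc)
  vals <- vapply(seq_len(nb), function(b) {
    wb <- w[bin == b]
    if (sum(wb) > 0) sum(wb * x[bin == b]) / sum(wb) else mean(edges[b + 0:1])
  }, numeric(1))
  mid <- (edges[-1] + edges[-(nb + 1)]) / 2
  p_inj <- .exceedance(mid, strength)
  cstates <- sprintf("bin%03d", seq_len(nb))
  f_c <- discrete_factor("C", list(C = cstates), pc)
  f_ic <- discrete_factor(c("I", "C"), list(I = c("true", "false"), C = cstates),
                          rbind(p_inj, 1 - p_inj))
  structure(list(factors = list(f_c, f_ic), bin_edges = edges, bin_values = vals),
            class = "discrete_network")
}

#' Exact inference on discrete factors by variable elimination
#'
#' Multiplies evidence-reduced factors together, sums out every variable
#' except the query, and normalises. Small-scale stand-in for the
#' junction-tree propagation used by full Bayesian-network engines; on these
#' factor sets the answer is exact.
#'
#' @param factors list of `discrete_factor`s (or a `discrete_network`).
#' @param evidence named character vector/list of observed states, e.g.
#'   `c(I = "true")`; may be empty.
#' @param query variable name to keep.
#' @return Named numeric vector: normalized posterior over the query states.
#' @export
eliminate <- function(factors, evidence = NULL, query) {
  if (inherits(factors, "discrete_network")) factors <- factors$factors
  if (!length(factors)) stop("no factors supplied", call. = FALSE)
  if (!is.null(evidence) && length(evidence)) {
    for (v in names(evidence))
      factors <- lapply(factors, .factor_reduce, var = v, state = evidence[[v]])
  }
  all_vars <- unique(unlist(lapply(factors, `[[`, "variables")))
  if (!query %in% all_vars)
    stop(sprintf("query variable '%s' not present in factors", query), call. = FALSE)
  for (v in setdiff(all_vars, c(query, "const"))) {
    touching <- vapply(factors, function(f) v %in% f$variables, logical(1))
    if (!any(touching)) next
    prod_f <- Reduce(.factor_product, factors[touching])
    factors <- c(factors[!touching], list(.factor_marginalize(prod_f, v)))
  }
  res <- Reduce(.factor_product, factors)
  if (!identical(res$variables, query)) res <- .factor_marginalize(res, setdiff(res$variables, query))
  p <- as.numeric(res$table)
  names(p) <- dimnames(res$table)[[match(query, res$variables)]]
  if (sum(p) <= 0) stop("evidence has zero probability in the discrete network",
                        call. = FALSE)
  p / sum(p)
}

#' Posterior mean compression from the discrete verifier
#'
#' Runs [eliminate()] for the compression node given injury evidence and
#' collapses the bin posterior onto the per-bin representative values.
#'
#' @param network a `discrete_network` from [build_discrete_network()].
#' @param evidence "none", "true" or "false".
#' @return Posterior mean compression (N).
#' @export
discrete_posterior_mean <- function(network, evidence = c("none", "true", "false")) {
  evidence <- match.arg(evidence)
  ev <- if (evidence == "none") NULL else c(I = evidence)
  post <- eliminate(network, ev, query = "C")
  sum(post * network$bin_values)
}
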