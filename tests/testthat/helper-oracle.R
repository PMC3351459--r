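# Independent LP oracle built on pracma::linprog (a different algorithm and
# code path from the package's simplex). Solves max c'v, S v = 0,
# l <= v <= u, optionally with one extra constraint coef'v >= rhs, by
# shifting to nonnegative variables z = v - l. pracma breaks pivot ties at
# random and can stall on degenerate problems, so failed solves are retried
# (each retry samples a different pivot sequence).
oracle_lp_max <- function(S, l, u, obj, extra = NULL, maxiter = 1000,
                          attempts = 25) {
  n <- ncol(S)
  beq <- as.vector(-S %*% l)
  Aub <- diag(n)
  bub <- u - l
  if (!is.null(extra)) {
    Aub <- rbind(Aub, -extra$coef)
    bub <- c(bub, -(extra$rhs - sum(extra$coef * l)))
  }
  for (k in seq_len(attempts)) {
    res <- tryCatch(
      pracma::linprog(-obj, A = Aub, b = bub, Aeq = S, beq = beq,
                      maxiter = maxiter),
      error = function(e) NULL)
    if (!is.null(res) && !is.null(res$x)) {
      v <- res$x + l
      return(list(objective = sum(obj * v), fluxes = v))
    }
  }
  NULL
}

oracle_fba <- function(model, limits = model_limits(model), cap = 1000) {
  lim <- resolve_bounds(limits, cap)
  obj <- numeric(length(model$reaction_ids))
  obj[model$biomass_reaction] <- 1
  res <- oracle_lp_max(model$S, lim$lower, lim$upper, obj)
  if (is.null(res)) return(NULL)
  names(res$fluxes) <- model$reaction_ids
  res
}

# brute-force per-reaction FVA: one shifted LP per direction per reaction
oracle_fva <- function(model, limits, fraction, objective_opt, cap = 1000) {
  lim <- resolve_bounds(limits, cap)
  n <- length(model$reaction_ids)
  f <- numeric(n); f[model$biomass_reaction] <- 1
  extra <- list(coef = f, rhs = fraction * objective_opt)
  vmin <- vmax <- numeric(n)
  for (j in seq_len(n)) {
    cj <- numeric(n); cj[j] <- 1
    up <- oracle_lp_max(model$S, lim$lower, lim$upper, cj, extra)
    dn <- oracle_lp_max(model$S, lim$lower, lim$upper, -cj, extra)
    if (is.null(up) || is.null(dn)) return(NULL)
    vmax[j] <- up$objective
    vmin[j] <- -dn$objective
  }
  list(vmin = stats::setNames(vmin, model$reaction_ids),
       vmax = stats::setNames(vmax, model$reaction_ids))
}
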