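#' Flux limit vectors
#'
#' Paired lower/upper flux bounds for every reaction of a model, the
#' \code{a}/\code{b} vectors of the FBA problem. Infinite entries are kept as
#' given and resolved to a finite cap only when a problem is solved.
#'
#' @param lower,upper numeric vectors of equal length (mmol/gDW/h).
#' @param reaction_ids optional names.
#' @return object of class \code{limit_vectors}.
#' @export
limit_vectors <- function(lower, upper, reaction_ids = NULL) {
  if (length(lower) != length(upper))
    stop("lower and upper must have equal length", call. = FALSE)
  if (any(lower > upper, na.rm = TRUE))
    stop("lower bound exceeds upper bound for ",
         sum(lower > upper), " reaction(s)", call. = FALSE)
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 reaction_ids = reaction_ids), class = "limit_vectors")
}

#' Default limits of a model
#'
#' @param model a \code{metabolic_model}.
#' @return the model's shipped bounds as a \code{limit_vectors}.
#' @export
model_limits <- function(model) {
  limit_vectors(model$lower, model$upper, model$reaction_ids)
}

#' Resolve unbounded flux limits to a finite cap
#'
#' LP solving requires finite bounds; entries at or beyond \code{cap} in
#' magnitude (including \code{Inf}) are clamped to \code{+/-cap}, the
#' conventional COBRA-style cap of 1000 mmol/gDW/h.
#'
#' @param limits a \code{limit_vectors}.
#' @param cap positive finite cap.
#' @return a \code{limit_vectors} with finite entries.
#' @export
resolve_bounds <- function(limits, cap = 1000) {
  stopifnot(is.finite(cap), cap > 0)
  lo <- pmax(limits$lower, -cap)
  up <- pmin(limits$upper, cap)
  # deliberately no lower <= upper validation: an inverted pair is a
  # legitimate way to express an infeasible scenario to the solver
  structure(list(lower = lo, upper = up, reaction_ids = limits$reaction_ids),
            class = "limit_vectors")
}

# Solve max c'v s.t. S v = 0, lo <= v <= up, optionally plus one linear
# row constraint extra$coef . v >= extra$rhs (implemented with a slack column).
lp_fba <- function(S, lo, up, obj, extra = NULL) {
  if (any(lo > up)) return(list(status = 1L, objective = NA_real_, x = NULL))
  if (is.null(extra)) {
    res <- .lp_simplex(S, rep(0, nrow(S)), obj, lo, up)
    return(res)
  }
  n <- ncol(S)
  A <- rbind(cbind(S, 0), c(extra$coef, -1))
  b <- c(rep(0, nrow(S)), extra$rhs)
  res <- .lp_simplex(A, b, c(obj, 0), c(lo, 0), c(up, 1e7))
  if (res$status == 0L) res$x <- res$x[seq_len(n)]
  res
}

#' Flux balance analysis: maximize an objective flux
#'
#' Solves the linear program \code{max f'v} subject to mass balance
#' \code{S v = 0} and flux bounds \code{a <= v <= b}, the standard model of
#' log-phase growth when the objective is the biomass reaction.
#'
#' @param model a \code{metabolic_model}.
#' @param limits a \code{limit_vectors}; default the model's shipped bounds.
#' @param objective reaction id or index to maximize; default the biomass
#'   reaction.
#' @param cap finite cap applied to unbounded limits before solving.
#' @return object of class \code{fba_solution}: \code{objective_value},
#'   \code{fluxes} (named, or \code{NULL} when not optimal) and \code{status}
#'   (\code{"optimal"}, \code{"infeasible"} or \code{"unbounded"}).
#' @examples
#' toy <- make_toy_model(panel_size = 2)
#' lim <- model_limits(toy$model)
#' lim$lower[match("EX_glc", toy$model$reaction_ids)] <- -10
#' solve_fba(toy$model, lim)
#' @export
solve_fba <- function(model, limits = model_limits(model),
                      objective = model$biomass_reaction, cap = 1000) {
  stopifnot(inherits(model, "metabolic_model"))
  j <- reaction_index(model$reaction_ids, objective)
  lim <- resolve_bounds(limits, cap)
  obj <- numeric(length(model$reaction_ids))
  obj[j] <- 1
  res <- lp_fba(model$S, lim$lower, lim$upper, obj)
  status <- c("optimal", "infeasible", "unbounded", "iteration_limit")[res$status + 1L]
  fluxes <- NULL
  if (res$status == 0L) {
    fluxes <- stats::setNames(res$x, model$reaction_ids)
  }
  structure(list(objective_value = if (res$status == 0L) res$objective else NA_real_,
                 fluxes = fluxes, status = status,
                 objective_reaction = model$reaction_ids[j]),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status: ", x$status, sep = "")
  if (x$status == "optimal")
    cat("; ", x$objective_reaction, " = ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Calibrate nutrient uptake to a target growth rate
#'
#' Finds the uptake bound \code{U} for one exchange reaction (lower bound
#' \code{-U}, uptake being negative flux) such that the optimal biomass
#' production equals the target growth rate. Because optimal biomass is
#' continuous and nondecreasing in \code{U}, the inverse is found by bisection
#' on \code{[0, cap]}.
#'
#' @param model a \code{metabolic_model}.
#' @param exchange exchange reaction id or index for the nutrient.
#' @param target_growth target growth rate in 1/h (must be > 0); when no
#'   measured rate is available the conventional nominal rate is 0.5/h.
#' @param limits base limits in which to calibrate (other nutrients already
#'   closed as desired); default the model's shipped bounds.
#' @param cap maximum uptake magnitude considered in the search.
#' @param bound_cap finite cap applied to unbounded limits before solving.
#' @param tol relative tolerance on the achieved growth rate.
#' @return list with \code{uptake} (the positive magnitude \code{U}),
#'   \code{lower}/\code{upper} (the calibrated exchange bounds), and
#'   \code{growth} (the re-solved optimum).
#' @export
calibrate_uptake <- function(model, exchange, target_growth = 0.5,
                             limits = model_limits(model), cap = 1000,
                             tol = 1e-6, bound_cap = 1000) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.numeric(target_growth) || target_growth <= 0)
    stop("target_growth must be positive", call. = FALSE)
  j <- reaction_index(model$reaction_ids, exchange)
  if (!(j %in% model$exchange_reactions))
    stop("'", model$reaction_ids[j], "' is not an exchange reaction", call. = FALSE)
  lim <- resolve_bounds(limits, bound_cap)

  growth_at <- function(U) {
    l2 <- lim
    l2$lower[j] <- -U
    if (l2$upper[j] < -U) l2$upper[j] <- -U
    sol <- lp_fba(model$S, l2$lower, l2$upper,
                  objective_vector(model), extra = NULL)
    if (sol$status != 0L) NA_real_ else sol$objective
  }
  f_cap <- growth_at(cap)
  if (is.na(f_cap) || f_cap < target_growth * (1 - tol))
    stop(sprintf(
      "calibration failed for '%s': target %.6g/h exceeds achievable maximum %.6g/h",
      model$reaction_ids[j], target_growth,
      if (is.na(f_cap)) 0 else f_cap), call. = FALSE)

  lo <- 0; hi <- cap
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    f <- growth_at(mid)
    if (is.na(f) || f < target_growth) lo <- mid else hi <- mid
    if (abs(f - target_growth) <= tol * target_growth &&
        !is.na(f) && f >= target_growth) { hi <- mid; break }
  }
  U <- hi
  achieved <- growth_at(U)
  list(uptake = U, lower = -U, upper = lim$upper[j], growth = achieved,
       exchange = model$reaction_ids[j])
}

objective_vector <- function(model) {
  f <- numeric(length(model$reaction_ids))
  f[model$biomass_reaction] <- 1
  f
}

#' Flux variability analysis (the max/min problem)
#'
#' For each reaction, maximizes and minimizes its flux subject to the FBA
#' constraints plus the requirement that biomass production be at least
#' \code{fraction} of its optimum \code{objective_opt} — 2n LPs in total.
#' The resulting per-reaction envelope captures every near-optimal flux
#' distribution regardless of which optimal vertex an individual FBA solve
#' happens to return.
#'
#' @param model a \code{metabolic_model}.
#' @param limits a \code{limit_vectors}.
#' @param fraction required optimality fraction in (0, 1]; default 0.9.
#' @param objective_opt precomputed biomass optimum for these limits; computed
#'   by FBA when \code{NULL}.
#' @param reactions ids/indices to analyze (default all).
#' @param cap finite cap for unbounded limits.
#' @return object of class \code{fva_result}: named vectors \code{vmin},
#'   \code{vmax}, and the \code{fraction} used.
#' @export
flux_variability <- function(model, limits = model_limits(model),
                             fraction = 0.9, objective_opt = NULL,
                             reactions = NULL, cap = 1000) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]", call. = FALSE)
  lim <- resolve_bounds(limits, cap)
  f <- objective_vector(model)
  if (is.null(objective_opt)) {
    sol <- lp_fba(model$S, lim$lower, lim$upper, f)
    if (sol$status != 0L)
      stop("FBA infeasible under the supplied limits", call. = FALSE)
    objective_opt <- sol$objective
  }
  extra <- list(coef = f, rhs = fraction * objective_opt)
  idx <- if (is.null(reactions)) seq_along(model$reaction_ids) else
    vapply(reactions, reaction_index, 1L, ids = model$reaction_ids)

  n <- length(model$reaction_ids)
  vmin <- vmax <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    cj <- numeric(n); cj[idx[k]] <- 1
    up <- lp_fba(model$S, lim$lower, lim$upper, cj, extra = extra)
    dn <- lp_fba(model$S, lim$lower, lim$upper, -cj, extra = extra)
    if (up$status != 0L || dn$status != 0L)
      stop("flux variability subproblem infeasible (fraction * optimum ",
           "unattainable); check inputs", call. = FALSE)
    vmax[k] <- up$objective
    vmin[k] <- -dn$objective
  }
  # LP round-off can leave vmin a hair above vmax on fixed fluxes
  swap <- vmin > vmax
  if (any(swap)) {
    mid <- (vmin[swap] + vmax[swap]) / 2
    vmin[swap] <- vmax[swap] <- mid
  }
  structure(list(vmin = stats::setNames(vmin, model$reaction_ids[idx]),
                 vmax = stats::setNames(vmax, model$reaction_ids[idx]),
                 fraction = fraction, objective_opt = objective_opt),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat("<fva_result> ", length(x$vmin), " reactions at fraction ",
      x$fraction, " of optimum ", format(x$objective_opt), "\n", sep = "")
  invisible(x)
}
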